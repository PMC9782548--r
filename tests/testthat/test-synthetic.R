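test_that("default peak tables carry the standard metabolite sets", {
  p31 <- defaultPeakTable("P31")
  expect_setequal(metabolites(p31),
                  c("PCr", "gamma-ATP", "alpha-ATP", "beta-ATP", "Pi",
                    "NADH", "NAD+", "PE", "PC", "GPE", "GPC", "MP", "DPG"))
  expect_length(metabolites(p31), 13)
  pcr <- peakLines(p31)[peakLines(p31)$metabolite == "PCr", ]
  expect_identical(pcr$shift_ppm, 0)

  h1 <- defaultPeakTable("H1")
  expect_setequal(metabolites(h1),
                  c("Ala", "Asp", "Cr", "PCr", "GABA", "Glc", "Gln", "Glu",
                    "GPC", "PCh", "GSH", "Ins", "Lac", "NAA", "NAAG", "Tau"))
  expect_length(metabolites(h1), 16)
  expect_true(all(peakLines(h1)$shift_ppm >= 0.2 &
                    peakLines(h1)$shift_ppm <= 4.0))

  expect_error(defaultPeakTable("C13"))
})

test_that("synthesized FIDs follow the damped-exponential closed form", {
  acq <- toyAcq(64L)
  ## single line at the carrier, negligible damping: constant 1 + 0i
  tab0 <- PeakTable(data.frame(metabolite = "X", shift_ppm = 0,
                               amplitude = 1, lw_hz = 1e-12, phase_deg = 0),
                    "P31")
  fid0 <- synthesizeFID(tab0, acq)
  expect_equal(samples(fid0), rep(1 + 0i, 64), tolerance = 1e-9)
  expect_identical(provenance(fid0), "ground_truth")

  ## magnitude envelope exp(-pi L t dt)
  L <- 25
  tabL <- PeakTable(data.frame(metabolite = "X", shift_ppm = 3,
                               amplitude = 2, lw_hz = L, phase_deg = 40),
                    "P31")
  fidL <- synthesizeFID(tabL, acq)
  tt <- (0:63) * dwellTime(fidL)
  expect_equal(Mod(samples(fidL)), 2 * exp(-pi * L * tt), tolerance = 1e-12)

  ## linearity: union table == sum of individual FIDs, exactly
  t1 <- toyTable(shifts = c(-6, 2), amps = c(1, 0.5), names = c("A", "B"))
  t2 <- toyTable(shifts = c(4), amps = c(2), names = "C")
  both <- PeakTable(rbind(peakLines(t1), peakLines(t2)), "P31")
  expect_identical(samples(synthesizeFID(both, acq)),
                   samples(synthesizeFID(t1, acq)) +
                     samples(synthesizeFID(t2, acq)))

  ## out-of-band line names the offending metabolite
  bad <- PeakTable(data.frame(metabolite = "FarAway", shift_ppm = 500,
                              amplitude = 1, lw_hz = 10, phase_deg = 0),
                   "P31")
  expect_error(synthesizeFID(bad, acq), "FarAway")
})

test_that("the default 31P table yields 13 resolvable maxima at its shifts", {
  acq <- AcquisitionParams("P31")  # 4096 points, 16025.64 Hz
  tab <- defaultPeakTable("P31")
  sp <- toSpectrum(synthesizeFID(tab, acq))
  y <- Re(spectrumValues(sp))
  ppm <- ppmAxis(sp)
  ## brute-force local-maximum scan on the noiseless spectrum
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  loc <- loc[y[loc] > 0.005 * max(y)]
  expect_length(loc, 13)
  found <- sort(ppm[loc])
  truth <- sort(peakLines(tab)$shift_ppm)
  grid_step <- abs(ppm[1] - ppm[2])
  expect_true(all(abs(found - truth) <= grid_step))
})

test_that("added noise is white, seeded and of the requested scale", {
  acq <- AcquisitionParams("P31")
  gt <- synthesizeFID(defaultPeakTable("P31"), acq)

  expect_identical(samples(addNoise(gt, 0, 1)), samples(gt))
  expect_error(addNoise(gt, -1, 1), "sigma")

  n1 <- addNoise(gt, 1, 123)
  n2 <- addNoise(gt, 1, 123)
  expect_identical(samples(n1), samples(n2))
  expect_identical(provenance(n1), "raw")

  delta <- samples(n1) - samples(gt)
  expect_equal(sd(Re(delta)), 1, tolerance = 0.05)
  expect_equal(sd(Im(delta)), 1, tolerance = 0.05)

  ## whiteness: autocorrelation at lags >= 1 within 3/sqrt(N)
  N <- length(delta)
  for (ch in list(Re(delta), Im(delta))) {
    ac <- acf(ch, lag.max = 5, plot = FALSE)$acf[-1]
    expect_true(all(abs(ac) < 3 / sqrt(N)))
  }

  ## RNG state of the caller is untouched
  set.seed(77)
  before <- .Random.seed
  invisible(addNoise(gt, 1, 5))
  expect_identical(.Random.seed, before)
})

test_that("a noiseless K-line FID has Hankel numerical rank K", {
  acq <- toyAcq(256L)
  for (K in c(1L, 3L, 5L)) {
    fid <- synthesizeFID(kLineTable(K), acq)
    H <- buildHankel(fid, 128L)
    d <- svd(H@entries, nu = 0, nv = 0)$d
    expect_lt(d[K + 1] / d[1], 1e-8)
  }
})

test_that("sigma calibration hits a target SNR and scales inversely", {
  tab <- toyTable()
  acq <- toyAcq(256L)
  gt <- synthesizeFID(tab, acq)
  basis <- makeBasis(tab, acq)
  meanSNR <- function(sigma, seeds) {
    mean(vapply(seeds, function(s) {
      fittedSNR(fitSpectrum(addNoise(gt, sigma, s), basis,
                            fit_nuisance = FALSE))
    }, numeric(1)))
  }

  ## doubling sigma approximately halves the SNR
  s20 <- meanSNR(0.02, 1:20)
  s40 <- meanSNR(0.04, 21:40)
  expect_equal(s20 / s40, 2, tolerance = 0.15)

  ## calibration to a toy operating point, checked by re-simulation
  sigma <- calibrateSigma(tab, acq, target_snr = 20, n_probe = 6,
                          rng_seed = 11, fit_nuisance = FALSE)
  resim <- meanSNR(as.numeric(sigma), 101:120)
  expect_gt(resim, 20 * 0.8)
  expect_lt(resim, 20 * 1.2)

  ## monotone limit: a huge target needs nearly no noise
  sigma0 <- calibrateSigma(tab, acq, target_snr = 1e6, n_probe = 2,
                           rng_seed = 3, fit_nuisance = FALSE)
  expect_lt(as.numeric(sigma0), 1e-3 * max(Mod(samples(gt))))

  expect_error(calibrateSigma(tab, acq, target_snr = -1), "target_snr")
})
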
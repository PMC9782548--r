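test_that("spectra peak at the right ppm and conserve energy", {
  acq <- toyAcq(256L)

  ## constant FID: maximum at the carrier (ref ppm)
  const <- FIDSignal(rep(1 + 0i, 256), acq, "ground_truth")
  spc <- toSpectrum(const)
  expect_equal(ppmAxis(spc)[which.max(Re(spectrumValues(spc)))],
               refPpm(const), tolerance = 1e-9)

  ## single line at +4.8 ppm: maximum within one grid step
  tab <- PeakTable(data.frame(metabolite = "Pi", shift_ppm = 4.8,
                              amplitude = 1, lw_hz = 10, phase_deg = 0),
                   "P31")
  sp <- toSpectrum(synthesizeFID(tab, acq))
  grid_step <- abs(ppmAxis(sp)[1] - ppmAxis(sp)[2])
  expect_lt(abs(ppmAxis(sp)[which.max(Re(spectrumValues(sp)))] - 4.8),
            grid_step)

  ## Parseval under the 1/N DFT convention
  fid <- synthesizeFID(toyTable(), acq)
  e_t <- sum(Mod(samples(fid))^2)
  e_f <- sum(Mod(spectrumValues(toSpectrum(fid)))^2) / 256
  expect_lt(abs(e_t - e_f) / e_t, 1e-10)

  ## ppm axis is decreasing and spans SW/frequency ppm around the carrier
  expect_true(all(diff(ppmAxis(sp)) < 0))
  span <- spectralWidth(fid) / 161.98
  expect_equal(max(ppmAxis(sp)) - min(ppmAxis(sp)), span * 255 / 256,
               tolerance = 1e-9)
})

test_that("window indexing covers the requested ppm range", {
  acq <- AcquisitionParams("P31")  # 4096 pts; axis ~ +/- 49.5 ppm
  sp <- toSpectrum(synthesizeFID(defaultPeakTable("P31"), acq))

  all_idx <- windowIndices(sp, min(ppmAxis(sp)) - 1, max(ppmAxis(sp)) + 1)
  expect_identical(all_idx, seq_len(4096L))

  ## the standard 31P analysis window sits strictly inside the axis
  win <- windowIndices(sp, -19.5, 10)
  expect_gt(min(win), 1L)
  expect_lt(max(win), 4096L)
  expect_true(all(ppmAxis(sp)[win] >= -19.5 & ppmAxis(sp)[win] <= 10))
  ## boundary bins included: neighbours are outside
  expect_gt(ppmAxis(sp)[min(win) - 1L], 10)
  expect_lt(ppmAxis(sp)[max(win) + 1L], -19.5)

  ## degenerate single-bin window
  p0 <- ppmAxis(sp)[2000]
  one <- windowIndices(sp, p0 - 1e-9, p0 + 1e-9)
  expect_identical(one, 2000L)

  expect_error(windowIndices(sp, 10, -19.5), "lo_ppm < hi_ppm")
  expect_error(windowIndices(sp, 200, 300), "overlap")
})

test_that("the fit recovers exact-model amplitudes and injected phase", {
  tab <- toyTable()
  acq <- toyAcq(256L)
  basis <- makeBasis(tab, acq)
  gt <- synthesizeFID(tab, acq)
  truth <- totalAmplitudes(tab)

  fit <- fitSpectrum(gt, basis, fit_nuisance = FALSE)
  expect_equal(amplitudes(fit)[names(truth)], truth, tolerance = 1e-3)
  expect_lt(max(abs(amplitudes(fit)[names(truth)] - truth) / truth), 1e-3)

  ## zero-order phase error of 30 degrees is recovered
  rot <- FIDSignal(samples(gt) * exp(1i * 30 * pi / 180), acq, "raw")
  fitp <- fitSpectrum(rot, basis)
  expect_equal(fitp@phase0_deg, 30, tolerance = 1)
  expect_lt(max(abs(amplitudes(fitp)[names(truth)] - truth) / truth), 0.01)

  ## duplicated basis entries are rejected as collinear
  dup <- PeakTable(rbind(peakLines(tab),
                         within(peakLines(tab)[2, ],
                                metabolite <- "Bcopy")), "P31")
  expect_error(fitSpectrum(gt, makeBasis(dup, acq)), "collinear")

  ## grid mismatch is rejected
  expect_error(fitSpectrum(gt, makeBasis(tab, toyAcq(128L))), "grid")
})

test_that("CRLB matches the one-parameter closed form and scales with sigma", {
  acq <- toyAcq(256L)
  tab <- PeakTable(data.frame(metabolite = "X", shift_ppm = 0,
                              amplitude = 2, lw_hz = 20, phase_deg = 0),
                   "P31")
  basis <- makeBasis(tab, acq)
  gt <- synthesizeFID(tab, acq)
  ## amplitude-only model: no nuisance, no baseline
  fit <- fitSpectrum(gt, basis, fit_nuisance = FALSE, baseline_degree = -1,
                     crlb = FALSE)
  sigma <- 0.4
  crlb <- computeCRLB(fit, basis, sigma = sigma)

  ## hand-coded scalar Fisher sum over the window
  ord <- rev(((seq_len(256L) - 1L + 128L) %% 256L) + 1L)
  Bw <- fft(basis@fids[, 1])[ord][fit@window]
  expected <- 100 * sigma / (amplitudes(fit)[["X"]] * sqrt(sum(Mod(Bw)^2)))
  expect_equal(unname(crlb[["X"]]), unname(expected), tolerance = 1e-10)

  ## exact linearity in sigma, full model
  noisy <- addNoise(gt, 0.1, 8)
  fitn <- fitSpectrum(noisy, basis)
  c1 <- computeCRLB(fitn, basis, sigma = 1)
  c2 <- computeCRLB(fitn, basis, sigma = 2)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("CRLBs never shrink when the basis grows (information nesting)", {
  acq <- toyAcq(256L)
  tab2 <- toyTable(shifts = c(-5, 0), amps = c(1, 2), names = c("A", "B"))
  tab3 <- toyTable()
  gt <- synthesizeFID(tab2, acq)
  f2 <- fitSpectrum(gt, makeBasis(tab2, acq), fit_nuisance = FALSE,
                    crlb = FALSE)
  f3 <- fitSpectrum(gt, makeBasis(tab3, acq), fit_nuisance = FALSE,
                    crlb = FALSE)
  c2 <- computeCRLB(f2, makeBasis(tab2, acq), sigma = 0.5)
  c3 <- computeCRLB(f3, makeBasis(tab3, acq), sigma = 0.5)
  for (m in c("A", "B"))
    expect_gte(c3[[m]], c2[[m]] - 1e-9)
})

test_that("the SNR statistic follows its printed definition", {
  ## constructed fit: peak minus baseline 10, residual RMS 0.5 -> SNR 10
  n <- 64L
  resid <- complex(real = rep(c(0.5, -0.5), n / 2), imaginary = rep(0, n))
  fit <- new("FitResult",
             amplitudes = c(X = 1), crlb_pct = c(X = 1),
             phase0_deg = 0, phase1_deg_per_ppm = 0, shift_hz = 0,
             extra_damping_hz = 0,
             baseline = complex(real = rep(2, n), imaginary = rep(0, n)),
             residual = resid,
             data_window = complex(real = c(12, rep(2, n - 1)),
                                   imaginary = rep(0, n)),
             window = seq_len(n), ppm_window = seq(10, 5, length.out = n),
             snr = NA_real_, sigma = 0.5, baseline_degree = 0L,
             fit_nuisance = FALSE)
  expect_equal(estimateSNR(fit), 10)

  ## noiseless fit-consistent input: +Inf sentinel
  tab <- toyTable()
  acq <- toyAcq(256L)
  gt <- synthesizeFID(tab, acq)
  basis <- makeBasis(tab, acq)
  fit0 <- fitSpectrum(gt, basis, fit_nuisance = FALSE)
  expect_identical(fittedSNR(fit0), Inf)
  expect_true(all(is.na(crlbPct(fit0))))

  ## scale invariance: doubling the signal leaves SNR unchanged
  noisy <- addNoise(gt, 0.05, 3)
  f1 <- fitSpectrum(noisy, basis, fit_nuisance = FALSE)
  f2 <- fitSpectrum(FIDSignal(2 * samples(noisy), acq, "raw"), basis,
                    fit_nuisance = FALSE)
  expect_equal(fittedSNR(f2), fittedSNR(f1), tolerance = 1e-9)

  ## halving sigma roughly doubles SNR
  mean_snr <- function(sigma, seeds)
    mean(vapply(seeds, function(s)
      fittedSNR(fitSpectrum(addNoise(gt, sigma, s), basis,
                            fit_nuisance = FALSE)), numeric(1)))
  expect_equal(mean_snr(0.02, 1:20) / mean_snr(0.04, 21:40), 2,
               tolerance = 0.15)
})

test_that("concentration ratios normalize to the reference metabolite", {
  acq <- toyAcq(256L)
  tab <- toyTable(names = c("PCr", "ATP", "Pi"), amps = c(2, 1, 0.5))
  basis <- makeBasis(tab, acq)
  fit <- fitSpectrum(synthesizeFID(tab, acq), basis, fit_nuisance = FALSE)

  r <- concentrationRatios(fit, "PCr")
  expect_equal(unname(r[["PCr"]]), 1)
  expect_equal(unname(r[["ATP"]]), 0.5, tolerance = 1e-3)
  expect_equal(unname(r[["Pi"]]), 0.25, tolerance = 1e-3)

  ## scale invariance
  fit2 <- fitSpectrum(FIDSignal(3 * samples(synthesizeFID(tab, acq)), acq,
                                "raw"), basis, fit_nuisance = FALSE)
  expect_equal(concentrationRatios(fit2, "PCr"), r, tolerance = 1e-6)

  expect_error(concentrationRatios(fit, "Missing"), "not in the fit")
})
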
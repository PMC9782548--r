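test_that("apodization multiplies by the exponential envelope", {
  acq <- toyAcq(128L)
  fid <- synthesizeFID(toyTable(), acq)

  expect_identical(samples(apodize(fid, 0)), samples(fid))
  expect_error(apodize(fid, -2), "lb_hz")

  lb <- 7
  out <- apodize(fid, lb)
  tt <- (0:127) * dwellTime(fid)
  expect_equal(Mod(samples(out)) / Mod(samples(fid)), exp(-pi * lb * tt),
               tolerance = 1e-12)
})

test_that("apodization broadens a Lorentzian FWHM by exactly lb_hz", {
  ## dense noiseless grid so the half-maximum scan resolves 2%
  acq <- AcquisitionParams("P31", n_points = 8192L, spectral_width = 2000)
  tab <- PeakTable(data.frame(metabolite = "X", shift_ppm = 0, amplitude = 1,
                              lw_hz = 10, phase_deg = 0), "P31")
  fwhmHz <- function(fid) {
    sp <- toSpectrum(fid)
    y <- Re(spectrumValues(sp))
    f <- (ppmAxis(sp) - refPpm(fid)) * 161.98   # back to Hz
    i0 <- which.max(y)
    half <- y[i0] / 2
    cross <- function(side) {
      idx <- if (side == "l") seq(i0, 2) else seq(i0, length(y) - 1)
      for (i in idx) {
        j <- if (side == "l") i - 1L else i + 1L
        if (y[j] <= half) {
          w <- (y[i] - half) / (y[i] - y[j])
          return(f[i] + w * (f[j] - f[i]))
        }
      }
      NA_real_
    }
    abs(cross("r") - cross("l"))
  }
  fid <- synthesizeFID(tab, acq)
  expect_equal(fwhmHz(fid), 10, tolerance = 0.02)
  expect_equal(fwhmHz(apodize(fid, 5)), 15, tolerance = 0.02)
})

test_that("Hankel construction matches its definition", {
  H <- buildHankel(as.complex(1:4), 2L)
  expect_equal(H@entries, matrix(as.complex(c(1, 2, 2, 3, 3, 4)), 2, 3))
  expect_identical(H@source_length, 4L)

  expect_error(buildHankel(as.complex(1:4), 0L), "W must")
  expect_error(buildHankel(as.complex(1:4), 4L), "W must")

  ## half-length default shape on the 4096-point grid: 2048 x 2049
  x <- complex(real = rnorm(4096), imaginary = rnorm(4096))
  H2 <- buildHankel(x, 2048L)
  expect_identical(dim(H2@entries), c(2048L, 2049L))

  ## anti-diagonal constancy
  set.seed(5)
  x <- complex(real = rnorm(40), imaginary = rnorm(40))
  Hs <- buildHankel(x, 17L)@entries
  for (n in seq_len(40)) {
    i <- pmax(1L, n - ncol(Hs) + 1L):pmin(17L, n)
    vals <- Hs[cbind(i, n - i + 1L)]
    expect_true(all(vals == vals[1]))
  }
})

test_that("rank truncation is the Eckart-Young optimum", {
  set.seed(42)
  ## rank-1 matrix is reproduced at r = 1
  u <- complex(real = rnorm(6), imaginary = rnorm(6))
  v <- complex(real = rnorm(5), imaginary = rnorm(5))
  A <- u %*% t(v)
  expect_lt(relErr(truncateRank(A, 1L), A), 1e-10)

  ## independently coded full SVD (eigendecomposition of the Gram matrix)
  ## gives the optimal residual sqrt(sum of trailing singular values^2)
  A <- matrix(complex(real = rnorm(42), imaginary = rnorm(42)), 6, 7)
  ev <- sort(Re(eigen(Conj(t(A)) %*% A, symmetric = TRUE)$values),
             decreasing = TRUE)
  for (r in c(2L, 4L)) {
    res <- sqrt(sum(Mod(A - truncateRank(A, r))^2))
    expect_equal(res, sqrt(sum(pmax(ev[(r + 1):length(ev)], 0))),
                 tolerance = 1e-10)
  }

  ## r = min(dim): no truncation
  expect_identical(truncateRank(A, 6L), A)
  expect_error(truncateRank(A, 0L), "r must")
  expect_error(truncateRank(A, 7L), "r must")

  ## monotone residual and non-expansive Frobenius norm
  H <- buildHankel(samples(addNoise(synthesizeFID(kLineTable(3), toyAcq(64L)),
                                    0.3, 9)), 32L)
  res <- vapply(1:8, function(r)
    sqrt(sum(Mod(H@entries - truncateRank(H, r)@entries)^2)), numeric(1))
  expect_true(all(diff(res) <= 1e-10))
  for (r in c(1L, 3L, 8L))
    expect_lte(sqrt(sum(Mod(truncateRank(H, r)@entries)^2)),
               sqrt(sum(Mod(H@entries)^2)) + 1e-10)
})

test_that("reconstruction inverts the Hankel embedding and averages anti-diagonals", {
  set.seed(31)
  for (W in c(1L, 2L, 13L, 31L)) {
    x <- complex(real = rnorm(32), imaginary = rnorm(32))
    H <- buildHankel(x, W)
    expect_identical(reconstructFID(H, "concat_first_row_last_col"), x)
    expect_equal(reconstructFID(H, "antidiagonal_mean"), x, tolerance = 1e-15)
  }

  ones <- new("HankelMatrix", entries = matrix(1 + 0i, 2, 3),
              source_length = 4L)
  expect_equal(reconstructFID(ones, "concat_first_row_last_col"),
               rep(1 + 0i, 4))
  expect_equal(reconstructFID(ones, "antidiagonal_mean"), rep(1 + 0i, 4))

  ## anti-diagonal mean minimizes the per-anti-diagonal squared deviation:
  ## brute-force grid search around each mean never finds a better value
  E <- matrix(complex(real = rnorm(12), imaginary = rnorm(12)), 3, 4)
  Hn <- new("HankelMatrix", entries = E, source_length = 6L)
  s <- reconstructFID(Hn, "antidiagonal_mean")
  for (n in 1:6) {
    i <- pmax(1L, n - 3L):pmin(3L, n)
    vals <- E[cbind(i, n - i + 1L)]
    ss <- function(z) sum(Mod(vals - z)^2)
    cand <- s[n] + c(0, 0.05, -0.05, 0.05i, -0.05i, 0.03 + 0.04i)
    expect_true(all(ss(s[n]) <= vapply(cand, ss, numeric(1)) + 1e-12))
  }
})

test_that("low-rank denoising is exact on noiseless low-rank signals", {
  acq <- toyAcq(256L)
  for (K in c(1L, 5L)) {
    fid <- synthesizeFID(kLineTable(K), acq)
    den <- lowrankDenoise(fid, DenoiseParams(r = K))
    expect_lt(relErr(samples(den), samples(fid)), 1e-8)
    expect_identical(provenance(den), "denoised")
    expect_identical(den@meta$denoise_W, 128L)
  }

  ## no-op limit: full rank, no line broadening
  noisy <- addNoise(synthesizeFID(kLineTable(2L), acq), 0.5, 4)
  full <- lowrankDenoise(noisy, DenoiseParams(r = 128L, W = 128L))
  expect_lt(relErr(samples(full), samples(noisy)), 1e-10)

  expect_error(lowrankDenoise(noisy, DenoiseParams(r = 0L)), "r must")
  expect_error(lowrankDenoise(noisy, DenoiseParams(r = 200L)), "r must")
  expect_error(lowrankDenoise(noisy, DenoiseParams(r = 1L, W = 256L)),
               "W must")
})

test_that("rank-1 denoising reduces the error of a noisy single line", {
  acq <- toyAcq(256L)
  tab <- kLineTable(1L)
  gt <- synthesizeFID(tab, acq)
  ## sigma giving a raw-SNR-~5-grade corruption of the unit-amplitude line
  sigma <- 0.25
  better <- vapply(1:100, function(s) {
    noisy <- addNoise(gt, sigma, s)
    den <- lowrankDenoise(noisy, DenoiseParams(r = 1L))
    mean(Mod(samples(den) - samples(gt))^2) <
      mean(Mod(samples(noisy) - samples(gt))^2)
  }, logical(1))
  expect_gte(sum(better), 95)
})

test_that("denoise parameters resolve nucleus-specific defaults", {
  p31 <- addNoise(synthesizeFID(defaultPeakTable("P31"),
                                AcquisitionParams("P31", n_points = 128L)),
                  0.1, 1)
  expect_error(lowrankDenoise(p31), NA)
  den <- lowrankDenoise(p31)
  expect_identical(den@meta$denoise_r, 13L)
  expect_identical(den@meta$denoise_W, 64L)
})
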
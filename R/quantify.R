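## Frequency-domain quantification: FFT spectra, analysis windows, basis
## generation, windowed linear-combination fitting with global nuisance
## parameters, Cramer-Rao lower bounds and the LCModel-convention SNR.

#' Fourier transform an FID into a spectrum
#'
#' Plain DFT with frequencies reordered onto a decreasing ppm axis. Under
#' this convention a decaying exponential at offset \eqn{f} Hz from the
#' carrier produces an absorption-mode Lorentzian peaked at
#' \code{ref_ppm + f / spectrometer_freq} after zero-order phasing.
#' Parseval holds as \eqn{\sum_t |x_t|^2 = \frac{1}{N}\sum_\nu |X_\nu|^2}.
#'
#' @param fid a \linkS4class{FIDSignal}.
#' @return a \linkS4class{Spectrum}.
#' @name toSpectrum
#' @export
setMethod("toSpectrum", "FIDSignal", function(fid) {
  acq <- fid@acq
  N <- acq@n_points
  ord <- .spectrumOrder(N)
  vals <- stats::fft(fid@samples)[ord]
  freq <- rev(.shiftedFreqAxis(N, acq@spectral_width))
  new("Spectrum", values = vals,
      ppm = acq@ref_ppm + freq / acq@spectrometer_freq, acq = acq)
})

#' Standard analysis window for a nucleus
#'
#' \code{-19.5..10} ppm for 31P and \code{0.2..4.0} ppm for 1H, the
#' conventional fitting ranges for brain spectra.
#'
#' @param nucleus \code{"P31"} or \code{"H1"}.
#' @return numeric \code{c(lo_ppm, hi_ppm)}.
#' @export
defaultWindow <- function(nucleus = c("P31", "H1")) {
  nucleus <- match.arg(nucleus)
  if (nucleus == "P31") c(-19.5, 10) else c(0.2, 4.0)
}

#' Indices of a ppm window into a spectrum
#'
#' Returns the contiguous index range of the (decreasing) ppm axis covered
#' by \code{[lo_ppm, hi_ppm]}, boundary bins included.
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param lo_ppm,hi_ppm window bounds, \code{lo_ppm < hi_ppm}.
#' @return integer index vector (increasing; ppm decreasing along it).
#' @export
windowIndices <- function(spectrum, lo_ppm, hi_ppm) {
  stopifnot(is(spectrum, "Spectrum"))
  if (!(lo_ppm < hi_ppm)) stop("window must satisfy lo_ppm < hi_ppm")
  idx <- which(spectrum@ppm >= lo_ppm & spectrum@ppm <= hi_ppm)
  if (length(idx) == 0L)
    stop("window does not overlap the spectral axis")
  seq(min(idx), max(idx))
}

#' Generate a fitting basis from a peak table
#'
#' One noiseless time-domain response per metabolite on the acquisition
#' grid. Within each metabolite the line amplitudes are renormalized to
#' multiplet weights summing to one, so the fitted amplitude of a
#' metabolite is directly comparable to the total amplitude it carries in a
#' ground-truth table.
#'
#' @param table a \linkS4class{PeakTable}.
#' @param acq acquisition grid for the basis.
#' @return a \linkS4class{BasisSet}.
#' @export
makeBasis <- function(table, acq) {
  stopifnot(is(table, "PeakTable"), is(acq, "AcquisitionParams"))
  mets <- metabolites(table)
  fids <- vapply(mets, function(m) {
    sub <- table@lines[table@lines$metabolite == m, , drop = FALSE]
    tot <- sum(sub$amplitude)
    if (tot <= 0)
      stop(sprintf("metabolite %s has zero total amplitude in the table", m))
    sub$amplitude <- sub$amplitude / tot
    synthesizeFID(PeakTable(sub, table@nucleus), acq)@samples
  }, complex(acq@n_points))
  colnames(fids) <- mets
  new("BasisSet", fids = fids, acq = acq, table = table)
}

## Shared geometry of a windowed fit, precomputed once.
.fitContext <- function(fid, basis, window, baseline_degree) {
  acq <- fid@acq
  bacq <- basis@acq
  if (acq@n_points != bacq@n_points ||
      abs(acq@spectral_width - bacq@spectral_width) > 1e-9 ||
      abs(acq@spectrometer_freq - bacq@spectrometer_freq) > 1e-9 ||
      abs(acq@ref_ppm - bacq@ref_ppm) > 1e-9)
    stop("basis and FID are not on the same acquisition grid")
  spec <- toSpectrum(fid)
  win <- windowIndices(spec, window[1], window[2])
  N <- acq@n_points
  ord <- .spectrumOrder(N)
  ppm_w <- spec@ppm[win]
  ## baseline in a normalized window coordinate for conditioning
  u_norm <- if (length(ppm_w) > 1L) {
    2 * (ppm_w - min(ppm_w)) / (max(ppm_w) - min(ppm_w)) - 1
  } else rep(0, length(ppm_w))
  P <- if (baseline_degree >= 0L)
    outer(u_norm, 0:baseline_degree, `^`) else NULL
  list(acq = acq, spec = spec, win = win, spec_idx = ord[win],
       ppm_w = ppm_w, u = ppm_w - acq@ref_ppm, u_norm = u_norm,
       y = spec@values[win],
       tt = (seq_len(N) - 1) / acq@spectral_width, P = P)
}

## Basis spectra on the window for given global shift/damping.
.basisWindow <- function(ctx, basis, shift_hz, damp_hz) {
  mod <- exp((2i * pi * shift_hz - pi * damp_hz) * ctx$tt)
  stats::mvfft(basis@fids * mod)[ctx$spec_idx, , drop = FALSE]
}

## Solve the phased linear subproblem: min ||Y - B a - P c||^2, a >= 0,
## c free, by projecting out the baseline columns then NNLS.
.solveLinear <- function(ctx, Bw, phi) {
  Yph <- ctx$y * exp(-1i * phi)
  yr <- stackReIm(Yph)
  Ar <- stackReIm(Bw)
  if (!is.null(ctx$P)) {
    Pc <- cbind(ctx$P, 1i * ctx$P)          # complex coefficients
    Pr <- stackReIm(Pc)
    qrP <- qr(Pr)
    A1 <- qr.resid(qrP, Ar)
    y1 <- qr.resid(qrP, yr)
    a <- pracma::lsqnonneg(A1, y1)$x
    cr <- qr.coef(qrP, yr - Ar %*% a)
    cr[is.na(cr)] <- 0
    baseline <- as.vector(Pc %*% cr)
    resid <- Yph - as.vector(Bw %*% a) - baseline
  } else {
    a <- pracma::lsqnonneg(Ar, yr)$x
    baseline <- complex(length.out = length(Yph))
    resid <- Yph - as.vector(Bw %*% a)
  }
  list(a = a, baseline = baseline, resid = resid, Yph = Yph,
       ss = sum(Re(resid)^2 + Im(resid)^2))
}

.defaultFitControl <- function(acq) {
  df <- acq@spectral_width / acq@n_points
  list(phi0_bound = 180, phi1_bound = 20,
       shift_bound = 0.1 * acq@spectrometer_freq,   # +/- 0.1 ppm in Hz
       ## zero extra damping must be an interior point (a boundary there
       ## censors the parameter and biases amplitude variances below the
       ## Cramer-Rao bound); mild negative damping = line sharpening
       damp_lower = -10, damp_upper = 30, maxit = 100, factr = 1e7,
       ndeps = c(0.05, 0.02, max(df / 50, 1e-3), 0.05))
}

#' Linear-combination fit of a spectrum
#'
#' Fits, on the analysis window, the model
#' \deqn{S(\nu) = e^{i(\phi_0 + \phi_1 (\nu - \nu_{ref}))}
#'       \left[\sum_m a_m B_m(\nu; \delta f, d) + P(\nu)\right]}
#' where \eqn{B_m} are the basis responses subject to a global frequency
#' shift \eqn{\delta f} and extra Lorentzian damping \eqn{d}, \eqn{P} is a
#' complex polynomial baseline, and phases are in degrees (\eqn{\phi_1} per
#' ppm relative to the carrier). Amplitudes are constrained non-negative
#' (NNLS with the unconstrained baseline projected out); the four nonlinear
#' nuisance parameters are refined by bounded quasi-Newton optimization
#' from zero initialization. Real and imaginary channels are fitted
#' jointly. Deterministic for fixed inputs.
#'
#' Per-metabolite Cramer-Rao lower bounds (\code{\link{computeCRLB}}) and
#' the SNR statistic (\code{\link{estimateSNR}}) are filled in on the
#' returned object.
#'
#' @param fid the \linkS4class{FIDSignal} to quantify.
#' @param basis a \linkS4class{BasisSet} on the same acquisition grid.
#' @param window ppm window \code{c(lo, hi)}; default: the nucleus'
#'   standard analysis window.
#' @param baseline_degree polynomial baseline degree (default 2; -1
#'   disables the baseline).
#' @param fit_nuisance refine the nonlinear nuisance parameters (default
#'   TRUE); when FALSE they are fixed at zero and only the NNLS solve runs.
#' @param crlb compute CRLBs on the result (default TRUE).
#' @param sentinel_threshold relative amplitude below which a metabolite is
#'   reported as not detected (CRLB sentinel 999).
#' @param control list overriding optimizer bounds/steps; see
#'   \code{lowrankMRS:::.defaultFitControl}.
#' @return a \linkS4class{FitResult}.
#' @export
fitSpectrum <- function(fid, basis, window = NULL, baseline_degree = 2,
                        fit_nuisance = TRUE, crlb = TRUE,
                        sentinel_threshold = 1e-8, control = list()) {
  stopifnot(is(fid, "FIDSignal"), is(basis, "BasisSet"))
  window <- window %||% defaultWindow(nucleus(fid))
  baseline_degree <- as.integer(baseline_degree)
  ctrl <- utils::modifyList(.defaultFitControl(fid@acq), control)
  ctx <- .fitContext(fid, basis, window, baseline_degree)

  ## collinearity guard on the unshifted window basis
  B0 <- .basisWindow(ctx, basis, 0, 0)
  nb <- sqrt(colSums(Mod(B0)^2))
  if (any(nb == 0)) stop("basis column with zero energy on the fit window")
  G <- Mod(Conj(t(B0)) %*% B0) / outer(nb, nb)
  diag(G) <- 0
  if (any(G > 1 - 1e-10)) {
    bad <- which(G > 1 - 1e-10, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    pairs <- apply(bad, 1L, function(ij)
      paste(colnames(B0)[ij], collapse = " ~ "))
    stop(sprintf("collinear basis entries on the fit window: %s",
                 paste(unique(pairs), collapse = "; ")))
  }

  objective <- function(theta) {
    phi <- (theta[1] + theta[2] * ctx$u) * pi / 180
    Bw <- if (theta[3] == 0 && theta[4] == 0) B0 else
      .basisWindow(ctx, basis, theta[3], theta[4])
    .solveLinear(ctx, Bw, phi)$ss
  }

  theta <- c(phi0 = 0, phi1 = 0, shift = 0, damp = 0)
  if (fit_nuisance) {
    lower <- c(-ctrl$phi0_bound, -ctrl$phi1_bound, -ctrl$shift_bound,
               ctrl$damp_lower)
    upper <- c(ctrl$phi0_bound, ctrl$phi1_bound, ctrl$shift_bound,
               ctrl$damp_upper)
    opt <- stats::optim(theta, objective, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = ctrl$maxit,
                                       factr = ctrl$factr,
                                       ndeps = ctrl$ndeps))
    theta <- opt$par
  }
  phi <- (theta[1] + theta[2] * ctx$u) * pi / 180
  Bw <- .basisWindow(ctx, basis, theta[3], theta[4])
  sol <- .solveLinear(ctx, Bw, phi)
  a <- stats::setNames(sol$a, metabolites(basis))
  n_w <- length(ctx$y)
  sigma <- sqrt(sum(Re(sol$resid)^2 + Im(sol$resid)^2) / (2 * n_w))

  fit <- new("FitResult",
             amplitudes = a,
             crlb_pct = stats::setNames(rep(NA_real_, length(a)), names(a)),
             phase0_deg = unname(theta[1]),
             phase1_deg_per_ppm = unname(theta[2]),
             shift_hz = unname(theta[3]),
             extra_damping_hz = unname(theta[4]),
             baseline = sol$baseline, residual = sol$resid,
             data_window = sol$Yph,
             window = as.integer(ctx$win), ppm_window = ctx$ppm_w,
             snr = NA_real_, sigma = sigma,
             baseline_degree = baseline_degree,
             fit_nuisance = fit_nuisance)
  fit@snr <- estimateSNR(fit)
  ## CRLBs are undefined for a degenerate (noiseless) residual; left NA
  if (crlb && is.finite(fit@snr) && fit@sigma > 0)
    fit@crlb_pct <- computeCRLB(fit, basis,
                                sentinel_threshold = sentinel_threshold)
  fit
}

#' Cramer-Rao lower bounds of the fitted amplitudes
#'
#' Builds the Fisher information matrix
#' \eqn{F_{jk} = \sigma^{-2} \mathrm{Re} \sum_\nu
#'   (\partial S/\partial\theta_j)^* (\partial S/\partial\theta_k)}
#' over all active parameters (amplitudes, fitted nuisance parameters and
#' baseline coefficients) on the fit window, under white complex Gaussian
#' noise of per-channel SD \eqn{\sigma}, and returns
#' \eqn{100\sqrt{(F^{-1})_{mm}} / a_m} per metabolite -- the percent-SD
#' uncertainty convention of linear-combination fitting. Amplitudes below
#' the detection threshold, and all amplitudes when the Fisher matrix is
#' singular, receive the "not detected" sentinel 999. The bound is exactly
#' proportional to \eqn{\sigma}.
#'
#' @param fit a \linkS4class{FitResult}.
#' @param basis the \linkS4class{BasisSet} used for the fit.
#' @param sigma per-channel noise SD on the spectral window; default: the
#'   fit's residual-based estimate (\code{fit@sigma}). A SD measured over a
#'   signal-free region may be supplied instead.
#' @param sentinel_threshold relative amplitude below which a metabolite is
#'   "not detected".
#' @return named numeric vector of percent SDs (999 = not detected).
#' @export
computeCRLB <- function(fit, basis, sigma = NULL, sentinel_threshold = 1e-8) {
  stopifnot(is(fit, "FitResult"), is(basis, "BasisSet"))
  sigma <- sigma %||% fit@sigma
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be > 0 (degenerate noiseless fit?)")
  a <- fit@amplitudes
  M <- length(a)
  out <- stats::setNames(rep(999, M), names(a))
  amax <- max(a)
  detected <- if (amax > 0) a > sentinel_threshold * amax else rep(FALSE, M)
  if (!any(detected)) {
    warning("no detected metabolites; all CRLBs set to sentinel 999")
    return(out)
  }
  acq <- basis@acq
  N <- acq@n_points
  ord <- .spectrumOrder(N)
  win <- fit@window
  spec_idx <- ord[win]
  ppm_w <- fit@ppm_window
  u <- ppm_w - acq@ref_ppm
  tt <- (seq_len(N) - 1) / acq@spectral_width
  phi <- (fit@phase0_deg + fit@phase1_deg_per_ppm * u) * pi / 180
  eiphi <- exp(1i * phi)
  mod <- exp((2i * pi * fit@shift_hz - pi * fit@extra_damping_hz) * tt)
  Bt <- basis@fids * mod
  Bw <- stats::mvfft(Bt)[spec_idx, , drop = FALSE]
  model_ph <- fit@data_window - fit@residual       # B a + P c, phased frame

  J <- eiphi * Bw[, detected, drop = FALSE]
  if (fit@fit_nuisance) {
    d_phi0 <- 1i * (pi / 180) * eiphi * model_ph
    d_phi1 <- 1i * (pi / 180) * u * eiphi * model_ph
    dB_shift <- stats::mvfft(Bt * (2i * pi * tt))[spec_idx, , drop = FALSE]
    dB_damp <- stats::mvfft(Bt * (-pi * tt))[spec_idx, , drop = FALSE]
    J <- cbind(J, d_phi0, d_phi1,
               eiphi * as.vector(dB_shift %*% a),
               eiphi * as.vector(dB_damp %*% a))
  }
  if (fit@baseline_degree >= 0L) {
    u_norm <- if (length(ppm_w) > 1L) {
      2 * (ppm_w - min(ppm_w)) / (max(ppm_w) - min(ppm_w)) - 1
    } else rep(0, length(ppm_w))
    P <- outer(u_norm, 0:fit@baseline_degree, `^`)
    J <- cbind(J, eiphi * P, 1i * eiphi * P)
  }
  F_ <- Re(Conj(t(J)) %*% J) / sigma^2
  Finv <- tryCatch(solve(F_), error = function(e) NULL)
  idx <- seq_len(sum(detected))
  if (is.null(Finv) || any(!is.finite(diag(Finv)[idx])) ||
      any(diag(Finv)[idx] <= 0)) {
    warning("singular Fisher information; CRLB sentinel 999 reported")
    return(out)
  }
  out[detected] <- 100 * sqrt(diag(Finv)[idx]) / a[detected]
  out
}

#' LCModel-convention signal-to-noise ratio
#'
#' The ratio of the maximum of the real phased spectrum minus the fitted
#' baseline over the analysis window to twice the root-mean-square of the
#' real-channel fit residual. A residual RMS of zero (noiseless,
#' fit-consistent input) yields the \code{+Inf} sentinel.
#'
#' @param fit a \linkS4class{FitResult}.
#' @return the SNR (possibly \code{Inf}).
#' @export
estimateSNR <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  peak <- max(Re(fit@data_window) - Re(fit@baseline))
  rms <- sqrt(mean(Re(fit@residual)^2))
  ## a residual at relative machine scale is a noiseless, fit-consistent
  ## input: report the +Inf sentinel rather than a meaningless huge number
  if (rms == 0 || rms < 1e-12 * max(abs(peak), 1e-300)) return(Inf)
  peak / (2 * rms)
}

#' Concentration ratios relative to a reference metabolite
#'
#' Divides every fitted amplitude by the reference amplitude (conventionally
#' PCr for 31P brain spectra, which then maps to 1.00). Invariant under
#' global amplitude rescaling.
#'
#' @param fit a \linkS4class{FitResult}.
#' @param reference reference metabolite name.
#' @return named numeric vector of ratios.
#' @export
concentrationRatios <- function(fit, reference = "PCr") {
  stopifnot(is(fit, "FitResult"))
  a <- fit@amplitudes
  if (!(reference %in% names(a)))
    stop(sprintf("reference metabolite %s not in the fit", reference))
  if (a[[reference]] <= 0)
    stop(sprintf("reference metabolite %s has zero amplitude", reference))
  a / a[[reference]]
}
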
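#' @import methods
NULL

.NUCLEI <- c("P31", "H1")

#' Acquisition parameters of a single-voxel MRS experiment
#'
#' Holds the sampling grid and spectrometer metadata needed to interpret a
#' time-domain free induction decay (FID): the number of complex points
#' \eqn{N}, the spectral bandwidth in Hz (whose reciprocal is the dwell
#' time), the transmitter frequency in MHz used for the ppm/Hz conversion,
#' the observed nucleus and the ppm value assigned to the carrier (the
#' centre of the spectral window).
#'
#' @slot n_points integer, number of complex samples (\eqn{N \ge 4}).
#' @slot spectral_width numeric, bandwidth in Hz (> 0).
#' @slot spectrometer_freq numeric, transmitter frequency in MHz (> 0).
#' @slot nucleus character, one of \code{"P31"} or \code{"H1"}.
#' @slot ref_ppm numeric, ppm coordinate of the carrier frequency.
#'
#' @examples
#' AcquisitionParams(nucleus = "P31")
#' @export AcquisitionParams
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(
    n_points = "integer",
    spectral_width = "numeric",
    spectrometer_freq = "numeric",
    nucleus = "character",
    ref_ppm = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (length(object@n_points) != 1L || is.na(object@n_points) ||
      object@n_points < 4L)
    msg <- c(msg, "n_points must be a single integer >= 4")
  if (length(object@spectral_width) != 1L || !is.finite(object@spectral_width) ||
      object@spectral_width <= 0)
    msg <- c(msg, "spectral_width must be a single positive number (Hz)")
  if (length(object@spectrometer_freq) != 1L ||
      !is.finite(object@spectrometer_freq) || object@spectrometer_freq <= 0)
    msg <- c(msg, "spectrometer_freq must be a single positive number (MHz)")
  if (length(object@nucleus) != 1L || !(object@nucleus %in% .NUCLEI))
    msg <- c(msg, sprintf("nucleus must be one of: %s",
                          paste(.NUCLEI, collapse = ", ")))
  if (length(object@ref_ppm) != 1L || !is.finite(object@ref_ppm))
    msg <- c(msg, "ref_ppm must be a single finite number")
  if (length(msg)) msg else TRUE
})

## Defaults mirror the 9.4 T acquisitions the simulator emulates:
## 31P whole brain, 4096 points over 16025.64 Hz at 161.98 MHz, carrier on
## PCr (0 ppm); 1H striatum, 2048 points over 4401.41 Hz at 400.13 MHz,
## carrier on water (4.7 ppm).
.ACQ_DEFAULTS <- list(
  P31 = list(n_points = 4096L, spectral_width = 16025.64,
             spectrometer_freq = 161.98, ref_ppm = 0),
  H1 = list(n_points = 2048L, spectral_width = 4401.41,
            spectrometer_freq = 400.13, ref_ppm = 4.7)
)

AcquisitionParams <- function(nucleus = c("P31", "H1"), n_points = NULL,
                              spectral_width = NULL, spectrometer_freq = NULL,
                              ref_ppm = NULL) {
  nucleus <- match.arg(nucleus)
  d <- .ACQ_DEFAULTS[[nucleus]]
  new("AcquisitionParams",
      n_points = as.integer(n_points %||% d$n_points),
      spectral_width = as.numeric(spectral_width %||% d$spectral_width),
      spectrometer_freq = as.numeric(spectrometer_freq %||% d$spectrometer_freq),
      nucleus = nucleus,
      ref_ppm = as.numeric(ref_ppm %||% d$ref_ppm))
}

#' Table of ground-truth resonance lines
#'
#' A \code{PeakTable} lists Lorentzian resonance lines (one or more per
#' metabolite, so multiplets are fixed sub-line groups) with chemical shift
#' in ppm, concentration-proportional amplitude, linewidth (FWHM, Hz) and a
#' per-line phase. It is both the simulator's ground truth and the source
#' of the fitting basis.
#'
#' @slot lines data.frame with columns \code{metabolite}, \code{shift_ppm},
#'   \code{amplitude}, \code{lw_hz}, \code{phase_deg}.
#' @slot nucleus character, \code{"P31"} or \code{"H1"}.
#' @export PeakTable
#' @exportClass PeakTable
setClass("PeakTable",
  representation(lines = "data.frame", nucleus = "character")
)

.PEAK_COLS <- c("metabolite", "shift_ppm", "amplitude", "lw_hz", "phase_deg")

setValidity("PeakTable", function(object) {
  msg <- character()
  if (!all(.PEAK_COLS %in% names(object@lines)))
    msg <- c(msg, sprintf("lines must have columns: %s",
                          paste(.PEAK_COLS, collapse = ", ")))
  else {
    if (any(object@lines$amplitude < 0))
      msg <- c(msg, "all amplitudes must be >= 0")
    if (any(object@lines$lw_hz <= 0))
      msg <- c(msg, "all linewidths must be > 0")
  }
  if (length(object@nucleus) != 1L || !(object@nucleus %in% .NUCLEI))
    msg <- c(msg, "nucleus must be one of P31, H1")
  if (length(msg)) msg else TRUE
})

PeakTable <- function(lines, nucleus) {
  lines <- as.data.frame(lines)
  lines$metabolite <- as.character(lines$metabolite)
  for (col in .PEAK_COLS[-1]) lines[[col]] <- as.numeric(lines[[col]])
  new("PeakTable", lines = lines[, .PEAK_COLS], nucleus = nucleus)
}

#' A complex time-domain FID signal
#'
#' @slot samples complex vector of length \code{nPoints(acq)}.
#' @slot acq an \linkS4class{AcquisitionParams}.
#' @slot provenance character tag: \code{"ground_truth"}, \code{"raw"} or
#'   \code{"denoised"}.
#' @slot meta list of free-form metadata (e.g. denoising parameters used),
#'   carried through file round-trips.
#' @export FIDSignal
#' @exportClass FIDSignal
setClass("FIDSignal",
  representation(samples = "complex", acq = "AcquisitionParams",
                 provenance = "character", meta = "list")
)

setValidity("FIDSignal", function(object) {
  msg <- character()
  if (length(object@samples) != object@acq@n_points)
    msg <- c(msg, "length(samples) must equal acq n_points")
  if (any(!is.finite(Re(object@samples))) || any(!is.finite(Im(object@samples))))
    msg <- c(msg, "all samples must be finite")
  if (length(object@provenance) != 1L)
    msg <- c(msg, "provenance must be a single string")
  if (length(msg)) msg else TRUE
})

FIDSignal <- function(samples, acq, provenance = "raw", meta = list()) {
  new("FIDSignal", samples = as.complex(samples), acq = acq,
      provenance = provenance, meta = meta)
}

#' Parameters of the low-rank denoiser
#'
#' The knobs of the Hankel/truncated-SVD pipeline: the Hankel row dimension
#' \code{W} (default \eqn{\lfloor N/2 \rfloor}), the rank \code{r} (default:
#' the number of metabolites in the matching basis, 13 for 31P and 16 for
#' 1H), the reconstruction mode, and optional exponential line broadening
#' applied before denoising (in Hz; 0 disables).
#'
#' @slot W integer or NA (resolved to \code{floor(N/2)} at use).
#' @slot r integer or NA (resolved from the signal's nucleus at use).
#' @slot recon_mode character, \code{"concat_first_row_last_col"} or
#'   \code{"antidiagonal_mean"}.
#' @slot lb_hz numeric, pre-denoising exponential line broadening (>= 0).
#' @export DenoiseParams
#' @exportClass DenoiseParams
setClass("DenoiseParams",
  representation(W = "integer", r = "integer", recon_mode = "character",
                 lb_hz = "numeric")
)

.RECON_MODES <- c("concat_first_row_last_col", "antidiagonal_mean")

setValidity("DenoiseParams", function(object) {
  msg <- character()
  if (!is.na(object@W) && object@W < 1L)
    msg <- c(msg, "W must be >= 1")
  if (!is.na(object@r) && object@r < 1L)
    msg <- c(msg, "r must be >= 1")
  if (!(object@recon_mode %in% .RECON_MODES))
    msg <- c(msg, sprintf("recon_mode must be one of: %s",
                          paste(.RECON_MODES, collapse = ", ")))
  if (!is.finite(object@lb_hz) || object@lb_hz < 0)
    msg <- c(msg, "lb_hz must be >= 0")
  if (length(msg)) msg else TRUE
})

DenoiseParams <- function(r = NA, W = NA,
                          recon_mode = c("concat_first_row_last_col",
                                         "antidiagonal_mean", "concat", "avg"),
                          lb_hz = 0) {
  recon_mode <- match.arg(recon_mode)
  if (recon_mode == "concat") recon_mode <- "concat_first_row_last_col"
  if (recon_mode == "avg") recon_mode <- "antidiagonal_mean"
  new("DenoiseParams", W = as.integer(W), r = as.integer(r),
      recon_mode = recon_mode, lb_hz = as.numeric(lb_hz))
}

#' Hankel embedding of an FID
#'
#' At construction \code{entries[i, j] = x[i + j - 1]} (constant
#' anti-diagonals); after rank truncation this structural property is
#' intentionally relaxed while the shape and \code{source_length} persist.
#'
#' @slot entries complex matrix of shape \code{W x (N - W + 1)}.
#' @slot source_length integer, the original signal length \code{N}.
#' @exportClass HankelMatrix
setClass("HankelMatrix",
  representation(entries = "matrix", source_length = "integer")
)

setValidity("HankelMatrix", function(object) {
  W <- nrow(object@entries)
  L <- ncol(object@entries)
  if (W + L - 1L != object@source_length)
    return("shape must satisfy nrow + ncol - 1 == source_length")
  TRUE
})

#' Frequency-domain view of an FID
#'
#' Discrete Fourier transform of the FID with a decreasing ppm axis
#' (conventional MRS display order): a decaying exponential at offset
#' \eqn{f} from the carrier appears as an absorption-mode Lorentzian at
#' \code{ref_ppm + f / spectrometer_freq} after zero-order phasing.
#'
#' @slot values complex vector, same length as the source FID.
#' @slot ppm numeric vector, strictly decreasing ppm coordinates.
#' @slot acq the source \linkS4class{AcquisitionParams}.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(values = "complex", ppm = "numeric", acq = "AcquisitionParams")
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@values) != length(object@ppm))
    msg <- c(msg, "values and ppm must have equal length")
  if (length(object@ppm) > 1L && any(diff(object@ppm) >= 0))
    msg <- c(msg, "ppm axis must be strictly decreasing")
  if (length(msg)) msg else TRUE
})

#' Basis set for linear-combination fitting
#'
#' One noiseless unit-total-amplitude time-domain response per metabolite on
#' the acquisition grid, generated from a \linkS4class{PeakTable} with each
#' metabolite's line amplitudes renormalized to stoichiometric multiplet
#' weights summing to one, so a fitted amplitude estimates the metabolite's
#' total amplitude in the table's units.
#'
#' @slot fids complex matrix, \code{N x M}, columns named by metabolite.
#' @slot acq the grid the basis lives on.
#' @slot table the source \linkS4class{PeakTable}.
#' @exportClass BasisSet
setClass("BasisSet",
  representation(fids = "matrix", acq = "AcquisitionParams",
                 table = "PeakTable")
)

#' Result of a linear-combination spectral fit
#'
#' @slot amplitudes named numeric, non-negative metabolite amplitude
#'   estimates.
#' @slot crlb_pct named numeric, Cramer-Rao lower bounds in percent
#'   standard deviation (\code{999} = not detected sentinel).
#' @slot phase0_deg,phase1_deg_per_ppm,shift_hz,extra_damping_hz fitted
#'   global nuisance parameters.
#' @slot baseline complex baseline values on the fit window (phased frame).
#' @slot residual complex residual on the fit window (phased frame).
#' @slot data_window complex phased data on the fit window.
#' @slot window integer indices of the fit window into the spectrum.
#' @slot ppm_window numeric ppm coordinates of the window.
#' @slot snr numeric, LCModel-convention signal-to-noise ratio.
#' @slot sigma numeric, per-channel noise SD estimate on the window
#'   (RMS of the complex residual / sqrt(2)).
#' @slot baseline_degree integer, polynomial degree used (-1 = none).
#' @slot fit_nuisance logical, whether nuisance parameters were optimized.
#' @exportClass FitResult
setClass("FitResult",
  representation(
    amplitudes = "numeric", crlb_pct = "numeric",
    phase0_deg = "numeric", phase1_deg_per_ppm = "numeric",
    shift_hz = "numeric", extra_damping_hz = "numeric",
    baseline = "complex", residual = "complex", data_window = "complex",
    window = "integer", ppm_window = "numeric",
    snr = "numeric", sigma = "numeric",
    baseline_degree = "integer", fit_nuisance = "logical"
  )
)

## ---- show methods ----

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf("AcquisitionParams: %s, N = %d, SW = %.2f Hz, %.2f MHz, ref %.2f ppm\n",
              object@nucleus, object@n_points, object@spectral_width,
              object@spectrometer_freq, object@ref_ppm))
})

setMethod("show", "PeakTable", function(object) {
  cat(sprintf("PeakTable (%s): %d lines, %d metabolites\n", object@nucleus,
              nrow(object@lines), length(unique(object@lines$metabolite))))
  print(utils::head(object@lines, 8))
  if (nrow(object@lines) > 8) cat("  ...\n")
})

setMethod("show", "FIDSignal", function(object) {
  cat(sprintf("FIDSignal [%s]: %d complex points, %s, dwell %.4g s\n",
              object@provenance, length(object@samples), object@acq@nucleus,
              1 / object@acq@spectral_width))
})

setMethod("show", "DenoiseParams", function(object) {
  cat(sprintf("DenoiseParams: W = %s, r = %s, mode = %s, lb = %.1f Hz\n",
              ifelse(is.na(object@W), "N/2", object@W),
              ifelse(is.na(object@r), "auto", object@r),
              object@recon_mode, object@lb_hz))
})

setMethod("show", "HankelMatrix", function(object) {
  cat(sprintf("HankelMatrix: %d x %d (source length %d)\n",
              nrow(object@entries), ncol(object@entries), object@source_length))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %.2f .. %.2f ppm (%s)\n",
              length(object@values), object@ppm[1],
              object@ppm[length(object@ppm)], object@acq@nucleus))
})

setMethod("show", "BasisSet", function(object) {
  cat(sprintf("BasisSet (%s): %d metabolites on N = %d grid\n",
              object@table@nucleus, ncol(object@fids), nrow(object@fids)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %d metabolites, SNR = %.2f, phase0 = %.1f deg\n",
              length(object@amplitudes), object@snr, object@phase0_deg))
  df <- data.frame(amplitude = round(object@amplitudes, 4),
                   crlb_pct = round(object@crlb_pct, 2))
  print(df)
})
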
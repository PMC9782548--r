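#' @include AllClasses.R
NULL

#' Accessors for MRS objects
#'
#' Small accessor generics used across the package instead of direct slot
#' access: number of points, dwell time, spectral width, nucleus, reference
#' ppm, complex samples, provenance tag, metabolite names, fitted
#' amplitudes and CRLB percentages.
#'
#' @param object an object of the relevant class.
#' @return the corresponding scalar or vector.
#' @name accessors
#' @aliases nPoints dwellTime spectralWidth nucleus refPpm samples
#'   provenance metabolites amplitudes crlbPct fittedSNR ppmAxis
#'   spectrumValues
NULL

#' @rdname accessors
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setGeneric("dwellTime", function(object) standardGeneric("dwellTime"))
#' @rdname accessors
#' @export
setGeneric("spectralWidth", function(object) standardGeneric("spectralWidth"))
#' @rdname accessors
#' @export
setGeneric("nucleus", function(object) standardGeneric("nucleus"))
#' @rdname accessors
#' @export
setGeneric("refPpm", function(object) standardGeneric("refPpm"))
#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("crlbPct", function(object) standardGeneric("crlbPct"))
#' @rdname accessors
#' @export
setGeneric("fittedSNR", function(object) standardGeneric("fittedSNR"))
#' @rdname accessors
#' @export
setGeneric("ppmAxis", function(object) standardGeneric("ppmAxis"))
#' @rdname accessors
#' @export
setGeneric("spectrumValues", function(object) standardGeneric("spectrumValues"))

setMethod("nPoints", "AcquisitionParams", function(object) object@n_points)
setMethod("nPoints", "FIDSignal", function(object) object@acq@n_points)
setMethod("dwellTime", "AcquisitionParams",
          function(object) 1 / object@spectral_width)
setMethod("dwellTime", "FIDSignal", function(object) dwellTime(object@acq))
setMethod("spectralWidth", "AcquisitionParams",
          function(object) object@spectral_width)
setMethod("spectralWidth", "FIDSignal",
          function(object) object@acq@spectral_width)
setMethod("nucleus", "AcquisitionParams", function(object) object@nucleus)
setMethod("nucleus", "FIDSignal", function(object) object@acq@nucleus)
setMethod("nucleus", "PeakTable", function(object) object@nucleus)
setMethod("refPpm", "AcquisitionParams", function(object) object@ref_ppm)
setMethod("refPpm", "FIDSignal", function(object) object@acq@ref_ppm)
setMethod("samples", "FIDSignal", function(object) object@samples)
setMethod("provenance", "FIDSignal", function(object) object@provenance)
setMethod("metabolites", "PeakTable",
          function(object) unique(object@lines$metabolite))
setMethod("metabolites", "BasisSet", function(object) colnames(object@fids))
setMethod("metabolites", "FitResult", function(object) names(object@amplitudes))
setMethod("amplitudes", "FitResult", function(object) object@amplitudes)
setMethod("crlbPct", "FitResult", function(object) object@crlb_pct)
setMethod("fittedSNR", "FitResult", function(object) object@snr)
setMethod("ppmAxis", "Spectrum", function(object) object@ppm)
setMethod("spectrumValues", "Spectrum", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("acquisition", function(object) standardGeneric("acquisition"))
setMethod("acquisition", "FIDSignal", function(object) object@acq)
setMethod("acquisition", "Spectrum", function(object) object@acq)
setMethod("acquisition", "BasisSet", function(object) object@acq)

#' @rdname accessors
#' @export
setGeneric("peakLines", function(object) standardGeneric("peakLines"))
setMethod("peakLines", "PeakTable", function(object) object@lines)
setMethod("peakLines", "BasisSet", function(object) object@table@lines)

setMethod("length", "FIDSignal", function(x) length(x@samples))

## ---- operation generics ----

#' @rdname apodize
#' @export
setGeneric("apodize", function(fid, lb_hz) standardGeneric("apodize"))

#' @rdname buildHankel
#' @export
setGeneric("buildHankel", function(fid, W) standardGeneric("buildHankel"))

#' @rdname truncateRank
#' @export
setGeneric("truncateRank", function(H, r) standardGeneric("truncateRank"))

#' @rdname reconstructFID
#' @export
setGeneric("reconstructFID",
  function(H, mode = c("concat_first_row_last_col", "antidiagonal_mean"),
           acq = NULL, meta = list())
    standardGeneric("reconstructFID"))

#' @rdname lowrankDenoise
#' @export
setGeneric("lowrankDenoise",
  function(fid, params = DenoiseParams()) standardGeneric("lowrankDenoise"))

#' @rdname toSpectrum
#' @export
setGeneric("toSpectrum", function(fid) standardGeneric("toSpectrum"))
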
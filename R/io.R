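## File formats: the canonical columnar FID text format (bit-exact round
## trip), peak-table CSV, comparison-table export, YAML experiment
## configuration, and a minimal single-voxel NIfTI-MRS export.

.FID_HEADER_KEYS <- c("n_points", "spectral_width_hz", "spectrometer_freq_mhz",
                      "nucleus", "ref_ppm", "provenance")

#' Write an FID to a file
#'
#' The canonical \code{"columnar_text"} format is a plain-text block of
#' \code{# key: value} header lines (acquisition metadata, provenance and
#' any scalar entries of \code{meta}) followed by
#' \code{index,time_s,real,imag} rows at full double precision, so that
#' \code{\link{readFID}} round-trips samples and metadata bit-exactly.
#' \code{"nifti_mrs"} writes a minimal single-voxel NIfTI-MRS-style file
#' (complex 1x1x1xN image, dwell time in the fourth pixdim, JSON metadata
#' in a NIfTI header extension); requires the RNifti and jsonlite
#' packages.
#'
#' @param fid a \linkS4class{FIDSignal}.
#' @param path output file path.
#' @param format \code{"columnar_text"} or \code{"nifti_mrs"}.
#' @return \code{path}, invisibly.
#' @export
writeFID <- function(fid, path, format = c("columnar_text", "nifti_mrs")) {
  stopifnot(is(fid, "FIDSignal"))
  format <- match.arg(format)
  if (format == "nifti_mrs") return(.writeFIDNifti(fid, path))
  acq <- fid@acq
  num <- function(v) sprintf("%.17g", v)
  header <- c(
    paste0("# n_points: ", acq@n_points),
    paste0("# spectral_width_hz: ", num(acq@spectral_width)),
    paste0("# spectrometer_freq_mhz: ", num(acq@spectrometer_freq)),
    paste0("# nucleus: ", acq@nucleus),
    paste0("# ref_ppm: ", num(acq@ref_ppm)),
    paste0("# provenance: ", fid@provenance))
  scalars <- Filter(function(v) is.atomic(v) && length(v) == 1L, fid@meta)
  for (k in names(scalars)) {
    v <- scalars[[k]]
    header <- c(header, paste0("# meta_", k, ": ",
                               if (is.numeric(v)) num(v) else as.character(v)))
  }
  idx <- seq_len(acq@n_points) - 1L
  rows <- paste(idx, num(idx / acq@spectral_width),
                num(Re(fid@samples)), num(Im(fid@samples)), sep = ",")
  writeLines(c(header, "index,time_s,real,imag", rows), path)
  invisible(path)
}

#' Read an FID from a file
#'
#' Counterpart of \code{\link{writeFID}}. Missing header keys and a sample
#' count differing from the declared \code{n_points} are errors.
#'
#' @param path input file path.
#' @param format file format; default guesses \code{"nifti_mrs"} for
#'   \code{.nii}/\code{.nii.gz} paths and \code{"columnar_text"} otherwise.
#' @return a \linkS4class{FIDSignal}.
#' @export
readFID <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.nii(\\.gz)?$", path)) "nifti_mrs" else "columnar_text")
  format <- match.arg(format, c("columnar_text", "nifti_mrs"))
  if (format == "nifti_mrs") return(.readFIDNifti(path))
  lines <- readLines(path)
  is_head <- grepl("^# ", lines)
  header <- lines[is_head]
  kv <- regmatches(header, regexec("^# ([^:]+): (.*)$", header))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  missing <- setdiff(.FID_HEADER_KEYS, keys)
  if (length(missing))
    stop(sprintf("missing FID header key(s): %s",
                 paste(missing, collapse = ", ")))
  get <- function(k) vals[match(k, keys)]
  acq <- new("AcquisitionParams",
             n_points = as.integer(get("n_points")),
             spectral_width = as.numeric(get("spectral_width_hz")),
             spectrometer_freq = as.numeric(get("spectrometer_freq_mhz")),
             nucleus = get("nucleus"),
             ref_ppm = as.numeric(get("ref_ppm")))
  validObject(acq)
  meta <- list()
  for (j in which(startsWith(keys, "meta_"))) {
    v <- vals[j]
    vn <- suppressWarnings(as.numeric(v))
    meta[[sub("^meta_", "", keys[j])]] <- if (is.na(vn)) v else vn
  }
  body <- lines[!is_head]
  if (length(body) < 1L || body[1] != "index,time_s,real,imag")
    stop("malformed FID file: missing column header line")
  dat <- utils::read.csv(text = body[-1], header = FALSE,
                         col.names = c("index", "time_s", "real", "imag"),
                         colClasses = "numeric")
  if (nrow(dat) != acq@n_points)
    stop(sprintf("FID length mismatch: header declares %d points, file has %d",
                 acq@n_points, nrow(dat)))
  FIDSignal(complex(real = dat$real, imaginary = dat$imag), acq,
            provenance = get("provenance"), meta = meta)
}

.requireNifti <- function() {
  if (!requireNamespace("RNifti", quietly = TRUE) ||
      !requireNamespace("jsonlite", quietly = TRUE))
    stop("NIfTI-MRS support requires the RNifti and jsonlite packages")
}

.writeFIDNifti <- function(fid, path) {
  .requireNifti()
  acq <- fid@acq
  arr <- array(fid@samples, dim = c(1L, 1L, 1L, acq@n_points))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, 1 / acq@spectral_width))
  hdr <- list(SpectrometerFrequency = acq@spectrometer_freq,
              ResonantNucleus = acq@nucleus,
              ReferencePpm = acq@ref_ppm,
              Provenance = fid@provenance)
  RNifti::extension(img, 44L) <-
    as.character(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA))
  RNifti::writeNifti(img, path)
  invisible(path)
}

.readFIDNifti <- function(path) {
  .requireNifti()
  img <- RNifti::readNifti(path)
  ext <- RNifti::extension(img, 44L, mode = "raw")
  if (is.null(ext)) stop("missing NIfTI-MRS metadata extension (ecode 44)")
  ext <- as.raw(ext)
  hdr <- jsonlite::fromJSON(rawToChar(ext[ext != as.raw(0L)]))
  samp <- as.complex(img[1, 1, 1, ])
  dwell <- RNifti::pixdim(img)[4]
  acq <- new("AcquisitionParams", n_points = length(samp),
             spectral_width = 1 / dwell,
             spectrometer_freq = as.numeric(hdr$SpectrometerFrequency),
             nucleus = as.character(hdr$ResonantNucleus),
             ref_ppm = as.numeric(hdr$ReferencePpm %||% 0))
  validObject(acq)
  FIDSignal(samp, acq, provenance = as.character(hdr$Provenance %||% "raw"))
}

#' Read/write peak tables
#'
#' CSV with a \code{# nucleus:} header line and columns
#' \code{metabolite, shift_ppm, amplitude, lw_hz, phase_deg}.
#'
#' @param table a \linkS4class{PeakTable}.
#' @param path file path.
#' @return \code{writePeakTable}: \code{path} invisibly;
#'   \code{readPeakTable}: a \linkS4class{PeakTable}.
#' @export
writePeakTable <- function(table, path) {
  stopifnot(is(table, "PeakTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nucleus: ", table@nucleus), con)
  utils::write.csv(table@lines, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePeakTable
#' @export
readPeakTable <- function(path) {
  lines <- readLines(path)
  nuc_line <- grep("^# nucleus:", lines, value = TRUE)
  if (length(nuc_line) != 1L)
    stop("peak table file must have exactly one '# nucleus:' header line")
  nucleus <- trimws(sub("^# nucleus:", "", nuc_line))
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
  PeakTable(dat, nucleus)
}

#' Write a comparison table
#'
#' @param comparison output of \code{\link{summarizeExperiment}}.
#' @param path output path.
#' @param format \code{"tsv"} (machine-readable) or \code{"text"}
#'   (human-readable aligned table).
#' @return \code{path}, invisibly.
#' @export
writeComparisonTable <- function(comparison, path, format = c("tsv", "text")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(comparison), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    writeLines(formatComparisonTable(comparison), path)
  }
  invisible(path)
}

## ---- YAML experiment configuration ----

.CONFIG_SECTIONS <- list(
  acquisition = c("nucleus", "n_points", "spectral_width_hz",
                  "spectrometer_freq_mhz", "ref_ppm"),
  peak_table = c("builtin", "path", "stroke", "stroke_global_scale",
                 "stroke_lac_factor"),
  noise = c("sigma", "target_snr", "n_probe"),
  denoise = c("rank", "W", "mode", "lb_hz"),
  fit = c("window_lo_ppm", "window_hi_ppm", "baseline_degree",
          "fit_nuisance", "reference"),
  experiment = c("n_replicates", "master_seed", "null_mode")
)

#' Read and validate a YAML experiment configuration
#'
#' Sections \code{acquisition}, \code{peak_table}, \code{noise},
#' \code{denoise}, \code{fit} and \code{experiment}; unknown sections or
#' keys are rejected before any computation. Returns the validated
#' \code{\link{experimentConfig}} together with replicate count, master
#' seed and a stable configuration hash (MD5 of the canonicalized
#' content).
#'
#' @param path YAML file path.
#' @return list with elements \code{config}, \code{n_replicates},
#'   \code{master_seed}, \code{hash}.
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(.CONFIG_SECTIONS))
  if (length(unknown))
    stop(sprintf("unknown config section(s): %s",
                 paste(unknown, collapse = ", ")))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), .CONFIG_SECTIONS[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in config section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  a <- raw$acquisition %||% list()
  if (is.null(a$nucleus)) stop("config: acquisition$nucleus is required")
  acq <- AcquisitionParams(a$nucleus, n_points = a$n_points,
                           spectral_width = a$spectral_width_hz,
                           spectrometer_freq = a$spectrometer_freq_mhz,
                           ref_ppm = a$ref_ppm)
  p <- raw$peak_table %||% list()
  table <- if (!is.null(p$path)) readPeakTable(p$path)
           else defaultPeakTable(p$builtin %||% a$nucleus)
  if (isTRUE(p$stroke))
    table <- strokePeakTable(table,
                             global_scale = p$stroke_global_scale %||% 0.15,
                             lac_factor = p$stroke_lac_factor %||% 3)
  d <- raw$denoise %||% list()
  den <- DenoiseParams(r = d$rank %||% NA, W = d$W %||% NA,
                       recon_mode = d$mode %||% "concat_first_row_last_col",
                       lb_hz = d$lb_hz %||% 0)
  f <- raw$fit %||% list()
  window <- if (!is.null(f$window_lo_ppm) || !is.null(f$window_hi_ppm)) {
    c(f$window_lo_ppm %||% defaultWindow(nucleus(acq))[1],
      f$window_hi_ppm %||% defaultWindow(nucleus(acq))[2])
  } else NULL
  nz <- raw$noise %||% list()
  e <- raw$experiment %||% list()
  cfg <- experimentConfig(table, acq, sigma = nz$sigma,
                          target_snr = nz$target_snr, denoise = den,
                          window = window,
                          baseline_degree = f$baseline_degree %||% 2,
                          fit_nuisance = f$fit_nuisance %||% TRUE,
                          reference = f$reference,
                          null_mode = e$null_mode %||% "none",
                          n_probe = nz$n_probe %||% 6)
  list(config = cfg,
       n_replicates = as.integer(e$n_replicates %||% 10L),
       master_seed = as.integer(e$master_seed %||% 1L),
       hash = configHash(raw))
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical YAML serialization; identical configurations give
#' identical hashes regardless of file formatting.
#'
#' @param config a parsed configuration list.
#' @return hex MD5 string.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a fit result as a flat table
#'
#' Columns \code{metabolite, amplitude, crlb_pct} and, when a reference is
#' given, \code{ratio_to_ref}; fitted nuisance parameters, SNR and sigma
#' are recorded as \code{# key: value} header lines.
#'
#' @param fit a \linkS4class{FitResult}.
#' @param path output path.
#' @param reference optional reference metabolite for ratios.
#' @return \code{path}, invisibly.
#' @export
writeFitResult <- function(fit, path, reference = NULL) {
  stopifnot(is(fit, "FitResult"))
  df <- data.frame(metabolite = names(fit@amplitudes),
                   amplitude = unname(fit@amplitudes),
                   crlb_pct = unname(fit@crlb_pct))
  if (!is.null(reference))
    df$ratio_to_ref <- unname(concentrationRatios(fit, reference))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# snr: %.6g", fit@snr),
               sprintf("# sigma: %.6g", fit@sigma),
               sprintf("# phase0_deg: %.6g", fit@phase0_deg),
               sprintf("# phase1_deg_per_ppm: %.6g", fit@phase1_deg_per_ppm),
               sprintf("# shift_hz: %.6g", fit@shift_hz),
               sprintf("# extra_damping_hz: %.6g", fit@extra_damping_hz)),
             con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
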
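## Seeded Monte-Carlo raw-vs-denoised experiments and paired comparison
## tables: mean +/- SD per condition, percent difference from raw, paired
## t-tests with not-detected (999) sentinel filtering.

#' Build and validate an experiment configuration
#'
#' Bundles the simulation, denoising and fitting settings of a
#' raw-vs-denoised Monte-Carlo experiment. Either \code{sigma} (noise SD
#' per channel) or \code{target_snr} (calibrated at run time) must be
#' given.
#'
#' @param table ground-truth \linkS4class{PeakTable}.
#' @param acq \linkS4class{AcquisitionParams}.
#' @param sigma noise SD per channel, or NULL to calibrate.
#' @param target_snr target mean raw SNR for calibration.
#' @param denoise a \linkS4class{DenoiseParams}.
#' @param window fit window in ppm (default: nucleus standard).
#' @param baseline_degree baseline polynomial degree.
#' @param fit_nuisance refine nonlinear nuisance parameters in fits.
#' @param reference reference metabolite for concentration ratios (NULL:
#'   report raw amplitudes only).
#' @param null_mode \code{"none"} (actual denoising),
#'   \code{"independent_noise"} (null pipeline: the second arm is an
#'   independent noise realization of the same ground truth, for type-I
#'   error calibration) or \code{"identity"} (second arm is the identical
#'   raw signal; all paired differences are exactly zero).
#' @param n_probe probe realizations per sigma evaluation when calibrating.
#' @param fit_control optimizer control overrides for all fits.
#' @return a validated config list (class \code{mrs_experiment_config}).
#' @export
experimentConfig <- function(table, acq, sigma = NULL, target_snr = NULL,
                             denoise = DenoiseParams(), window = NULL,
                             baseline_degree = 2, fit_nuisance = TRUE,
                             reference = NULL,
                             null_mode = c("none", "independent_noise",
                                           "identity"),
                             n_probe = 6, fit_control = list()) {
  stopifnot(is(table, "PeakTable"), is(acq, "AcquisitionParams"),
            is(denoise, "DenoiseParams"))
  null_mode <- match.arg(null_mode)
  if (is.null(sigma) && is.null(target_snr))
    stop("one of sigma or target_snr must be given")
  if (!is.null(sigma) && (!is.finite(sigma) || sigma < 0))
    stop("sigma must be >= 0")
  window <- window %||% defaultWindow(nucleus(table))
  if (!is.null(reference) && !(reference %in% metabolites(table)))
    stop(sprintf("reference metabolite %s not in the table", reference))
  structure(list(table = table, acq = acq, sigma = sigma,
                 target_snr = target_snr, denoise = denoise, window = window,
                 baseline_degree = baseline_degree,
                 fit_nuisance = fit_nuisance, reference = reference,
                 null_mode = null_mode, n_probe = n_probe,
                 fit_control = fit_control),
            class = "mrs_experiment_config")
}

.fitMetrics <- function(fit, reference) {
  a <- fit@amplitudes
  vals <- c(snr = fit@snr,
            stats::setNames(fit@crlb_pct, paste0("crlb_", names(a))),
            stats::setNames(a, paste0("amp_", names(a))))
  if (!is.null(reference)) {
    ratios <- tryCatch(concentrationRatios(fit, reference),
                       error = function(e) {
                         stats::setNames(rep(NA_real_, length(a)), names(a))
                       })
    vals <- c(vals, stats::setNames(ratios, paste0("ratio_", names(a))))
  }
  vals
}

#' Run a seeded raw-vs-denoised Monte-Carlo experiment
#'
#' For each replicate the ground truth is corrupted with an independent
#' seeded noise realization, the noisy signal is fitted (condition
#' \code{"raw"}), the same noisy signal is low-rank denoised and fitted
#' again (condition \code{"denoised"}), and SNR, per-metabolite CRLB,
#' amplitude and optional concentration-ratio metrics are recorded for
#' both arms. Fully reproducible from \code{master_seed} (one derived seed
#' per replicate, recorded in the output). A failing replicate is logged
#' and excluded rather than aborting the run.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param n_replicates number of paired replicates (>= 2).
#' @param master_seed integer master seed.
#' @return a list of class \code{mrs_experiment} with elements
#'   \code{records} (long data.frame: replicate, seed, condition, metric,
#'   value), \code{sigma}, \code{config} and \code{errors}.
#' @export
runExperiment <- function(config, n_replicates, master_seed = 1L) {
  stopifnot(inherits(config, "mrs_experiment_config"), n_replicates >= 2)
  gt <- synthesizeFID(config$table, config$acq)
  basis <- makeBasis(config$table, config$acq)
  sigma <- config$sigma
  if (is.null(sigma)) {
    sigma <- calibrateSigma(config$table, config$acq, config$target_snr,
                            n_probe = config$n_probe,
                            rng_seed = deriveSeed(master_seed, 999983L),
                            window = config$window,
                            baseline_degree = config$baseline_degree,
                            fit_nuisance = config$fit_nuisance)
    sigma <- as.numeric(sigma)
  }
  fitOne <- function(fid) {
    fitSpectrum(fid, basis, window = config$window,
                baseline_degree = config$baseline_degree,
                fit_nuisance = config$fit_nuisance,
                control = config$fit_control)
  }
  rows <- list()
  errors <- list()
  for (i in seq_len(n_replicates)) {
    seed_i <- deriveSeed(master_seed, i)
    rec <- tryCatch({
      noisy <- addNoise(gt, sigma, seed_i)
      raw_fit <- fitOne(noisy)
      second <- switch(config$null_mode,
        none = lowrankDenoise(noisy, config$denoise),
        independent_noise = addNoise(gt, sigma,
                                     deriveSeed(master_seed, 500000L + i)),
        identity = noisy)
      den_fit <- fitOne(second)
      raw_m <- .fitMetrics(raw_fit, config$reference)
      den_m <- .fitMetrics(den_fit, config$reference)
      data.frame(
        replicate = i, seed = seed_i,
        condition = rep(c("raw", "denoised"),
                        times = c(length(raw_m), length(den_m))),
        metric = c(names(raw_m), names(den_m)),
        value = unname(c(raw_m, den_m)),
        row.names = NULL)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      errors[[length(errors) + 1L]] <-
        list(replicate = i, seed = seed_i, message = conditionMessage(rec))
    } else {
      rows[[length(rows) + 1L]] <- rec
    }
  }
  if (length(errors))
    warning(sprintf("%d replicate(s) failed and were excluded",
                    length(errors)))
  structure(list(records = do.call(rbind, rows), sigma = sigma,
                 config = config, errors = errors),
            class = "mrs_experiment")
}

#' Paired t-test with not-detected sentinel filtering
#'
#' Two-sided paired t-test on \code{denoised - raw} differences. Pairs in
#' which either arm is missing, non-finite or equal to the not-detected
#' sentinel (999) are removed first. Degenerate cases follow the reporting
#' conventions of paired metabolite tables: fewer than two surviving
#' pairs, or all differences exactly zero, give \code{NA} (rendered NaN);
#' zero variance with a nonzero mean gives \code{NA} with a warning.
#'
#' @param raw_values,denoised_values equal-length numeric vectors, paired
#'   by position.
#' @param sentinel the not-detected code (default 999).
#' @return the p-value, or \code{NA_real_}.
#' @export
pairedTTest <- function(raw_values, denoised_values, sentinel = 999) {
  if (length(raw_values) != length(denoised_values))
    stop("paired vectors must have equal length")
  ok <- is.finite(raw_values) & is.finite(denoised_values) &
    raw_values != sentinel & denoised_values != sentinel
  x <- raw_values[ok]
  y <- denoised_values[ok]
  if (length(x) < 2L) return(NA_real_)
  d <- y - x
  if (all(d == 0)) return(NA_real_)
  if (stats::sd(d) == 0) {
    warning("zero-variance nonzero paired differences; p-value undefined")
    return(NA_real_)
  }
  stats::t.test(y, x, paired = TRUE)$p.value
}

#' Percent difference from the raw condition
#'
#' \code{100 * (mean_denoised - mean_raw) / mean_raw}, the convention of
#' raw-vs-denoised summary tables; always recomputed from the means.
#'
#' @param mean_raw,mean_denoised condition means.
#' @return percent difference.
#' @export
pctDiff <- function(mean_raw, mean_denoised) {
  100 * (mean_denoised - mean_raw) / mean_raw
}

#' Summarize an experiment into a paired comparison table
#'
#' Per metric: the paired replicates surviving sentinel filtering
#' (pairwise deletion, mirroring how not-detected values are removed
#' before statistics), mean and sample SD (n-1 denominator) per condition,
#' percent difference of the means from raw, the paired t-test p-value and
#' a significance flag at \code{alpha}.
#'
#' @param experiment an \code{mrs_experiment} (or its \code{records}
#'   data.frame).
#' @param alpha significance level (default 0.05).
#' @param sentinel not-detected code (default 999).
#' @return data.frame with one row per metric: \code{metric, n_pairs,
#'   mean_raw, sd_raw, mean_denoised, sd_denoised, pct_diff, p_value,
#'   significant}.
#' @export
summarizeExperiment <- function(experiment, alpha = 0.05, sentinel = 999) {
  records <- if (inherits(experiment, "mrs_experiment"))
    experiment$records else experiment
  stopifnot(is.data.frame(records),
            all(c("replicate", "condition", "metric", "value") %in%
                  names(records)))
  out <- lapply(unique(records$metric), function(m) {
    sub <- records[records$metric == m, ]
    raw <- sub[sub$condition == "raw", ]
    den <- sub[sub$condition == "denoised", ]
    reps <- intersect(raw$replicate, den$replicate)
    x <- raw$value[match(reps, raw$replicate)]
    y <- den$value[match(reps, den$replicate)]
    ok <- is.finite(x) & is.finite(y) & x != sentinel & y != sentinel
    x <- x[ok]
    y <- y[ok]
    p <- pairedTTest(x, y, sentinel = sentinel)
    if (length(x) == 0L) {
      data.frame(metric = m, n_pairs = 0L, mean_raw = NA_real_,
                 sd_raw = NA_real_, mean_denoised = NA_real_,
                 sd_denoised = NA_real_, pct_diff = NA_real_,
                 p_value = NA_real_, significant = FALSE)
    } else {
      data.frame(metric = m, n_pairs = length(x),
                 mean_raw = mean(x), sd_raw = stats::sd(x),
                 mean_denoised = mean(y), sd_denoised = stats::sd(y),
                 pct_diff = pctDiff(mean(x), mean(y)),
                 p_value = p,
                 significant = is.finite(p) && p < alpha)
    }
  })
  res <- do.call(rbind, out)
  class(res) <- c("mrs_comparison", "data.frame")
  res
}

#' Render a comparison table as aligned text
#'
#' Fixed two-decimal formatting of means, SDs and percentages, with
#' significance marked by an asterisk and undefined p-values rendered as
#' NaN.
#'
#' @param comparison output of \code{\link{summarizeExperiment}}.
#' @return character vector of lines.
#' @export
formatComparisonTable <- function(comparison) {
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.2f", v), "NaN")
  fmtp <- function(p, sig) ifelse(is.finite(p),
                                  paste0(sprintf("%.4f", p),
                                         ifelse(sig, " *", "")), "NaN")
  body <- data.frame(
    Metric = comparison$metric,
    Raw = paste(fmt(comparison$mean_raw), "+/-", fmt(comparison$sd_raw)),
    Denoised = paste(fmt(comparison$mean_denoised), "+/-",
                     fmt(comparison$sd_denoised)),
    `PctDiff` = fmt(comparison$pct_diff),
    `p` = fmtp(comparison$p_value, comparison$significant),
    check.names = FALSE)
  utils::capture.output(print(body, row.names = FALSE))
}
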
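# End-to-end pipeline driver: raw acquisitions -> truncation/CR removal ->
# background subtraction + calibration -> baseline removal -> SNV, with
# batch averaging and a quality report.

known_stage_keys <- c("truncate", "crfilter", "background", "irf", "xaxis",
                      "baseline", "snv")

#' Declarative pipeline configuration
#'
#' Stages run in the fixed dependency order: truncate, crfilter,
#' (accumulation combination, implicit), background, irf, xaxis, baseline,
#' snv. Truncation and background removal are optional (not every dataset
#' has a filter-transition region or a stored background); baseline
#' removal must precede SNV. Unknown stage keys are rejected.
#'
#' @param truncate `NULL` to skip, or `list(cut_low =, cut_high =)`.
#' @param crfilter `NULL` to skip, or `list(method = "multi"|"single",
#'   threshold_mads =, widen_px =)` (missing fields take the filter
#'   defaults).
#' @param background `TRUE` to subtract each acquisition's own stored
#'   background, `FALSE`/`NULL` to skip.
#' @param irf `NULL` to skip, or an [irf_model()] applied after combining.
#' @param xaxis `NULL` to skip, or `list(cal = shift_calibration or NULL,
#'   grid = numeric)` resampling all spectra onto the common grid.
#' @param baseline `NULL` to skip, or `list(algorithm =, ...)` with
#'   algorithm-specific tuning passed to [remove_baseline()].
#' @param snv Logical: apply [snv()] as the final stage.
#' @param keep_stages Logical: retain every intermediate spectrum in the
#'   result's `artifacts` field.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(truncate = NULL, crfilter = list(),
                            background = FALSE, irf = NULL, xaxis = NULL,
                            baseline = list(algorithm = "bubblefill"),
                            snv = TRUE, keep_stages = FALSE) {
  cfg <- list(truncate = truncate, crfilter = crfilter,
              background = isTRUE(background), irf = irf, xaxis = xaxis,
              baseline = baseline, snv = isTRUE(snv),
              keep_stages = isTRUE(keep_stages))
  if (!is.null(truncate)) {
    bad <- setdiff(names(truncate), c("cut_low", "cut_high"))
    if (length(bad)) rp_value_error(paste("unknown truncate keys:",
                                          paste(bad, collapse = ", ")))
  }
  if (!is.null(crfilter)) {
    bad <- setdiff(names(crfilter), c("method", "threshold_mads", "widen_px"))
    if (length(bad)) rp_value_error(paste("unknown crfilter keys:",
                                          paste(bad, collapse = ", ")))
  }
  if (!is.null(baseline) && is.null(baseline$algorithm))
    rp_value_error("baseline stage needs an 'algorithm' key")
  if (isTRUE(snv) && is.null(baseline))
    message("note: SNV will be applied to baseline-contaminated spectra (no baseline stage)")
  structure(cfg, class = "pipeline_config")
}

stage_error <- function(stage, id, e) {
  rp_stop(sprintf("stage '%s' failed for spectrum %s: %s", stage, id,
                  conditionMessage(e)),
          "ramanpipe_stage_error")
}

#' Run the processing pipeline on a batch
#'
#' Applies the configured stages to every input, collects the final batch
#' (on a common axis when the `xaxis` stage is enabled), and computes the
#' batch average spectrum with its per-bin standard deviation. Stage
#' composition is exactly equivalent to calling the module functions by
#' hand in the same order; there is no hidden state.
#'
#' @param config A [pipeline_config()].
#' @param inputs A list of [raw_acquisition()] / [spectrum()] objects, or
#'   file paths readable by [read_spectra()].
#' @return List with `processed` (list of final spectra), `average` and
#'   `sd` (batch statistics, when the batch shares one axis), `fits`
#'   (baseline fits, if that stage ran), `quality` (ASSI tier report for
#'   batches of >= 5), and `artifacts` (per-stage intermediates when
#'   `keep_stages = TRUE`).
#' @export
run_pipeline <- function(config, inputs) {
  if (!inherits(config, "pipeline_config"))
    rp_value_error("config must be a pipeline_config")
  if (is.character(inputs))
    inputs <- unlist(lapply(inputs, read_spectra), recursive = FALSE)
  if (is_spectrum(inputs) || is_acquisition(inputs)) inputs <- list(inputs)
  processed <- vector("list", length(inputs))
  fits <- vector("list", length(inputs))
  artifacts <- if (config$keep_stages) vector("list", length(inputs)) else NULL
  for (i in seq_along(inputs)) {
    x <- inputs[[i]]
    keep <- list()
    run_stage <- function(stage, expr) {
      out <- tryCatch(expr, error = function(e) stage_error(stage, i, e))
      if (config$keep_stages) keep[[stage]] <<- out
      out
    }
    if (!is.null(config$truncate)) {
      x <- run_stage("truncate", truncate_pixels(
        x, cut_low = config$truncate$cut_low %||% 0L,
        cut_high = config$truncate$cut_high))
    }
    if (!is.null(config$crfilter)) {
      cf <- config$crfilter
      method <- cf$method %||%
        (if (is_acquisition(x) && nrow(x$accumulations) >= 3L) "multi"
         else "single")
      x <- run_stage("crfilter", {
        if (method == "multi" && is_acquisition(x))
          crfilter_multi(x, threshold_mads = cf$threshold_mads %||% 7,
                         widen_px = cf$widen_px %||% 2L)
        else if (is_acquisition(x)) x  # single-accumulation: filter later
        else crfilter_single(x, threshold_mads = cf$threshold_mads %||% 10,
                             widen_px = cf$widen_px %||% 2L)
      })
    }
    bg_source <- if (is_acquisition(x)) x else NULL
    if (is_acquisition(x)) x <- run_stage("combine", combine_accumulations(x))
    if (config$background) {
      if (is.null(bg_source) || is.null(bg_source$background))
        stage_error("background", i, simpleError("no background available"))
      bg <- bg_source$background
      if (!is.null(config$crfilter))
        bg <- crfilter_single(spectrum(bg))$intensity
      x <- run_stage("background", subtract_background(
        x, bg, exposure_acq = bg_source$exposure_acq,
        exposure_bg = bg_source$exposure_bg))
    }
    if (!is.null(config$irf)) x <- run_stage("irf", apply_irf(x, config$irf))
    if (!is.null(config$xaxis)) {
      x <- run_stage("xaxis", resample_common_axis(
        x, config$xaxis$cal, config$xaxis$grid))
    }
    if (!is.null(config$baseline)) {
      fit <- run_stage("baseline", do.call(remove_baseline, c(
        list(x), config$baseline)))
      fits[[i]] <- fit
      x <- spectrum(fit$raman, axis = x$axis, axis_kind = x$axis_kind,
                    metadata = x$metadata)
    }
    if (config$snv) x <- run_stage("snv", snv(x))
    processed[[i]] <- x
    if (config$keep_stages) artifacts[[i]] <- keep
  }
  axes <- lapply(processed, function(s) s$axis)
  same_axis <- all(vapply(axes, function(a) identical(a, axes[[1]]),
                          logical(1)))
  avg <- sd_ <- NULL
  if (same_axis && length(processed) > 1L) {
    mat <- do.call(rbind, lapply(processed, function(s) s$intensity))
    avg <- spectrum(colMeans(mat), axis = axes[[1]],
                    axis_kind = processed[[1]]$axis_kind)
    sd_ <- apply(mat, 2, stats::sd)
  }
  quality <- if (length(processed) >= 5L) {
    quality_tiers(processed, fits = if (!is.null(config$baseline) &&
                                        all(!vapply(fits, is.null, logical(1))))
      fits else NULL)
  } else NULL
  list(processed = processed, average = avg, sd = sd_, fits = fits,
       quality = quality, artifacts = artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
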
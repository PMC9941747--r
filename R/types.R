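# S3 domain types shared by all processing stages.

#' Construct a Raman spectrum
#'
#' A spectrum couples a strictly increasing axis (camera-pixel index or
#' Raman shift in cm^-1) with an intensity vector of equal length.
#'
#' @param intensity Numeric vector of detector counts or normalized units.
#' @param axis Numeric vector, strictly increasing, same length as
#'   `intensity`. Defaults to the 0-based pixel index.
#' @param axis_kind Either `"pixel"` (camera pixel index, dimensionless) or
#'   `"shift"` (Raman shift, cm^-1).
#' @param metadata Named list of free-form metadata carried through the
#'   pipeline.
#' @return An object of class `raman_spectrum` with fields `axis`,
#'   `intensity`, `axis_kind`, `metadata`.
#' @examples
#' s <- spectrum(c(1, 4, 2, 5))
#' s$axis_kind
#' @export
spectrum <- function(intensity, axis = NULL, axis_kind = c("pixel", "shift"),
                     metadata = list()) {
  axis_kind <- match.arg(axis_kind)
  intensity <- as.numeric(intensity)
  if (length(intensity) < 2L)
    rp_value_error("a spectrum needs at least 2 samples")
  if (is.null(axis)) axis <- seq_along(intensity) - 1  # 0-based pixels
  axis <- as.numeric(axis)
  if (length(axis) != length(intensity))
    rp_dim_error("axis and intensity must have equal length")
  if (any(diff(axis) <= 0))
    rp_value_error("axis must be strictly increasing")
  if (!is.list(metadata)) rp_value_error("metadata must be a list")
  structure(
    list(axis = axis, intensity = intensity, axis_kind = axis_kind,
         metadata = metadata),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d samples, axis_kind=%s, range [%g, %g]\n",
              length(x$intensity), x$axis_kind, min(x$axis), max(x$axis)))
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$intensity)

is_spectrum <- function(x) inherits(x, "raman_spectrum")

as_intensity <- function(x) {
  if (is_spectrum(x)) x$intensity else as.numeric(x)
}

#' Construct a raw acquisition
#'
#' One acquisition site: N repeated accumulations (rows) over the same
#' detector pixels (columns), an optional laser-off background spectrum,
#' and the exposure times needed to normalize the background.
#'
#' @param accumulations Numeric matrix (`n_acc` x `n_pix`) of detector
#'   counts, or a list of equal-length numeric vectors.
#' @param background Optional numeric vector of counts, same length as one
#'   accumulation, measured with the excitation source off.
#' @param exposure_acq,exposure_bg Exposure times in seconds (> 0) of the
#'   accumulations and of the background.
#' @param axis Optional axis vector (see [spectrum()]).
#' @param axis_kind `"pixel"` or `"shift"`.
#' @param metadata Named list of free-form metadata.
#' @return An object of class `raman_acquisition`.
#' @export
raw_acquisition <- function(accumulations, background = NULL,
                            exposure_acq = 1, exposure_bg = 1,
                            axis = NULL, axis_kind = c("pixel", "shift"),
                            metadata = list()) {
  axis_kind <- match.arg(axis_kind)
  if (is.list(accumulations)) {
    lens <- lengths(accumulations)
    if (length(unique(lens)) != 1L)
      rp_dim_error("ragged accumulation rows: all accumulations must have equal length")
    accumulations <- do.call(rbind, lapply(accumulations, as.numeric))
  }
  accumulations <- as.matrix(accumulations)
  storage.mode(accumulations) <- "double"
  n_pix <- ncol(accumulations)
  if (n_pix < 2L) rp_value_error("accumulations need at least 2 pixels")
  if (!is.null(background)) {
    background <- as.numeric(background)
    if (length(background) != n_pix)
      rp_dim_error(sprintf(
        "background length (%d) must match accumulation length (%d)",
        length(background), n_pix))
  }
  if (!is.numeric(exposure_acq) || exposure_acq <= 0)
    rp_value_error("exposure_acq must be > 0 seconds")
  if (!is.numeric(exposure_bg) || exposure_bg <= 0)
    rp_value_error("exposure_bg must be > 0 seconds")
  if (is.null(axis)) axis <- seq_len(n_pix) - 1
  axis <- as.numeric(axis)
  if (length(axis) != n_pix)
    rp_dim_error("axis length must match accumulation length")
  if (!is.list(metadata)) rp_value_error("metadata must be a list")
  structure(
    list(accumulations = accumulations, background = background,
         exposure_acq = as.numeric(exposure_acq),
         exposure_bg = as.numeric(exposure_bg),
         axis = axis, axis_kind = axis_kind, metadata = metadata),
    class = "raman_acquisition"
  )
}

#' @export
print.raman_acquisition <- function(x, ...) {
  cat(sprintf(
    "<raman_acquisition> %d accumulation(s) x %d pixels, background: %s\n",
    nrow(x$accumulations), ncol(x$accumulations),
    if (is.null(x$background)) "absent" else "present"))
  invisible(x)
}

is_acquisition <- function(x) inherits(x, "raman_acquisition")

#' Construct a baseline fit
#'
#' The additive decomposition `intensity = baseline + raman` produced by a
#' baseline-removal algorithm, together with the tuning parameters that
#' produced it. The reconstruction is exact by construction.
#'
#' @param baseline,raman Numeric vectors of equal length.
#' @param algorithm One of `"bubblefill"`, `"morphbr"`, `"imodpoly"`.
#' @param params Named list of tuning parameters used.
#' @param axis Optional axis carried from the input spectrum.
#' @param diagnostics Optional list of algorithm internals (e.g. the
#'   pre-smoothing baseline for BubbleFill).
#' @return An object of class `baseline_fit`.
#' @export
baseline_fit <- function(baseline, raman,
                         algorithm = c("bubblefill", "morphbr", "imodpoly"),
                         params = list(), axis = NULL, diagnostics = list()) {
  algorithm <- match.arg(algorithm)
  baseline <- as.numeric(baseline)
  raman <- as.numeric(raman)
  if (length(baseline) != length(raman))
    rp_dim_error("baseline and raman must have equal length")
  structure(
    list(baseline = baseline, raman = raman, algorithm = algorithm,
         params = params, axis = axis, diagnostics = diagnostics),
    class = "baseline_fit"
  )
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> %s, %d samples\n", x$algorithm,
              length(x$raman)))
  invisible(x)
}

#' Instrument response function model
#'
#' The per-pixel sensitivity ratio measured/theoretical of the
#' spectrometer; strictly positive so division is always defined.
#'
#' @param irf Numeric vector of strictly positive, finite ratios.
#' @return An object of class `irf_model`.
#' @export
irf_model <- function(irf) {
  irf <- as.numeric(irf)
  if (any(!is.finite(irf)) || any(irf <= 0))
    rp_value_error("IRF values must be finite and strictly positive")
  structure(list(irf = irf), class = "irf_model")
}

#' @export
print.irf_model <- function(x, ...) {
  cat(sprintf("<irf_model> %d pixels, range [%g, %g]\n",
              length(x$irf), min(x$irf), max(x$irf)))
  invisible(x)
}

#' Pixel-to-Raman-shift calibration
#'
#' Polynomial map from camera pixel index to Raman shift (cm^-1), fitted
#' from reference peaks; strictly increasing over its pixel range.
#'
#' @param coeffs Ascending polynomial coefficients (`c0 + c1*p + ...`).
#' @param order Polynomial order (2 or 3).
#' @param reference_peaks Data frame with columns `pixel` and `shift`.
#' @param pixel_range Length-2 numeric: pixel range the fit is valid over.
#' @param residuals Fit residuals (cm^-1), one per reference peak.
#' @return An object of class `shift_calibration`.
#' @export
shift_calibration <- function(coeffs, order, reference_peaks, pixel_range,
                              residuals = numeric(0)) {
  if (!order %in% c(2L, 3L)) rp_value_error("order must be 2 or 3")
  if (nrow(reference_peaks) < order + 1L)
    rp_cal_error("need at least order+1 reference peaks")
  structure(
    list(coeffs = as.numeric(coeffs), order = as.integer(order),
         reference_peaks = reference_peaks,
         pixel_range = as.numeric(pixel_range),
         residuals = as.numeric(residuals)),
    class = "shift_calibration"
  )
}

#' @export
print.shift_calibration <- function(x, ...) {
  cat(sprintf(
    "<shift_calibration> order %d, %d reference peaks, max |residual| %.3g cm^-1\n",
    x$order, nrow(x$reference_peaks),
    if (length(x$residuals)) max(abs(x$residuals)) else NA_real_))
  invisible(x)
}

#' Synthetic benchmark spectrum
#'
#' One simulated spectrum `S = (sbr*R + B)/max(sbr*R + B) + noise` with all
#' generating components retained, so the recovery error of a baseline
#' algorithm is computable against the known target.
#'
#' Constructed by [generate_spectrum()]; not usually called directly.
#'
#' @param raman_component Unit-max Raman component `R`.
#' @param baseline_component Baseline component `B`.
#' @param raman_target Raman content on the normalized-spectrum scale,
#'   `sbr*R/max(sbr*R + B)` — the signal a perfect baseline removal would
#'   recover.
#' @param noise Realized noise vector.
#' @param noise_sigma Standard deviation used to draw the noise.
#' @param sbr Signal-to-baseline ratio knob of the mixing equation.
#' @param seed Integer seed behind the noise draw.
#' @param spectrum Final simulated intensity vector.
#' @param axis Axis (Raman shift, cm^-1).
#' @return An object of class `synthetic_spectrum`.
#' @export
synthetic_spectrum <- function(raman_component, baseline_component,
                               raman_target, noise, noise_sigma, sbr, seed,
                               spectrum, axis) {
  n <- length(spectrum)
  vecs <- list(raman_component, baseline_component, raman_target, noise, axis)
  if (any(lengths(vecs) != n))
    rp_dim_error("all synthetic_spectrum vectors must have equal length")
  if (noise_sigma < 0) rp_value_error("noise_sigma must be >= 0")
  if (sbr < 0) rp_value_error("sbr must be >= 0")
  structure(
    list(raman_component = as.numeric(raman_component),
         baseline_component = as.numeric(baseline_component),
         raman_target = as.numeric(raman_target),
         noise = as.numeric(noise),
         noise_sigma = as.numeric(noise_sigma), sbr = as.numeric(sbr),
         seed = as.integer(seed), spectrum = as.numeric(spectrum),
         axis = as.numeric(axis)),
    class = "synthetic_spectrum"
  )
}

#' @export
print.synthetic_spectrum <- function(x, ...) {
  cat(sprintf("<synthetic_spectrum> %d bins, sbr=%g, noise_sigma=%g, seed=%d\n",
              length(x$spectrum), x$sbr, x$noise_sigma, x$seed))
  invisible(x)
}

#' Benchmark result container
#'
#' Best-case (minimum over the tuning grid) nMSE per algorithm, possibly
#' across an RBR grid, with the full per-grid-point detail retained.
#'
#' @param algorithms Character vector of algorithm names.
#' @param rbr_grid Numeric vector of RBR values (length 1 for a single
#'   spectrum sweep).
#' @param tuning_grids Named list: tuning grid per algorithm.
#' @param nmse Matrix (algorithm x rbr) of best-case nMSE values (>= 0).
#' @param details Data frame of every evaluated grid point.
#' @return An object of class `benchmark_result`.
#' @export
benchmark_result <- function(algorithms, rbr_grid, tuning_grids, nmse,
                             details) {
  nmse <- as.matrix(nmse)
  if (any(nmse[is.finite(nmse)] < 0))
    rp_value_error("nMSE must be nonnegative")
  structure(
    list(algorithms = algorithms, rbr_grid = as.numeric(rbr_grid),
         tuning_grids = tuning_grids, nmse = nmse, details = details),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %s over %d RBR value(s)\n",
              paste(x$algorithms, collapse = ", "), length(x$rbr_grid)))
  print(signif(x$nmse, 4))
  invisible(x)
}
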
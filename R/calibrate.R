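# Instrument-response (y-axis) and Raman-shift (x-axis) calibration.
#
# Y-axis: a NIST-style standard reference material (SRM) glass has a
# certified fluorescence shape given as polynomial coefficients; the ratio
# of the measured SRM spectrum to that certificate curve is the instrument
# response function (IRF), and spectra are corrected by dividing by it.
#
# X-axis: the pixel positions of prominent peaks of a reference compound
# (acetaminophen / nylon) are matched to their known Raman shifts and a
# low-order polynomial pixel -> cm^-1 map is fitted.

#' Evaluate an SRM certificate polynomial
#'
#' @param coeffs Ascending polynomial coefficients (`c0 + c1*x + ...`) from
#'   the SRM certificate.
#' @param axis Points (pixel index or shift) at which to evaluate; must lie
#'   within the certificate's declared validity range.
#' @return Numeric vector of strictly positive theoretical intensities.
#' @export
srm_theoretical <- function(coeffs, axis) {
  if (length(coeffs) < 1L) rp_value_error("empty coefficient vector")
  out <- polyval_asc(as.numeric(coeffs), as.numeric(axis))
  if (any(!is.finite(out)) || any(out <= 0))
    rp_value_error(
      "certificate polynomial evaluates to a nonpositive value: axis outside the certificate's validity range?")
  out
}

#' Compute the instrument response function
#'
#' `IRF = SRM_measured / SRM_theoretical`, elementwise. The measured SRM
#' spectrum must already be truncated, cosmic-ray filtered and
#' background-subtracted.
#'
#' @param srm_measured A [spectrum()] (or numeric vector) of the processed
#'   SRM measurement.
#' @param srm_theoretical_curve Strictly positive numeric vector from
#'   [srm_theoretical()], same length.
#' @return An [irf_model()].
#' @export
compute_irf <- function(srm_measured, srm_theoretical_curve) {
  m <- as_intensity(srm_measured)
  t <- as.numeric(srm_theoretical_curve)
  if (length(m) != length(t))
    rp_dim_error("measured and theoretical SRM curves must have equal length")
  if (any(t <= 0)) rp_value_error("theoretical SRM curve must be strictly positive")
  irf_model(m / t)
}

#' Correct a spectrum for the instrument response
#'
#' Divides the intensity by the IRF, pixel by pixel.
#'
#' @param spec A [spectrum()].
#' @param irf An [irf_model()] of the same length.
#' @return The corrected [spectrum()].
#' @export
apply_irf <- function(spec, irf) {
  if (!inherits(irf, "irf_model")) rp_value_error("irf must be an irf_model")
  y <- as_intensity(spec)
  if (length(y) != length(irf$irf))
    rp_dim_error("spectrum and IRF lengths differ")
  out <- y / irf$irf
  if (is_spectrum(spec))
    spectrum(out, axis = spec$axis, axis_kind = spec$axis_kind,
             metadata = spec$metadata)
  else spectrum(out)
}

#' Find prominent peaks in a spectrum
#'
#' Local maxima filtered by topographic prominence (height above the
#' higher of the two flanking valleys toward the nearest higher ground)
#' and by a minimum mutual separation; of any two closer than
#' `min_separation` samples, the less prominent is dropped.
#'
#' @param y Numeric intensity vector.
#' @param prominence_frac Minimum prominence as a fraction of the signal
#'   range.
#' @param min_separation Minimum distance between kept peaks, in samples.
#' @return Data frame with columns `index` (1-based sample index),
#'   `offset` (sub-sample position refinement from a 3-point parabola, in
#'   samples), `height`, `prominence`, ordered by index.
#' @export
find_spectral_peaks <- function(y, prominence_frac = 0.05,
                                min_separation = 10L) {
  y <- as_intensity(y)
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L  # strict rise then fall/flat
  cand <- cand[y[cand] > y[cand - 1L]]
  if (length(cand) == 0L)
    return(data.frame(index = integer(0), offset = numeric(0),
                      height = numeric(0), prominence = numeric(0)))
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left <- if (i > 1) y[1:(i - 1L)] else numeric(0)
    right <- if (i < n) y[(i + 1L):n] else numeric(0)
    lv <- local_valley(left, h, reverse = TRUE)
    rv <- local_valley(right, h, reverse = FALSE)
    h - max(lv, rv)
  }, numeric(1))
  keep <- prom >= prominence_frac * diff(range(y))
  cand <- cand[keep]; prom <- prom[keep]
  # enforce separation: greedy by descending prominence
  ord <- order(-prom)
  taken <- integer(0)
  for (j in ord) {
    if (all(abs(cand[j] - cand[taken]) >= min_separation))
      taken <- c(taken, j)
  }
  taken <- sort(taken)
  idx <- cand[taken]
  # sub-sample apex from the parabola through the 3 samples around the peak
  offset <- vapply(idx, function(i) {
    if (i <= 1L || i >= n) return(0)
    denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
    if (denom >= 0) return(0)
    d <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
    max(min(d, 0.5), -0.5)
  }, numeric(1))
  data.frame(index = idx, offset = offset, height = y[idx],
             prominence = prom[taken])
}

# Lowest point between a peak (height h) and the nearest strictly higher
# sample on one side; the side's global minimum if no higher ground exists.
local_valley <- function(side, h, reverse) {
  if (length(side) == 0L) return(min(h, Inf))
  if (reverse) side <- rev(side)  # walk away from the peak
  higher <- which(side > h)
  seg <- if (length(higher)) side[1:higher[1]] else side
  min(seg)
}

#' Calibrate the pixel-to-Raman-shift map
#'
#' Detects the most prominent peaks of a fully preprocessed reference
#' spectrum (acetaminophen- or nylon-like), matches the top
#' `length(known_shifts)` of them to the known shifts by rank order along
#' the axis, and fits a least-squares polynomial of the given order.
#'
#' @param reference_spec A preprocessed [spectrum()] on a pixel axis.
#' @param known_shifts Increasing vector of known peak positions (cm^-1);
#'   at least `order + 1` of them.
#' @param order Polynomial order, 2 or 3.
#' @param prominence_frac,min_separation Passed to [find_spectral_peaks()].
#' @param reference_rbr Optional Raman-to-baseline ratio of the reference
#'   measurement; values below 0.2 trigger a warning (weak references make
#'   peak finding unreliable).
#' @return A [shift_calibration()].
#' @export
calibrate_xaxis <- function(reference_spec, known_shifts, order = 2L,
                            prominence_frac = 0.05, min_separation = 10L,
                            reference_rbr = NULL) {
  order <- as.integer(order)
  if (!order %in% c(2L, 3L)) rp_value_error("order must be 2 or 3")
  known_shifts <- sort(as.numeric(known_shifts))
  k <- length(known_shifts)
  if (k < order + 1L)
    rp_cal_error(sprintf(
      "calibration underdetermined: %d known shifts for order %d (need >= %d)",
      k, order, order + 1L))
  if (!is.null(reference_rbr) && reference_rbr < 0.2)
    warning(sprintf(
      "reference RBR %.3g is below 0.2; x-axis calibration may be unreliable",
      reference_rbr))
  peaks <- find_spectral_peaks(reference_spec, prominence_frac, min_separation)
  if (nrow(peaks) < k)
    rp_cal_error(sprintf(
      "found %d prominent peaks but %d known shifts were supplied",
      nrow(peaks), k))
  top <- peaks[order(-peaks$prominence)[1:k], ]
  top <- top[order(top$index), ]
  ax <- if (is_spectrum(reference_spec)) reference_spec$axis
        else seq_along(as_intensity(reference_spec)) - 1
  step <- stats::median(diff(ax))
  px <- ax[top$index] + top$offset * step  # sub-pixel peak positions
  fit <- stats::lm(known_shifts ~ stats::poly(px, order, raw = TRUE))
  coeffs <- unname(stats::coef(fit))
  coeffs[is.na(coeffs)] <- 0
  prange <- range(ax)
  # reject a non-monotonic map: derivative must stay positive on the range
  grid <- seq(prange[1], prange[2], length.out = 512L)
  dcoef <- coeffs[-1] * seq_len(order)
  if (any(polyval_asc(dcoef, grid) <= 0))
    rp_cal_error("fitted pixel->shift map is not strictly increasing over the pixel range")
  shift_calibration(
    coeffs = coeffs, order = order,
    reference_peaks = data.frame(pixel = px, shift = known_shifts),
    pixel_range = prange,
    residuals = unname(stats::resid(fit)))
}

#' Convert pixel indices to Raman shifts
#'
#' @param cal A [shift_calibration()].
#' @param pixels Pixel indices (within the calibrated range).
#' @return Raman shifts in cm^-1.
#' @export
predict_shift <- function(cal, pixels) {
  if (!inherits(cal, "shift_calibration"))
    rp_value_error("cal must be a shift_calibration")
  polyval_asc(cal$coeffs, as.numeric(pixels))
}

#' Resample a spectrum onto a common Raman-shift grid
#'
#' Applies the calibration to the spectrum's pixel axis and linearly
#' interpolates the intensity onto the target grid, so that a batch of
#' spectra shares one axis (a hard requirement for downstream statistics
#' and machine learning). No extrapolation: the grid must lie inside the
#' calibrated shift range.
#'
#' @param spec A [spectrum()]. A pixel axis is converted through `cal`; a
#'   shift axis is used as is (pass `cal = NULL`).
#' @param cal A [shift_calibration()] or `NULL`.
#' @param grid Increasing target shift vector (cm^-1).
#' @return A [spectrum()] on `grid` with `axis_kind = "shift"`.
#' @export
resample_common_axis <- function(spec, cal, grid) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) rp_value_error("grid must be strictly increasing")
  shifts <- if (spec$axis_kind == "shift") {
    spec$axis
  } else {
    if (is.null(cal)) rp_value_error("a shift_calibration is required for a pixel axis")
    predict_shift(cal, spec$axis)
  }
  if (grid[1] < min(shifts) || grid[length(grid)] > max(shifts))
    rp_range_error(sprintf(
      "grid [%g, %g] extends beyond the calibrated range [%g, %g]; extrapolation is not performed",
      grid[1], grid[length(grid)], min(shifts), max(shifts)))
  out <- stats::approx(shifts, spec$intensity, xout = grid)$y
  spectrum(out, axis = grid, axis_kind = "shift", metadata = spec$metadata)
}
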
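# Smoothing, normalizations, and spectral-quality statistics.

#' Moving-average smoothing
#'
#' Centered moving mean with an odd window; at the boundaries the window
#' shrinks symmetrically to what fits.
#'
#' @param spec A [spectrum()] or numeric vector.
#' @param window Odd window length `< length`.
#' @return Same type as the input, smoothed.
#' @export
smooth_moving_average <- function(spec, window = 5L) {
  y <- as_intensity(spec)
  n <- length(y)
  window <- as.integer(window)
  if (window %% 2L == 0L) rp_value_error("window must be odd")
  if (window >= n + 1L) rp_value_error("window must not exceed signal length")
  half <- (window - 1L) %/% 2L
  out <- y
  if (half > 0L) {
    cs <- cumsum(c(0, y))
    for (i in seq_len(n)) {
      h <- min(half, i - 1L, n - i)  # symmetric shrinkage at edges
      out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
    }
  }
  if (is_spectrum(spec))
    spectrum(out, axis = spec$axis, axis_kind = spec$axis_kind,
             metadata = spec$metadata)
  else out
}

#' Min-max normalization
#'
#' Shifts the minimum to 0 and scales so that the maximum — or the
#' intensity at a chosen Raman shift — becomes 1. Intended for visual
#' comparison of spectra spanning wide intensity ranges.
#'
#' @param spec A [spectrum()] or numeric vector.
#' @param anchor_shift Optional axis position whose (min-shifted)
#'   intensity is scaled to 1; the nearest axis sample is used.
#' @return Same type as the input, normalized.
#' @export
normalize_minmax <- function(spec, anchor_shift = NULL) {
  y <- as_intensity(spec)
  if (diff(range(y)) == 0) rp_value_error("cannot normalize a constant spectrum")
  shifted <- y - min(y)
  denom <- if (is.null(anchor_shift)) {
    max(shifted)
  } else {
    ax <- if (is_spectrum(spec)) spec$axis else seq_along(y) - 1
    shifted[which.min(abs(ax - anchor_shift))]
  }
  if (denom == 0) rp_value_error("anchor intensity equals the minimum; cannot scale")
  out <- shifted / denom
  if (is_spectrum(spec))
    spectrum(out, axis = spec$axis, axis_kind = spec$axis_kind,
             metadata = spec$metadata)
  else out
}

#' Standard normal variate (SNV) normalization
#'
#' Per-spectrum z-scoring with the population (1/N) standard deviation:
#' `(s - mean(s)) / sqrt(mean((s - mean(s))^2))`. The output has mean 0
#' and population SD 1; it is the normalization of choice ahead of
#' machine-learning models.
#'
#' @param spec A [spectrum()] or numeric vector (non-constant).
#' @return Same type as the input, SNV-normalized.
#' @export
snv <- function(spec) {
  y <- as_intensity(spec)
  s <- pop_sd(y)
  if (s == 0) rp_value_error("SNV is undefined for a constant spectrum")
  out <- (y - mean(y)) / s
  if (is_spectrum(spec))
    spectrum(out, axis = spec$axis, axis_kind = spec$axis_kind,
             metadata = spec$metadata)
  else out
}

#' Raman-to-baseline ratio (RBR)
#'
#' Intensity of the tallest Raman peak divided by the maximum of the
#' baseline signal.
#'
#' @param raman Numeric Raman vector (or a [baseline_fit()], in which case
#'   `baseline` is ignored).
#' @param baseline Numeric baseline vector with a positive maximum.
#' @return A nonnegative scalar.
#' @export
rbr <- function(raman, baseline = NULL) {
  if (inherits(raman, "baseline_fit")) {
    baseline <- raman$baseline
    raman <- raman$raman
  }
  raman <- as.numeric(raman)
  baseline <- as.numeric(baseline)
  if (max(baseline) <= 0)
    rp_value_error("baseline maximum must be positive for RBR")
  max(raman) / max(baseline)
}

#' Average signed squared intensity (ASSI)
#'
#' An instrument-portable spectral quality score: the input is SNV
#' normalized, then `ASSI = mean(sign(r) * r^2)`. A few large narrow peaks
#' push it toward 1, many small broad features toward 0 from above, and a
#' pure-noise signal scores ~0; it is bounded in `[-1, 1]`.
#'
#' @param spec A [spectrum()] or numeric vector (non-constant).
#' @return A scalar in `[-1, 1]`.
#' @export
assi <- function(spec) {
  r <- snv(as_intensity(spec))
  mean(sign(r) * r^2)
}

#' Tier a batch of spectra by ASSI quality
#'
#' Spectra are ranked by ASSI; the top 20% are tier `"high"`, the 40th-60th
#' percentile band `"average"`, the bottom 20% `"low"`, everything else
#' `"none"`. Ties are broken deterministically by input order.
#'
#' @param batch List of [spectrum()] objects or numeric vectors (>= 5).
#' @param fits Optional list of [baseline_fit()] objects (same length) from
#'   which a per-spectrum RBR column is computed.
#' @return Data frame with columns `id`, `assi`, `rbr` (NA without `fits`),
#'   `tier` (factor with levels high/average/low/none), in input order.
#' @export
quality_tiers <- function(batch, fits = NULL) {
  n <- length(batch)
  if (n < 5L) rp_value_error("quality tiering needs at least 5 spectra")
  scores <- vapply(batch, assi, numeric(1))
  rank_of <- integer(n)
  rank_of[order(scores, seq_len(n))] <- seq_len(n)  # stable: ties by input order
  k <- floor(n / 5)
  mid_start <- floor(0.4 * n) + 1L
  tier <- rep("none", n)
  tier[rank_of > n - k] <- "high"
  tier[rank_of >= mid_start & rank_of < mid_start + k] <- "average"
  tier[rank_of <= k] <- "low"
  rbrs <- rep(NA_real_, n)
  if (!is.null(fits)) {
    if (length(fits) != n) rp_dim_error("fits must match the batch length")
    rbrs <- vapply(fits, rbr, numeric(1))
  }
  data.frame(id = seq_len(n), assi = scores, rbr = rbrs,
             tier = factor(tier, levels = c("high", "average", "low", "none")))
}
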
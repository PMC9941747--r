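# Synthetic benchmark spectra.
#
# A benchmark spectrum mixes a known Raman component R (superposition of
# Gaussian peaks), a known smooth baseline B and Gaussian noise:
#     S = (sbr*R + B) / max(sbr*R + B) + N(0, sigma^2).
# Because every component is retained, the recovery error of a baseline
# algorithm is computable exactly — this is the framework used to compare
# BubbleFill, MorphBR and iModPoly on a level playing field.
#
# The peak presets are parameterized analogs of common reference
# compounds (acetaminophen/"tylenol", nylon, PDMS); the baseline kinds
# emulate the two fluorescence morphologies seen on real substrates: a
# single smooth decaying hump (nigrosin-like) and a shape with several
# localized bumps (aluminium-like, the case that defeats polynomial
# fitting). Benchmark numbers are trend-level reproductions: the measured
# components behind the published figures are not public.

#' Gaussian peak model for a synthetic Raman component
#'
#' @param centers Peak centers (cm^-1).
#' @param widths Gaussian sigma per peak (cm^-1), > 0.
#' @param amplitudes Positive peak amplitudes (relative).
#' @return An object of class `peak_model`.
#' @export
peak_model <- function(centers, widths, amplitudes) {
  if (length(centers) == 0L) rp_value_error("empty peak list")
  if (length(widths) != length(centers) ||
      length(amplitudes) != length(centers))
    rp_dim_error("centers, widths and amplitudes must have equal length")
  if (any(widths <= 0)) rp_value_error("widths must be > 0")
  if (any(amplitudes <= 0)) rp_value_error("amplitudes must be > 0")
  structure(list(centers = as.numeric(centers), widths = as.numeric(widths),
                 amplitudes = as.numeric(amplitudes)),
            class = "peak_model")
}

#' Built-in Raman peak presets
#'
#' Hand-parameterized Gaussian peak tables mimicking the density and
#' spread of common x-axis reference compounds over 400-1800 cm^-1:
#' `"tylenol_like"` (dense, many narrow peaks), `"nylon_like"`
#' (moderate), `"pdms_like"` (sparse).
#'
#' @param name Preset name.
#' @return A [peak_model()].
#' @export
raman_peak_preset <- function(name = c("tylenol_like", "nylon_like",
                                       "pdms_like")) {
  name <- match.arg(name)
  switch(name,
    tylenol_like = peak_model(
      centers = c(465, 651, 710, 797, 834, 857, 968, 1105, 1168, 1236,
                  1278, 1323, 1371, 1515, 1561, 1648),
      widths = c(5, 5, 4, 5, 4, 5, 6, 5, 6, 6, 5, 7, 6, 6, 5, 7),
      amplitudes = c(0.5, 0.6, 0.3, 0.8, 0.5, 1.0, 0.4, 0.3, 0.5, 0.7,
                     0.4, 0.9, 0.5, 0.3, 0.4, 0.6)),
    nylon_like = peak_model(
      centers = c(930, 1064, 1130, 1235, 1300, 1382, 1440, 1635),
      widths = c(8, 7, 7, 9, 8, 9, 9, 10),
      amplitudes = c(0.4, 0.8, 0.9, 0.3, 0.5, 0.3, 1.0, 0.6)),
    pdms_like = peak_model(
      centers = c(488, 618, 709, 862, 1262, 1412),
      widths = c(7, 6, 6, 7, 8, 9),
      amplitudes = c(1.0, 0.3, 0.9, 0.5, 0.6, 0.3)))
}

#' Baseline morphology model
#'
#' @param kind `"smooth"` (one broad decaying hump, nigrosin-like) or
#'   `"bumpy"` (several broad overlapping humps producing localized bumps,
#'   aluminium-like).
#' @param n_humps Number of humps for the bumpy kind.
#' @param hump_width_frac Hump sigma as a fraction of the axis span.
#' @param smooth_window Moving-average polish window (samples) applied to
#'   the finished curve.
#' @return An object of class `baseline_model`.
#' @export
baseline_model <- function(kind = c("smooth", "bumpy"), n_humps = 4L,
                           hump_width_frac = 0.08, smooth_window = 50L) {
  kind <- match.arg(kind)
  if (n_humps < 1L) rp_value_error("n_humps must be >= 1")
  if (hump_width_frac <= 0) rp_value_error("hump_width_frac must be > 0")
  structure(list(kind = kind, n_humps = as.integer(n_humps),
                 hump_width_frac = hump_width_frac,
                 smooth_window = as.integer(smooth_window)),
            class = "baseline_model")
}

#' Build the Raman component
#'
#' Sum of Gaussians evaluated on the axis, max-normalized to 1.
#'
#' @param peaks A [peak_model()].
#' @param axis Increasing axis vector (cm^-1).
#' @return Unit-max numeric vector.
#' @export
make_raman_component <- function(peaks, axis) {
  if (!inherits(peaks, "peak_model")) rp_value_error("peaks must be a peak_model")
  axis <- as.numeric(axis)
  if (any(diff(axis) <= 0)) rp_value_error("axis must be strictly increasing")
  out <- rep(0, length(axis))
  for (j in seq_along(peaks$centers)) {
    out <- out + peaks$amplitudes[j] *
      exp(-(axis - peaks$centers[j])^2 / (2 * peaks$widths[j]^2))
  }
  out / max(out)
}

#' Build the baseline component
#'
#' Draws hump positions/amplitudes from the seed, sums positive Gaussians
#' over a small pedestal, polishes with a moving-average filter
#' (emulating the denoising applied to measured fluorescence curves) and
#' max-normalizes to 1. The same seed reproduces the same curve.
#'
#' @param model A [baseline_model()].
#' @param axis Increasing axis vector (cm^-1).
#' @param seed Integer seed.
#' @return Nonnegative, smooth, unit-max numeric vector.
#' @export
make_baseline_component <- function(model, axis, seed = 0L) {
  if (!inherits(model, "baseline_model"))
    rp_value_error("model must be a baseline_model")
  axis <- as.numeric(axis)
  if (any(diff(axis) <= 0)) rp_value_error("axis must be strictly increasing")
  n <- length(axis)
  span <- diff(range(axis))
  lo <- min(axis)
  curve <- with_seed(seed, {
    if (model$kind == "smooth") {
      # one broad monotone-ish hump: fluorescence decaying across the window
      center <- lo - span * stats::runif(1, 0.05, 0.25)
      width <- span * stats::runif(1, 0.7, 1.0)
      0.05 + exp(-(axis - center)^2 / (2 * width^2))
    } else {
      centers <- lo + span * (seq_len(model$n_humps) - 0.5) / model$n_humps +
        span * stats::runif(model$n_humps, -0.04, 0.04)
      widths <- span * model$hump_width_frac *
        stats::runif(model$n_humps, 0.8, 1.25)
      amps <- stats::runif(model$n_humps, 0.4, 1)
      base <- 0.15 + 0.1 * (axis - lo) / span  # gentle pedestal
      for (j in seq_len(model$n_humps)) {
        base <- base + amps[j] * exp(-(axis - centers[j])^2 / (2 * widths[j]^2))
      }
      base
    }
  })
  win <- odd_at_most(model$smooth_window, n)
  curve <- smooth_moving_average(curve, win)
  curve <- pmax(curve, 0)
  curve / max(curve)
}

#' Generate one synthetic benchmark spectrum
#'
#' Mixes the components as `(sbr*R + B) / max(sbr*R + B)` — so the
#' noiseless part has maximum exactly 1 — then adds Gaussian noise drawn
#' under the seed.
#'
#' @param raman Unit-max Raman component (see [make_raman_component()]).
#' @param baseline Baseline component (see [make_baseline_component()]).
#' @param sbr Signal-to-baseline ratio knob (>= 0). The figures' "RBR"
#'   sweep moves this same knob; the post-hoc RBR of the generated
#'   spectrum is recomputable from the stored components via [rbr()].
#' @param noise_sigma Noise SD in units of the normalized spectrum (0.01 =
#'   1% of the baseline maximum).
#' @param seed Integer seed for the noise draw.
#' @param axis Optional axis stored with the result (defaults to the
#'   0-based bin index).
#' @return A [synthetic_spectrum()].
#' @export
generate_spectrum <- function(raman, baseline, sbr, noise_sigma = 0,
                              seed = 0L, axis = NULL) {
  raman <- as.numeric(raman)
  baseline <- as.numeric(baseline)
  if (length(raman) != length(baseline))
    rp_dim_error("raman and baseline components must have equal length")
  if (sbr < 0) rp_value_error("sbr must be >= 0")
  if (noise_sigma < 0) rp_value_error("noise_sigma must be >= 0")
  mix <- sbr * raman + baseline
  m <- max(mix)
  if (m <= 0) rp_value_error("all-zero mixture: nothing to normalize")
  noiseless <- mix / m
  n <- length(mix)
  noise <- if (noise_sigma > 0) {
    with_seed(seed, stats::rnorm(n, 0, noise_sigma))
  } else rep(0, n)
  if (is.null(axis)) axis <- seq_len(n) - 1
  synthetic_spectrum(
    raman_component = raman, baseline_component = baseline,
    raman_target = sbr * raman / m, noise = noise,
    noise_sigma = noise_sigma, sbr = sbr, seed = seed,
    spectrum = noiseless + noise, axis = axis)
}

#' Inject synthetic cosmic rays into an acquisition
#'
#' Places `n_spikes` sharp artifacts (1-5 pixels wide, peaked profile of
#' the given amplitude) at uniformly random, non-overlapping
#' (accumulation, pixel-range) loci, recording the ground truth for
#' recovery studies.
#'
#' @param acq A [raw_acquisition()].
#' @param n_spikes Number of spikes (>= 0).
#' @param amplitude Spike peak amplitude in counts.
#' @param width_px Spike width in pixels (1-5).
#' @param seed Integer seed.
#' @return List with `acquisition` (spiked copy) and `truth` (data frame
#'   with columns `accumulation`, `px_start`, `px_end`, 1-based inclusive).
#' @export
inject_cosmic_rays <- function(acq, n_spikes, amplitude, width_px = 3L,
                               seed = 0L) {
  if (!is_acquisition(acq)) rp_value_error("expects a raman_acquisition")
  if (n_spikes < 0) rp_value_error("n_spikes must be >= 0")
  if (!width_px %in% 1:5) rp_value_error("width_px must be in 1..5")
  A <- acq$accumulations
  n_acc <- nrow(A); n_pix <- ncol(A)
  truth <- data.frame(accumulation = integer(0), px_start = integer(0),
                      px_end = integer(0))
  if (n_spikes > 0) {
    placed <- with_seed(seed, {
      # candidate loci keep whole spike inside the row; enforce disjoint
      # (and non-adjacent) ranges within an accumulation
      got <- list()
      guard <- 0L
      while (length(got) < n_spikes) {
        guard <- guard + 1L
        if (guard > 1000L * n_spikes)
          rp_value_error("n_spikes exceeds the number of placeable loci")
        a <- sample.int(n_acc, 1L)
        s <- sample.int(n_pix - width_px + 1L, 1L)
        e <- s + width_px - 1L
        clash <- any(vapply(got, function(g) {
          g$a == a && !(e < g$s - 2L || s > g$e + 2L)
        }, logical(1)))
        if (!clash) got[[length(got) + 1L]] <- list(a = a, s = s, e = e)
      }
      got
    })
    profile <- function(w) {
      # peaked spike: maximum at center, tapering to half at the edges
      if (w == 1L) return(1)
      x <- seq_len(w)
      0.5 + 0.5 * exp(-((x - (w + 1) / 2)^2) / (w / 2))
    }
    for (g in placed) {
      w <- g$e - g$s + 1L
      A[g$a, g$s:g$e] <- A[g$a, g$s:g$e] + amplitude * profile(w)
      truth <- rbind(truth, data.frame(accumulation = g$a, px_start = g$s,
                                       px_end = g$e))
    }
  }
  list(
    acquisition = raw_acquisition(A, background = acq$background,
                                  exposure_acq = acq$exposure_acq,
                                  exposure_bg = acq$exposure_bg,
                                  axis = acq$axis, axis_kind = acq$axis_kind,
                                  metadata = acq$metadata),
    truth = truth)
}

#' Normalized mean squared error (nMSE)
#'
#' `sum((target - computed)^2) / (sum(target))^2` — the benchmark score
#' for baseline-removal recovery. Invariant under joint positive scaling
#' of both vectors.
#'
#' @param raman_computed Recovered Raman vector.
#' @param raman_target Known target Raman vector (nonzero sum).
#' @return Nonnegative scalar.
#' @export
nmse <- function(raman_computed, raman_target) {
  c_ <- as.numeric(raman_computed)
  t_ <- as.numeric(raman_target)
  if (length(c_) != length(t_)) rp_dim_error("vectors must have equal length")
  s <- sum(t_)
  if (s == 0) rp_value_error("target sums to zero; nMSE undefined")
  sum((t_ - c_)^2) / s^2
}
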
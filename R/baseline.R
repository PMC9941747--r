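# Baseline (autofluorescence) removal.
#
# Three algorithms share one contract: the input intensity is decomposed
# as intensity = baseline + raman, exactly, and the tuning parameters are
# recorded in the returned baseline_fit.
#
# BubbleFill is the morphological workhorse: the spectrum is detrended,
# rescaled to a square aspect ratio, and circular "bubbles" are grown
# underneath it — each bubble rises until it touches the signal, the
# touching point splits its interval in two, and children keep growing
# until they would be narrower than the minimum bubble width. The baseline
# is the upper envelope of all popped bubbles, Savitzky-Golay smoothed.

#' BubbleFill tuning parameters
#'
#' @param min_width Minimum bubble width: a scalar, or a per-pixel vector
#'   to allow different aggressiveness across the axis (larger bubbles
#'   preserve small peaks in a chosen region). Interpreted as a fraction
#'   of the axis span when `min_width_unit = "fraction"` (the canonical
#'   unit: it survives resampling), or directly in samples.
#' @param min_width_unit `"fraction"` or `"samples"`.
#' @param slope_order Order of the polynomial used to remove the global
#'   slope before bubble growth (0 = offset only, 1 = linear, default).
#' @param smooth_window Odd Savitzky-Golay window applied to the finished
#'   baseline; default couples it to the minimum bubble width.
#' @param smooth_polyorder Savitzky-Golay polynomial order
#'   (< `smooth_window`).
#' @return An object of class `bubble_params`.
#' @export
bubble_params <- function(min_width = 0.1,
                          min_width_unit = c("fraction", "samples"),
                          slope_order = 1L, smooth_window = NULL,
                          smooth_polyorder = 2L) {
  min_width_unit <- match.arg(min_width_unit)
  if (any(min_width <= 0)) rp_value_error("min_width must be > 0")
  if (slope_order < 0) rp_value_error("slope_order must be >= 0")
  if (!is.null(smooth_window)) {
    if (smooth_window %% 2 == 0) rp_value_error("smooth_window must be odd")
    if (smooth_polyorder >= smooth_window)
      rp_value_error("smooth_polyorder must be < smooth_window")
  }
  structure(list(min_width = min_width, min_width_unit = min_width_unit,
                 slope_order = as.integer(slope_order),
                 smooth_window = smooth_window,
                 smooth_polyorder = as.integer(smooth_polyorder)),
            class = "bubble_params")
}

#' Grow one bubble under a signal segment
#'
#' The bubble over 1-based index interval `[left, right]` is the upper
#' half-circle whose diameter spans the interval (in sample units; the
#' caller is responsible for square-aspect scaling of the y axis), raised
#' by the largest vertical lift keeping it at or below the signal on the
#' interval. Intervals touching a signal edge use an edge-anchored quarter
#' arc of doubled radius so the baseline can rise at the boundary.
#'
#' @param signal Numeric vector (square-aspect scaled).
#' @param left,right Interval bounds, `right - left >= 1`.
#' @param anchored `"none"` (centered bubble), `"left_edge"` or
#'   `"right_edge"` (doubled-radius arc anchored at that edge).
#' @return List with `arc` (bubble heights over `left:right`), `contact`
#'   (leftmost index where the bubble touches the signal), and `indices`.
#' @export
bubble_lift <- function(signal, left, right,
                        anchored = c("none", "left_edge", "right_edge")) {
  anchored <- match.arg(anchored)
  if (right - left < 1L) {
    return(list(arc = signal[left], contact = left, indices = left))
  }
  idx <- left:right
  x <- idx - left
  w <- right - left
  shape <- switch(anchored,
    none = {
      r <- w / 2
      sqrt(pmax(r^2 - (x - r)^2, 0))
    },
    left_edge = sqrt(pmax(w^2 - x^2, 0)),
    right_edge = sqrt(pmax(w^2 - (x - w)^2, 0))
  )
  gap <- signal[idx] - shape
  lift <- min(gap)
  # leftmost of the (numerically) tied minimal-gap samples
  tol <- 1e-9 * (max(abs(signal[idx])) + 1)
  contact <- idx[which(gap <= lift + tol)[1L]]
  list(arc = shape + lift, contact = contact, indices = idx)
}

# Iterative bubble growth over the scaled signal; returns the baseline
# envelope (same scale). min_width_samples is a per-pixel vector.
bubble_loop <- function(s, min_width_samples) {
  n <- length(s)
  B <- rep(min(s), n)
  queue <- list(c(1L, n))
  while (length(queue)) {
    iv <- queue[[1L]]
    queue <- queue[-1L]
    l <- iv[1L]; r <- iv[2L]
    if (r - l < 1L) next
    mw <- min_width_samples[(l + r) %/% 2L]
    if ((r - l) < mw) next  # branch reached the critical minimum diameter
    anchored <- if (l == 1L && r == n) "none"
                else if (l == 1L) "left_edge"
                else if (r == n) "right_edge"
                else "none"
    bub <- bubble_lift(s, l, r, anchored)
    seg <- l:r
    B[seg] <- pmax(B[seg], bub$arc)  # baseline = max(bubble, current)
    ct <- bub$contact
    if (ct == l) {
      queue <- c(queue, list(c(l + 1L, r)))       # endpoint contact:
    } else if (ct == r) {
      queue <- c(queue, list(c(l, r - 1L)))       #   single shrunk child
    } else {
      queue <- c(queue, list(c(l, ct), c(ct, r)))
    }
  }
  B
}

#' BubbleFill baseline removal
#'
#' Pipeline: (1) remove the global slope with a polynomial of order
#' `slope_order`; (2) rescale so the y range equals the x range (square
#' aspect ratio — bubbles are then truly circular); (3) grow bubbles
#' beneath the signal, splitting at every contact point, until every
#' branch is narrower than the local minimum bubble width; (4) undo the
#' scaling and re-add the trend; (5) Savitzky-Golay smooth the baseline;
#' (6) `raman = intensity - baseline`.
#'
#' A constant input is a documented degenerate case: the baseline equals
#' the input and the Raman part is zero.
#'
#' @param spec A [spectrum()] or numeric vector.
#' @param params A [bubble_params()].
#' @return A [baseline_fit()]; `diagnostics$presmooth` holds the baseline
#'   before smoothing and `diagnostics$scaled_signal` /
#'   `diagnostics$scaled_baseline` the square-aspect internals (the
#'   envelope never exceeds the signal there).
#' @export
bubblefill <- function(spec, params = bubble_params()) {
  if (!inherits(params, "bubble_params"))
    rp_value_error("params must be created with bubble_params()")
  y <- as_intensity(spec)
  n <- length(y)
  if (n < 8L) rp_value_error("need at least 8 samples")
  axis <- if (is_spectrum(spec)) spec$axis else seq_len(n) - 1
  plist <- list(min_width = params$min_width,
                min_width_unit = params$min_width_unit,
                slope_order = params$slope_order,
                smooth_polyorder = params$smooth_polyorder)

  wsamp <- params$min_width
  if (params$min_width_unit == "fraction") wsamp <- wsamp * (n - 1)
  wvec <- if (length(wsamp) == 1L) rep(wsamp, n) else as.numeric(wsamp)
  if (length(wvec) != n)
    rp_dim_error("per-pixel min_width must have the spectrum's length")

  degenerate <- function() {
    baseline_fit(baseline = y, raman = rep(0, n), algorithm = "bubblefill",
                 params = plist, axis = axis)
  }
  if (diff(range(y)) == 0) return(degenerate())

  # 1. detrend
  x01 <- seq(0, 1, length.out = n)
  trend <- if (params$slope_order == 0L) {
    rep(mean(y), n)
  } else {
    basis <- cbind(1, outer(x01, seq_len(params$slope_order), `^`))
    stats::lm.fit(basis, y)$fitted.values
  }
  s1 <- y - trend
  yrange <- diff(range(s1))
  if (yrange < .Machine$double.eps * max(1, diff(range(y)))) {
    # the trend explains everything (e.g. straight-line input)
    return(baseline_fit(baseline = y, raman = rep(0, n),
                        algorithm = "bubblefill", params = plist, axis = axis))
  }

  # 2. square aspect: y in [0, n-1], x in samples 0..n-1
  s2 <- (s1 - min(s1)) / yrange * (n - 1)

  # 3. grow bubbles
  B2 <- bubble_loop(s2, wvec)

  # 4. unscale + retrend
  presmooth <- B2 / (n - 1) * yrange + min(s1) + trend

  # 5. smooth
  win <- params$smooth_window
  if (is.null(win)) win <- max(2L * (floor(min(wvec)) %/% 2L) + 1L, 5L)
  win <- odd_at_most(win, n)
  porder <- min(params$smooth_polyorder, win - 1L)
  baseline <- savitzky_golay(presmooth, win, porder)
  plist$smooth_window <- win

  baseline_fit(
    baseline = baseline, raman = y - baseline, algorithm = "bubblefill",
    params = plist, axis = axis,
    diagnostics = list(presmooth = presmooth, trend = trend,
                       scaled_signal = s2, scaled_baseline = B2))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with a centered window;
#' boundary samples are smoothed by evaluating the polynomial fitted to
#' the first/last full window at their positions.
#'
#' @param y Numeric vector.
#' @param window Odd window length `<= length(y)`.
#' @param polyorder Polynomial order `< window`.
#' @return Smoothed numeric vector of the same length.
#' @export
savitzky_golay <- function(y, window, polyorder = 2L) {
  n <- length(y)
  window <- as.integer(window)
  if (window %% 2L == 0L) rp_value_error("window must be odd")
  if (window > n) rp_value_error("window exceeds signal length")
  if (polyorder >= window) rp_value_error("polyorder must be < window")
  if (window == 1L) return(y)
  half <- (window - 1L) %/% 2L
  X <- outer(seq(-half, half), 0:polyorder, `^`)
  H <- X %*% solve(crossprod(X), t(X))  # projection onto local polynomials
  out <- numeric(n)
  center <- H[half + 1L, ]
  for (i in (half + 1L):(n - half)) {
    out[i] <- sum(center * y[(i - half):(i + half)])
  }
  out[1:half] <- (H %*% y[1:window])[1:half]
  out[(n - half + 1L):n] <- (H %*% y[(n - window + 1L):n])[(half + 2L):window]
  out
}

#' Iterative modified polynomial baseline (iModPoly)
#'
#' Fits a polynomial of the given order, then repeatedly clips the working
#' signal down to `fit + DEV` (DEV = residual standard deviation) so that
#' peaks are progressively excluded, refitting until the relative change
#' in DEV drops below `tol` or `max_iter` is reached.
#'
#' @param spec A [spectrum()] or numeric vector with more than `order + 1`
#'   samples.
#' @param order Polynomial order (typically 5 or 6).
#' @param tol Relative DEV-change convergence tolerance.
#' @param max_iter Iteration cap; on hitting it the best fit is returned
#'   with `params$converged = FALSE`.
#' @return A [baseline_fit()].
#' @export
imodpoly <- function(spec, order = 5L, tol = 0.05, max_iter = 100L) {
  y <- as_intensity(spec)
  n <- length(y)
  order <- as.integer(order)
  if (order < 1L) rp_value_error("order must be >= 1")
  if (n <= order + 1L) rp_value_error("signal too short for the polynomial order")
  axis <- if (is_spectrum(spec)) spec$axis else seq_len(n) - 1
  x01 <- seq(0, 1, length.out = n)
  basis <- cbind(1, stats::poly(x01, order, raw = FALSE))  # orthogonal: stable
  work <- y
  prev_dev <- Inf
  converged <- FALSE
  fitvals <- work
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    fitvals <- stats::lm.fit(basis, work)$fitted.values
    dev <- stats::sd(work - fitvals)
    if (dev == 0) { converged <- TRUE; break }
    if (is.finite(prev_dev) && abs(prev_dev - dev) / dev < tol) {
      converged <- TRUE
      break
    }
    work <- pmin(work, fitvals + dev)
    prev_dev <- dev
  }
  baseline_fit(
    baseline = fitvals, raman = y - fitvals, algorithm = "imodpoly",
    params = list(order = order, tol = tol, max_iter = max_iter,
                  iterations = iters, converged = converged),
    axis = axis)
}

# Sliding min/max with a centered flat structuring element; the window is
# truncated at the edges. Implemented by reducing over shifted copies
# (tests compare against an explicit per-sample loop oracle).
sliding_extremum <- function(y, window, op = c("min", "max")) {
  op <- match.arg(op)
  n <- length(y)
  half <- (window - 1L) %/% 2L
  pad <- if (op == "min") Inf else -Inf
  acc <- y
  for (k in seq_len(half)) {
    lead <- c(y[-seq_len(k)], rep(pad, k))
    lag <- c(rep(pad, k), y[seq_len(n - k)])
    acc <- if (op == "min") pmin(acc, lead, lag) else pmax(acc, lead, lag)
  }
  acc
}

#' Morphological baseline removal (MorphBR)
#'
#' Grayscale morphology with a flat structuring element of odd width
#' `window`: erosion (sliding min), dilation (sliding max) and the opening
#' (dilation of the erosion). The default variant takes the baseline as
#' `min(opening, (erosion + dilation)/2)`; `variant = "opening"` uses the
#' plain opening.
#'
#' @param spec A [spectrum()] or numeric vector.
#' @param window Odd structuring-element width, `3 <= window < length`.
#' @param variant `"min_half_sum"` (default) or `"opening"`.
#' @return A [baseline_fit()].
#' @export
morphbr <- function(spec, window = 101L,
                    variant = c("min_half_sum", "opening")) {
  variant <- match.arg(variant)
  y <- as_intensity(spec)
  n <- length(y)
  window <- as.integer(window)
  if (window >= n) rp_value_error("window must be smaller than the signal length")
  if (window < 3L || window %% 2L == 0L)
    rp_value_error("window must be odd and >= 3")
  axis <- if (is_spectrum(spec)) spec$axis else seq_len(n) - 1
  ero <- sliding_extremum(y, window, "min")
  dil <- sliding_extremum(y, window, "max")
  opening <- sliding_extremum(ero, window, "max")
  baseline <- switch(variant,
    min_half_sum = pmin(opening, (ero + dil) / 2),
    opening = opening)
  baseline_fit(baseline = baseline, raman = y - baseline,
               algorithm = "morphbr",
               params = list(window = window, variant = variant), axis = axis)
}

#' Run a baseline algorithm by name
#'
#' Thin dispatcher used by the benchmark sweeps and the pipeline driver.
#'
#' @param spec A [spectrum()] or numeric vector.
#' @param algorithm `"bubblefill"`, `"morphbr"` or `"imodpoly"`.
#' @param ... Passed to the algorithm ([bubble_params()] fields for
#'   bubblefill, `window`/`variant` for morphbr, `order`/`tol`/`max_iter`
#'   for imodpoly).
#' @return A [baseline_fit()].
#' @export
remove_baseline <- function(spec,
                            algorithm = c("bubblefill", "morphbr", "imodpoly"),
                            ...) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    bubblefill = {
      args <- list(...)
      if (length(args) == 1L && inherits(args[[1]], "bubble_params"))
        bubblefill(spec, args[[1]])
      else bubblefill(spec, do.call(bubble_params, args))
    },
    morphbr = morphbr(spec, ...),
    imodpoly = imodpoly(spec, ...))
}
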
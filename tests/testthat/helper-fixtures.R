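# Fixture generators and independent oracles shared across test files.
# Oracles are deliberately naive (loops, dense grids, closed forms) and
# never call the implementation paths they check.

# --- fixtures ---------------------------------------------------------------

# smooth broad-hump signal with optional noise
fix_smooth_signal <- function(n = 500, noise = 0, seed = 1) {
  withr_seed(seed, {
    x <- seq(0, 1, length.out = n)
    y <- 100 + 40 * exp(-(x - 0.4)^2 / (2 * 0.15^2)) + 10 * x
    y + rnorm(n, 0, noise)
  })
}

# acquisition of n_acc noisy copies of a smooth base signal
fix_acquisition <- function(n_acc = 5, n_pix = 800, noise = 4, seed = 1,
                            background = NULL, exposure_acq = 1,
                            exposure_bg = 1) {
  withr_seed(seed, {
    base <- 200 + 50 * sin(seq(0, 6, length.out = n_pix))
    A <- matrix(rep(base, n_acc), nrow = n_acc, byrow = TRUE) +
      matrix(rnorm(n_acc * n_pix, 0, noise), n_acc, n_pix)
    attr(A, "truth") <- base
    raw_acquisition(A, background = background, exposure_acq = exposure_acq,
                    exposure_bg = exposure_bg)
  })
}

# reference spectrum whose peak pixels follow a known quadratic pixel->shift
# map exactly (continuous centers via root solving)
fix_calibration_case <- function(seed, n = 900, n_peaks = 8, sigma_px = 3) {
  withr_seed(seed, {
    px <- 0:(n - 1)
    a <- runif(1, 300, 500)
    b <- runif(1, 1.2, 1.8)
    cc <- runif(1, -3e-4, -5e-5)
    truth <- a + b * px + cc * px^2
    shifts <- seq(min(truth) + 80, max(truth) - 80, length.out = n_peaks) +
      runif(n_peaks, -30, 30)
    centers <- vapply(shifts, function(sh) {
      r <- Re(polyroot(c(a - sh, b, cc)))
      r[r > 0 & r < n][1]
    }, numeric(1))
    y <- rowSums(vapply(centers,
                        function(p) exp(-(px - p)^2 / (2 * sigma_px^2)),
                        numeric(n))) + 0.02
    list(spec = spectrum(y, axis = px), shifts = shifts, truth = truth,
         px = px)
  })
}

# seed-scoped RNG without disturbing global state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# --- oracles ----------------------------------------------------------------

# Horner-scheme polynomial evaluation (ascending coefficients)
oracle_horner <- function(coeffs, x) {
  out <- rep(0, length(x))
  for (c_ in rev(coeffs)) out <- out * x + c_
  out
}

# windowed mean by explicit loop with symmetric edge shrinkage
oracle_moving_average <- function(y, window) {
  n <- length(y)
  half <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    out[i] <- mean(y[(i - h):(i + h)])
  }
  out
}

# sliding min/max by explicit per-sample loop
oracle_sliding <- function(y, window, fun) {
  n <- length(y)
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    fun(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# brute-force bubble lift: scan a dense grid of vertical offsets for the
# largest one keeping the arc at or below the signal on the interval
oracle_bubble_lift <- function(signal, left, right, anchored = "none") {
  idx <- left:right
  x <- idx - left
  w <- right - left
  shape <- switch(anchored,
    none = sqrt(pmax((w / 2)^2 - (x - w / 2)^2, 0)),
    left_edge = sqrt(pmax(w^2 - x^2, 0)),
    right_edge = sqrt(pmax(w^2 - (x - w)^2, 0)))
  lifts <- seq(min(signal[idx]) - max(shape) - 1, max(signal[idx]) + 1,
               length.out = 20000)
  ok <- vapply(lifts, function(L) all(shape + L <= signal[idx] + 1e-12),
               logical(1))
  best <- max(lifts[ok])
  list(lift = best, arc = shape + best, pitch = lifts[2] - lifts[1])
}

# one-hot ASSI closed form: peak maps to sqrt(N-1), the rest to
# -1/sqrt(N-1); mean of signed squares collapses to (N-2)/N
oracle_assi_onehot <- function(n) (n - 2) / n
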
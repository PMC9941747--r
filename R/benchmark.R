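# Best-case-tuning benchmark sweeps: every algorithm is run across its
# whole tuning grid and only its best (smallest) nMSE is compared, so no
# algorithm is penalized for an unlucky default.

default_tuning_grids <- function(n) {
  list(
    # min bubble width, fraction of the axis span
    bubblefill = c(0.01, 0.015, 0.02, 0.03, 0.04, 0.05, 0.07, 0.1, 0.15,
                   0.2, 0.3),
    # structuring-element window, as odd sample counts from span fractions
    morphbr = unique(vapply(
      c(0.015, 0.02, 0.03, 0.04, 0.05, 0.07, 0.1, 0.15, 0.2, 0.3),
      function(f) odd_at_most(max(3L, round(f * n)), n - 2L), integer(1))),
    imodpoly = 2:9                                        # polynomial order
  )
}

run_algorithm_at <- function(spec_vec, algorithm, param) {
  switch(algorithm,
    bubblefill = bubblefill(spec_vec, bubble_params(min_width = param)),
    morphbr = morphbr(spec_vec, window = as.integer(param)),
    imodpoly = imodpoly(spec_vec, order = as.integer(param)),
    rp_value_error(sprintf("unknown algorithm '%s'", algorithm)))
}

#' Sweep baseline algorithms over their tuning grids
#'
#' Runs each algorithm at every tuning-grid point on one synthetic
#' spectrum, scores the recovered Raman against the known target with
#' [nmse()], and reports the best case per algorithm. A failure at a grid
#' point is recorded as `Inf`, not fatal.
#'
#' @param spec A [synthetic_spectrum()].
#' @param algorithms Algorithms to compare.
#' @param tuning_grids Named list of per-algorithm grids; defaults cover
#'   min-width fractions (bubblefill), window widths (morphbr) and
#'   polynomial orders (imodpoly).
#' @return A [benchmark_result()] with a 1-column nMSE matrix and a
#'   `details` data frame of every grid point.
#' @export
sweep_benchmark <- function(spec,
                            algorithms = c("bubblefill", "morphbr",
                                           "imodpoly"),
                            tuning_grids = NULL) {
  if (!inherits(spec, "synthetic_spectrum"))
    rp_value_error("spec must be a synthetic_spectrum")
  n <- length(spec$spectrum)
  grids <- default_tuning_grids(n)
  if (!is.null(tuning_grids)) grids[names(tuning_grids)] <- tuning_grids
  if (any(lengths(grids[algorithms]) == 0L))
    rp_value_error("tuning grids must be non-empty")
  s <- spectrum(spec$spectrum, axis = spec$axis, axis_kind = "shift")
  details <- do.call(rbind, lapply(algorithms, function(alg) {
    grid <- grids[[alg]]
    err <- vapply(grid, function(p) {
      tryCatch(nmse(run_algorithm_at(s, alg, p)$raman, spec$raman_target),
               error = function(e) Inf)
    }, numeric(1))
    data.frame(algorithm = alg, param = as.numeric(grid), nmse = err)
  }))
  best <- vapply(algorithms,
                 function(alg) min(details$nmse[details$algorithm == alg]),
                 numeric(1))
  benchmark_result(
    algorithms = algorithms, rbr_grid = spec$sbr,
    tuning_grids = grids[algorithms],
    nmse = matrix(best, ncol = 1, dimnames = list(algorithms, spec$sbr)),
    details = details)
}

#' Benchmark algorithms across an RBR grid
#'
#' Replicates [sweep_benchmark()] over a grid of signal-to-baseline
#' ratios and seeds (fresh baseline draw and noise per seed) and reports
#' the per-RBR mean best-case nMSE per algorithm.
#'
#' @param raman_kind A [raman_peak_preset()] name.
#' @param baseline_kind `"smooth"` or `"bumpy"`.
#' @param rbr_grid Numeric vector of SBR/RBR values.
#' @param algorithms Algorithms to compare.
#' @param noise_sigma Gaussian noise SD on the normalized spectrum scale.
#' @param seeds Integer vector of seeds (one replicate each).
#' @param axis Axis for the generated spectra.
#' @param tuning_grids Optional per-algorithm grids (see
#'   [sweep_benchmark()]).
#' @return A [benchmark_result()]; `nmse` is algorithm x RBR (mean over
#'   seeds) and `details` holds every (seed, rbr, algorithm) best case.
#' @export
rbr_curve <- function(raman_kind = "tylenol_like",
                      baseline_kind = c("bumpy", "smooth"),
                      rbr_grid = c(0.01, 0.05, 0.1),
                      algorithms = c("bubblefill", "morphbr", "imodpoly"),
                      noise_sigma = 0, seeds = 1:10,
                      axis = seq(400, 1800, length.out = 1000),
                      tuning_grids = NULL) {
  baseline_kind <- match.arg(baseline_kind)
  if (length(rbr_grid) == 0L || length(seeds) == 0L)
    rp_value_error("rbr_grid and seeds must be non-empty")
  R <- make_raman_component(raman_peak_preset(raman_kind), axis)
  bmodel <- baseline_model(baseline_kind)
  details <- list()
  for (sd_ in seeds) {
    B <- make_baseline_component(bmodel, axis, seed = sd_)
    for (rb in rbr_grid) {
      sp <- generate_spectrum(R, B, sbr = rb, noise_sigma = noise_sigma,
                              seed = sd_ + 7919L, axis = axis)
      sw <- sweep_benchmark(sp, algorithms, tuning_grids)
      best <- sw$nmse[, 1]
      best_param <- vapply(algorithms, function(alg) {
        d <- sw$details[sw$details$algorithm == alg, ]
        d$param[which.min(d$nmse)]
      }, numeric(1))
      details[[length(details) + 1L]] <- data.frame(
        algorithm = algorithms, rbr = rb, seed = sd_,
        best_param = best_param, nmse = unname(best))
    }
  }
  details <- do.call(rbind, details)
  nm <- matrix(NA_real_, length(algorithms), length(rbr_grid),
               dimnames = list(algorithms, rbr_grid))
  for (alg in algorithms) {
    for (j in seq_along(rbr_grid)) {
      sel <- details$algorithm == alg & details$rbr == rbr_grid[j]
      nm[alg, j] <- mean(details$nmse[sel])
    }
  }
  benchmark_result(algorithms = algorithms, rbr_grid = rbr_grid,
                   tuning_grids = if (is.null(tuning_grids))
                     default_tuning_grids(length(axis))[algorithms]
                   else tuning_grids,
                   nmse = nm, details = details)
}
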
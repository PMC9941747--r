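test_that("Raman component is a unit-max Gaussian superposition", {
  axis <- seq(400, 1800, length.out = 700)
  one <- make_raman_component(peak_model(1000, 10, 2), axis)
  expect_equal(max(one), 1)
  expect_equal(which.max(one), which.min(abs(axis - 1000)))

  two <- make_raman_component(peak_model(c(700, 1400), c(8, 8), c(1, 1)),
                              axis)
  locmax <- which(diff(sign(diff(two))) < 0) + 1
  expect_length(locmax, 2L)
  expect_equal(max(two), 1)

  # pointwise brute-force Gaussian-sum oracle
  pm <- raman_peak_preset("pdms_like")
  got <- make_raman_component(pm, axis)
  want <- rep(0, length(axis))
  for (j in seq_along(pm$centers)) {
    want <- want + pm$amplitudes[j] *
      exp(-(axis - pm$centers[j])^2 / (2 * pm$widths[j]^2))
  }
  expect_equal(got, want / max(want), tolerance = 1e-13)

  expect_error(peak_model(numeric(0), numeric(0), numeric(0)),
               class = "ramanpipe_value_error")
})

test_that("baseline components have the stated morphology and determinism", {
  axis <- seq(400, 1800, length.out = 800)
  interior_maxima <- function(v) {
    # count local maxima robustly at the Raman-peak scale
    sm <- smooth_moving_average(v, 15L)
    sum(diff(sign(diff(sm))) < -1e-12)
  }
  for (seed in 1:8) {
    smth <- make_baseline_component(baseline_model("smooth"), axis, seed)
    expect_lte(interior_maxima(smth), 1)
    expect_true(all(smth >= 0))
    expect_equal(max(smth), 1)
    bumpy <- make_baseline_component(baseline_model("bumpy", n_humps = 4),
                                     axis, seed)
    expect_gte(interior_maxima(bumpy), 2)
    expect_true(all(bumpy >= 0))
  }
  a <- make_baseline_component(baseline_model("bumpy"), axis, 42)
  b <- make_baseline_component(baseline_model("bumpy"), axis, 42)
  expect_identical(a, b)
})

test_that("the mixing equation normalizes, degenerates and reproduces", {
  axis <- seq(400, 1800, length.out = 600)
  R <- make_raman_component(raman_peak_preset("nylon_like"), axis)
  B <- make_baseline_component(baseline_model("smooth"), axis, 3)

  clean <- generate_spectrum(R, B, sbr = 0.3, noise_sigma = 0, axis = axis)
  expect_identical(max(clean$spectrum), 1)

  no_raman <- generate_spectrum(R, B, sbr = 0, noise_sigma = 0, axis = axis)
  expect_equal(no_raman$spectrum, B / max(B))
  expect_identical(no_raman$raman_target, rep(0, length(axis)))

  noisy <- generate_spectrum(R, B, sbr = 0.3, noise_sigma = 0.01, seed = 11,
                             axis = axis)
  expect_equal(sd(noisy$spectrum - (clean$spectrum)), 0.01, tolerance = 0.15)
  again <- generate_spectrum(R, B, sbr = 0.3, noise_sigma = 0.01, seed = 11,
                             axis = axis)
  expect_identical(noisy$spectrum, again$spectrum)  # bit-identical under seed

  expect_error(generate_spectrum(rep(0, 10), rep(0, 10), 1),
               class = "ramanpipe_value_error")
})

test_that("cosmic-ray injection bookkeeping is exact", {
  acq <- fix_acquisition(n_acc = 4, n_pix = 300, noise = 2, seed = 7)
  none <- inject_cosmic_rays(acq, 0, 100)
  expect_equal(none$acquisition, acq)
  expect_identical(nrow(none$truth), 0L)

  inj <- inject_cosmic_rays(acq, 3, amplitude = 400, width_px = 3, seed = 2)
  expect_identical(nrow(inj$truth), 3L)
  diff_cells <- which(inj$acquisition$accumulations != acq$accumulations,
                      arr.ind = TRUE)
  expect_identical(nrow(diff_cells), 9L)  # 3 spikes x 3 px, disjoint
  for (k in 1:3) {
    tr <- inj$truth[k, ]
    seg <- inj$acquisition$accumulations[tr$accumulation,
                                         tr$px_start:tr$px_end]
    expect_true(all(seg > acq$accumulations[tr$accumulation,
                                            tr$px_start:tr$px_end] + 100))
  }
  expect_identical(
    inject_cosmic_rays(acq, 3, 400, 3, seed = 2)$truth, inj$truth)
})

test_that("nMSE matches hand arithmetic and its scaling identity", {
  expect_identical(nmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(nmse(c(0, 0), c(1, 1)), 0.5)
  for (seed in 1:20) {
    v <- withr_seed(seed, list(t = runif(30, 0.1, 1), c = rnorm(30)))
    expect_equal(nmse(7.3 * v$c, 7.3 * v$t), nmse(v$c, v$t),
                 tolerance = 1e-12)
  }
  expect_error(nmse(c(1, -1), c(1, -1)), class = "ramanpipe_value_error")
})

test_that("sweep_benchmark reports the grid optimum", {
  axis <- seq(400, 1800, length.out = 500)
  R <- make_raman_component(raman_peak_preset("nylon_like"), axis)
  B <- make_baseline_component(baseline_model("smooth"), axis, 8)
  sp <- generate_spectrum(R, B, sbr = 0.2, axis = axis)

  single <- sweep_benchmark(sp, algorithms = "imodpoly",
                            tuning_grids = list(imodpoly = 5L))
  expect_identical(nrow(single$details), 1L)
  expect_identical(single$nmse["imodpoly", 1], single$details$nmse[1])

  sw <- sweep_benchmark(sp)
  for (alg in sw$algorithms) {
    d <- sw$details[sw$details$algorithm == alg, ]
    expect_identical(sw$nmse[alg, 1], min(d$nmse))
    expect_true(all(sw$nmse[alg, 1] <= d$nmse))
  }
  expect_true(all(sw$nmse >= 0))
})

test_that("rbr_curve trends: error shrinks with RBR; smooth case is close", {
  axis <- seq(400, 1800, length.out = 500)
  res <- rbr_curve("nylon_like", "smooth", rbr_grid = c(0.05, 0.15, 0.5),
                   seeds = 1:3, axis = axis)
  for (alg in res$algorithms) {
    expect_true(all(diff(res$nmse[alg, ]) <= 0))  # easier at higher RBR
  }
  # Fig-9 regime, scaled: smooth baseline, modest RBR, noise 1% -> all three
  # algorithms land within 5x of one another
  withins <- vapply(1:4, function(seed) {
    B <- make_baseline_component(baseline_model("smooth"), axis, seed)
    R <- make_raman_component(raman_peak_preset("nylon_like"), axis)
    sp <- generate_spectrum(R, B, sbr = 0.15, noise_sigma = 0.01,
                            seed = seed + 40, axis = axis)
    v <- sweep_benchmark(sp)$nmse[, 1]
    max(v) / min(v)
  }, numeric(1))
  expect_true(all(withins < 5))
})
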
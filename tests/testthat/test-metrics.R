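test_that("moving average matches the brute-force oracle", {
  s <- spectrum(1:50)
  expect_equal(smooth_moving_average(s, 1L), s)
  expect_equal(smooth_moving_average(rep(3, 30), 7L), rep(3, 30))
  for (seed in 1:15) {
    y <- withr_seed(seed, rnorm(sample(30:120, 1)))
    w <- sample(c(3L, 5L, 11L, 21L), 1)
    expect_equal(smooth_moving_average(y, w), oracle_moving_average(y, w),
                 tolerance = 1e-12)
  }
  expect_error(smooth_moving_average(1:10, 4L),
               class = "ramanpipe_value_error")
})

test_that("min-max normalization pins the range or an anchor", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_minmax(spectrum(c(2, 4, 6)),
                                anchor_shift = 1)$intensity, c(0, 1, 2))
  for (seed in 1:200) {
    y <- withr_seed(seed, rnorm(50))
    out <- normalize_minmax(y)
    expect_identical(c(min(out), max(out)), c(0, 1))
  }
  expect_error(normalize_minmax(rep(1, 10)), class = "ramanpipe_value_error")
})

test_that("SNV yields mean 0 and population SD 1, and is idempotent", {
  expect_equal(snv(c(0, 2)), c(-1, 1))
  for (seed in 1:50) {
    y <- withr_seed(seed, rnorm(sample(10:500, 1), sd = runif(1, 0.1, 50)))
    out <- snv(y)
    expect_lt(abs(mean(out)), 1e-12)
    expect_lt(abs(sqrt(mean((out - mean(out))^2)) - 1), 1e-12)
    expect_equal(snv(out), out, tolerance = 1e-12)
  }
  expect_error(snv(rep(2, 5)), class = "ramanpipe_value_error")
})

test_that("RBR is the ratio of maxima", {
  expect_equal(rbr(c(0, 5, 1), c(10, 2, 3)), 0.5)
  expect_equal(rbr(rep(0, 4), c(1, 2, 1, 1)), 0)
  expect_error(rbr(c(1, 2), c(-1, 0)), class = "ramanpipe_value_error")
  # generator round trip: components of an sbr = 0.2 spectrum recover ~0.2
  axis <- seq(400, 1800, length.out = 500)
  R <- make_raman_component(raman_peak_preset("nylon_like"), axis)
  B <- make_baseline_component(baseline_model("smooth"), axis, seed = 5)
  sp <- generate_spectrum(R, B, sbr = 0.2, axis = axis)
  expect_equal(rbr(sp$raman_target, sp$baseline_component / max(
    sp$sbr * sp$raman_component + sp$baseline_component)), 0.2,
    tolerance = 0.2)
})

test_that("ASSI closed forms, bounds and affine invariance hold", {
  one_hot <- rep(0, 100); one_hot[17] <- 1
  expect_equal(assi(one_hot), oracle_assi_onehot(100), tolerance = 1e-12)
  expect_equal(assi(c(0, 2)), 0)

  # closed form over the full one-hot family
  for (n in c(3L, 10L, 101L, 555L, 1000L)) {
    v <- rep(0, n); v[1] <- 1
    expect_equal(assi(v), oracle_assi_onehot(n), tolerance = 1e-12)
  }

  # bounds + affine invariance on random shapes
  for (seed in 1:300) {
    y <- withr_seed(seed, {
      n <- sample(3:500, 1)
      switch(seed %% 3 + 1,
             rnorm(n),
             { v <- rep(0, n); v[sample(n, 1)] <- runif(1, 1, 100); v },
             cumsum(rnorm(n)))
    })
    if (sd(y) == 0) next
    a <- assi(y)
    expect_gte(a, -1)
    expect_lte(a, 1)
    expect_lt(abs(assi(3.7 * y + 11) - a), 1e-9)
  }

  # narrow single peak scores above many broad low humps
  x <- seq(0, 1, length.out = 800)
  wins <- vapply(1:60, function(seed) {
    withr_seed(seed, {
      narrow <- exp(-(x - runif(1, 0.2, 0.8))^2 / (2 * 0.004^2))
      broad <- rowSums(vapply(runif(10, 0.1, 0.9), function(c_) {
        0.1 * exp(-(x - c_)^2 / (2 * 0.08^2))
      }, numeric(800)))
      assi(narrow) > assi(broad)
    })
  }, logical(1))
  expect_gte(mean(wins), 0.99)

  expect_error(assi(rep(1, 10)), class = "ramanpipe_value_error")
})

test_that("quality tiers cut the batch at the stated percentiles", {
  # 10 spectra with strictly increasing ASSI: exactly 2 per tier
  batch <- lapply(1:10, function(k) {
    v <- rep(0, 100) + seq(0, 1, length.out = 100) * 0.01
    v[40] <- k  # taller spike -> higher ASSI
    v
  })
  scores <- vapply(batch, assi, numeric(1))
  expect_true(all(diff(scores) > 0))
  tiers <- quality_tiers(batch)
  expect_identical(as.vector(table(tiers$tier)[c("high", "average", "low")]),
                   c(2L, 2L, 2L))
  expect_identical(tiers$tier[order(tiers$assi)][1:2],
                   factor(c("low", "low"), levels = levels(tiers$tier)))

  # all-identical ASSI: deterministic tie-break by input order
  same <- replicate(10, { v <- rep(0, 50); v[10] <- 1; v },
                    simplify = FALSE)
  t2 <- quality_tiers(same)
  expect_identical(as.character(t2$tier[1:2]), c("low", "low"))
  expect_identical(as.character(t2$tier[9:10]), c("high", "high"))

  expect_error(quality_tiers(batch[1:4]), class = "ramanpipe_value_error")

  # spectra generated at higher sbr cluster tighter (higher correlation)
  axis <- seq(400, 1800, length.out = 500)
  R <- make_raman_component(raman_peak_preset("tylenol_like"), axis)
  make_at <- function(sbr, seed) {
    B <- make_baseline_component(baseline_model("bumpy"), axis, seed = seed)
    sp <- generate_spectrum(R, B, sbr = sbr, noise_sigma = 0.01,
                            seed = seed + 500, axis = axis)
    bubblefill(sp$spectrum, bubble_params(min_width = 0.05))$raman
  }
  high <- lapply(1:5, make_at, sbr = 1)
  low <- lapply(6:10, make_at, sbr = 0.02)
  mean_cor <- function(group) {
    m <- do.call(cbind, group)
    cm <- cor(m)
    mean(cm[upper.tri(cm)])
  }
  expect_gt(mean_cor(high), mean_cor(low))
  expect_gt(mean(vapply(high, assi, numeric(1))),
            mean(vapply(low, assi, numeric(1))))
})
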
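# Pseudo-Wilson statistics: s^2 computation, per-frame OLS fits, rolling
# averages, aggregates, outlier flags.

test_that("squared scattering vector matches closed forms and a reciprocal-basis oracle", {
  expect_equal(reflection_s2(unit_cell(10, 10, 10), data.frame(h = 1, k = 0, l = 0)),
               0.0025)
  # long-cell (0,0,1): s^2 = 1/(4 c^2)
  expect_equal(reflection_s2(unit_cell(69, 169, 288), data.frame(h = 0, k = 0, l = 1)),
               1 / (4 * 288^2))

  set.seed(501)
  for (i in 1:20) {
    cl <- random_cell()
    hkl <- matrix(sample(-8:8, 15, replace = TRUE), ncol = 3)
    hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
    # oracle: explicitly constructed reciprocal basis, s^2 = |h a* + k b* + l c*|^2 / 4
    M0 <- serialdx:::real_basis_from_cell(cl)
    recip <- t(solve(M0))                  # columns a*, b*, c*
    q <- t(recip %*% t(hkl))
    expect_equal(reflection_s2(cl, hkl), rowSums(q^2) / 4, tolerance = 1e-10)
  }
  expect_error(reflection_s2(unit_cell(10, 10, 10), data.frame(h = 0, k = 0, l = 0)),
               "not a valid reflection")
})

test_that("noiseless Wilson-model frames are recovered exactly", {
  set.seed(502)
  s2 <- runif(50, 0.001, 0.08)
  B0 <- 20; G0 <- 100
  fit <- wilson_fit(s2, G0 * exp(-2 * B0 * s2))
  expect_equal(fit$b, B0, tolerance = 1e-9)
  expect_equal(fit$g, G0, tolerance = 1e-9)
  expect_true(fit$ok)

  # two-point line: m = -20, B = 10, c = ln 100
  fit2 <- wilson_fit(c(0, 0.1), c(100, 100 * exp(-2)), min_reflections = 2)
  expect_equal(fit2$slope, -20)
  expect_equal(fit2$b, 10)
  expect_equal(fit2$intercept, log(100))
})

test_that("scaling intensities shifts the intercept by ln k and fixes B", {
  set.seed(503)
  s2 <- runif(100, 0.001, 0.08)
  I <- 50 * exp(-2 * 12 * s2) * exp(rnorm(100, 0, 0.3))
  f1 <- wilson_fit(s2, I)
  f2 <- wilson_fit(s2, 7.5 * I)
  expect_equal(f2$b, f1$b, tolerance = 1e-10)
  expect_equal(f2$intercept - f1$intercept, log(7.5), tolerance = 1e-10)
})

test_that("non-positive intensities are dropped and counted, fits refused when thin", {
  set.seed(504)
  s2 <- runif(30, 0.01, 0.05)
  I <- 10 * exp(-2 * 5 * s2)
  base <- wilson_fit(s2, I)
  # appending non-positive intensities changes nothing but the counter
  mixed <- wilson_fit(c(s2, 0.02, 0.03), c(I, 0, -4))
  expect_equal(mixed$slope, base$slope)
  expect_equal(mixed$n_dropped_nonpositive, 2L)
  expect_equal(mixed$n_used, base$n_used)

  refused <- wilson_fit(s2[1:5], I[1:5])             # below min_reflections
  expect_false(refused$ok)
  novar <- wilson_fit(rep(0.02, 30), I)              # zero variance in x
  expect_false(novar$ok)
})

test_that("OLS standard errors give nominal coverage for B", {
  set.seed(505)
  n_frames <- 150
  hits <- 0
  for (i in 1:n_frames) {
    B0 <- rnorm(1, 15, 2)
    s2 <- runif(200, 0.001, 0.08)
    I <- 100 * exp(-2 * B0 * s2) * exp(rnorm(200, 0, 0.3))
    f <- wilson_fit(s2, I)
    se_b <- f$se_slope / 2
    hits <- hits + (abs(f$b - B0) <= 1.96 * se_b)
  }
  expect_gt(hits / n_frames, 0.90)
  expect_lt(hits / n_frames, 0.99)
})

test_that("rolling average is exact on degenerate and linear inputs", {
  pts <- tibble::tibble(s2 = seq(0.01, 0.1, length.out = 20), log_i = rnorm(20))
  expect_equal(rolling_average(pts, 1), dplyr::arrange(pts, s2))
  const <- tibble::tibble(s2 = seq(0.01, 0.1, length.out = 20), log_i = 3)
  expect_true(all(rolling_average(const, 5)$log_i == 3))
  # a line stays a line under windowed means of both coordinates
  lin <- tibble::tibble(s2 = seq(0, 1, length.out = 50), log_i = 2 - 30 * seq(0, 1, length.out = 50))
  ra <- rolling_average(lin, 7)
  expect_equal(ra$log_i, 2 - 30 * ra$s2, tolerance = 1e-12)
  expect_equal(nrow(ra), 50 - 7 + 1)
  expect_error(rolling_average(lin, 51), "window")
})

test_that("aggregate statistics pool frames coherently", {
  # identical noiseless frames: pooled slope equals the per-frame slope
  cfg <- two_form_config(n_frames = 4, jitter_edge = 0, jitter_angle = 0,
                         noise_sd = 0, partiality_range = c(1, 1), b_sd = 0,
                         log_g_sd = 0, misindex_fraction = 0, seed = 506)
  ds <- generate_frames(cfg)
  stats <- aggregate_intensity(ds$frames)
  per_frame <- stats$fits$slope[stats$fits$ok]
  expect_equal(stats$pooled_fit$slope, per_frame[1], tolerance = 1e-6)
  expect_lt(stats$trend, 0)
  expect_equal(nrow(stats$fits), 4)

  # noisy data keep the monotonically decreasing pooled trend
  ds2 <- generate_frames(two_form_config(n_frames = 30, seed = 507))
  stats2 <- aggregate_intensity(ds2$frames)
  expect_lt(stats2$pooled_fit$slope, 0)
  g <- glance(stats2)
  expect_equal(g$n_fit, sum(stats2$fits$ok))
})

test_that("outlier filter flags aberrant fits and nothing else", {
  base <- tibble::tibble(
    frame_id = sprintf("f%03d", 1:100),
    n_used = 100L, n_dropped_nonpositive = 0L,
    slope = c(rnorm(99, -30, 2), -1000), intercept = rnorm(100, log(100), 0.1),
    se_slope = 1, se_intercept = 0.1,
    b = NA_real_, g = NA_real_, ok = TRUE
  )
  set.seed(508)
  flagged <- flag_outlier_frames(base)
  expect_true(flagged$flagged[100])
  expect_equal(sum(flagged$flagged), 1)
  expect_equal(nrow(attr(flagged, "survivors")), 99)

  # all identical: zero flags
  ident <- base; ident$slope <- -30; ident$intercept <- 1
  expect_equal(sum(flag_outlier_frames(ident)$flagged), 0)
  expect_error(flag_outlier_frames(base[1:3, ]), "at least 5")
})

test_that("mis-indexed synthetic frames are flagged with high recall", {
  rec <- fp <- nmis <- ninl <- 0
  for (s in 1:5) {
    ds <- generate_frames(two_form_config(n_frames = 100, seed = 508 + s))
    fits <- flag_outlier_frames(wilson_fits(ds$frames))
    mis <- ds$truth$misindexed
    rec <- rec + sum(fits$flagged & mis); nmis <- nmis + sum(mis)
    fp <- fp + sum(fits$flagged & !mis); ninl <- ninl + sum(!mis)
  }
  expect_gte(rec / nmis, 0.9)
  expect_lte(fp / ninl, 0.05)
})
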
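# Lab-frame axis projections, spherical density, Bingham uniformity test.

test_that("real axes follow from the reciprocal basis by duality", {
  # cubic a=10 aligned with the lab axes
  axes <- real_axes_from_reciprocal(diag(1 / 10, 3))
  expect_equal(axes, diag(3), ignore_attr = TRUE)

  set.seed(401)
  # rotation equivariance
  m <- matrix(rnorm(9), 3, 3)
  R <- random_rotations(1)[[1]]
  expect_equal(real_axes_from_reciprocal(m %*% t(R)),
               real_axes_from_reciprocal(m) %*% t(R))

  # dual-basis identity: h-th real axis (pre-normalization) . k-th reciprocal = delta_hk
  for (i in 1:20) {
    m <- matrix(rnorm(9), 3, 3)
    if (abs(det(m)) < 1e-3) next
    axes <- real_axes_from_reciprocal(m)
    # recover pre-normalization real vectors via the inverse
    real <- solve(m)                       # columns a, b, c
    expect_equal(t(real) %*% t(m), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(axes, t(real / rep(sqrt(colSums(real^2)), each = 3)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }

  expect_error(real_axes_from_reciprocal(matrix(0, 3, 3)), "singular")
})

test_that("latitude/longitude follow the beam/up/right convention", {
  expect_equal(latlong_of_vector(c(0, 0, 1)), c(lat = 0, lon = 0))
  expect_equal(latlong_of_vector(c(0, 1, 0))[["lat"]], 90)
  expect_equal(latlong_of_vector(c(1, 0, 0)), c(lat = 0, lon = 90))
  expect_equal(latlong_of_vector(c(-1, 0, 0)), c(lat = 0, lon = -90))
  expect_error(latlong_of_vector(c(0, 0, 0)), "zero")
  expect_error(latlong_of_vector(c(0, 0, 2)), "unit")
})

test_that("axis projection emits antipodal pairs for every oriented frame", {
  frames <- frames_tbl(c("f1", "f2"),
                       as_cells_tbl(rbind(unit_cell(10, 10, 10), unit_cell(10, 10, 10))),
                       orientation = list(diag(1 / 10, 3), NULL))
  expect_message(proj <- project_axes(frames), "skipped 1")
  expect_equal(nrow(proj), 6)              # 3 axes x 2 antipodes, one frame
  expect_equal(attr(proj, "n_skipped"), 1L)

  # identity-oriented cubic frame: a East, b North pole, c along beam
  a_row <- proj[proj$axis == "a" & proj$hemisphere == 1, ]
  expect_equal(c(a_row$lat, a_row$lon), c(0, 90))
  b_row <- proj[proj$axis == "b" & proj$hemisphere == 1, ]
  expect_equal(b_row$lat, 90)
  c_row <- proj[proj$axis == "c" & proj$hemisphere == 1, ]
  expect_equal(c(c_row$lat, c_row$lon), c(0, 0))

  # antipode relations: lat2 = -lat1, lon2 = lon1 +- 180
  for (ax in c("a", "b", "c")) {
    p1 <- proj[proj$axis == ax & proj$hemisphere == 1, ]
    p2 <- proj[proj$axis == ax & proj$hemisphere == -1, ]
    expect_equal(p2$lat, -p1$lat, tolerance = 1e-9)
    dlon <- (p2$lon - p1$lon) %% 360
    expect_equal(dlon, 180, tolerance = 1e-9)
  }
})

test_that("spherical density peaks at a point mass, is flat for uniform input, and normalizes", {
  # single point mass: grid maximum at the nearest node
  pm <- tibble::tibble(lat = 41, lon = -59)
  d <- spherical_density(pm, kappa = 50, spacing = 2)
  top <- d[which.max(d$density), ]
  expect_equal(c(top$lat, top$lon), c(41, -59))

  # near-uniform Fibonacci grid of directions: flat within 5%
  n <- 3000; i <- seq(0, n - 1); phi <- (1 + sqrt(5)) / 2
  unif <- tibble::tibble(lat = asin(2 * (i + 0.5) / n - 1) * 180 / pi,
                         lon = ((i / phi) %% 1) * 360 - 180)
  du <- spherical_density(unif, kappa = 50, spacing = 4)
  expect_lt((max(du$density) - min(du$density)) / mean(du$density), 0.05)

  # equal-area quadrature: integral over the sphere = 1 within 1%
  for (dd in list(d, du)) {
    sp <- sort(unique(diff(sort(unique(dd$lon)))))[1] * pi / 180
    w <- cos(dd$lat * pi / 180) * sp^2
    expect_equal(sum(dd$density * w), 1, tolerance = 0.01)
  }
  expect_error(spherical_density(pm[0, ]), "no projections")
})

test_that("Bingham statistic hits its closed forms at the extremes", {
  # all axes identical: tau1 = 1, S = (15N/2)(2/3)
  X <- matrix(rep(c(0, 0, 1), 12), ncol = 3, byrow = TRUE)
  r <- bingham_test(X)
  expect_equal(r$tau1, 1)
  expect_equal(r$statistic, (15 * 12 / 2) * (2 / 3))
  expect_lt(r$p_value, 1e-10)

  # equal counts along the three lab axes: T = I/3, S = 0, p = 1
  X3 <- rbind(diag(3), diag(3), diag(3), diag(3))
  r3 <- bingham_test(X3)
  expect_equal(r3$statistic, 0, tolerance = 1e-12)
  expect_equal(r3$p_value, 1)

  expect_error(bingham_test(diag(3)), "at least 10")
})

test_that("Bingham statistic is rotation invariant and calibrated under the null", {
  set.seed(402)
  X <- matrix(rnorm(90), ncol = 3)
  X <- X / sqrt(rowSums(X^2))
  R <- random_rotations(1)[[1]]
  expect_equal(bingham_test(X)$statistic, bingham_test(X %*% t(R))$statistic,
               tolerance = 1e-9)

  rej <- mean(replicate(400, {
    U <- matrix(rnorm(300), ncol = 3)
    bingham_test(U)$p_value < 0.05
  }))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("vMF-biased orientations are detected with high power", {
  set.seed(403)
  rej <- mean(replicate(100, {
    bingham_test(sample_vmf(100, c(0, 1, 0), kappa = 5))$p_value < 0.05
  }))
  expect_gte(rej, 0.9)

  # per-axis tests on a generated biased dataset reject for the biased axis
  ds <- generate_frames(two_form_config(n_frames = 100, seed = 404,
                                        orientation_model = "vmf",
                                        orientation_kappa = 5))
  bt <- bingham_tests(ds$frames)
  expect_equal(sort(bt$axis), c("a", "b", "c"))
  expect_lt(bt$p_value[bt$axis == "c"], 0.05)   # c axis is the concentrated one
})

test_that("rotating all orientation matrices rotates the density and fixes S", {
  ds <- generate_frames(two_form_config(n_frames = 30, seed = 405))
  R <- rotation_about_lab_z <- serialdx:::rotation_about(c(0, 1, 0), pi / 2)
  rot <- ds$frames
  rot$orientation <- lapply(rot$orientation, function(m) m %*% t(R))
  b1 <- bingham_tests(ds$frames); b2 <- bingham_tests(rot)
  expect_equal(b1$statistic, b2$statistic, tolerance = 1e-9)

  # the density map rotates with the frames: compare on rotated grid points
  p1 <- project_axes(ds$frames); p2 <- project_axes(rot)
  d1 <- spherical_density(p1[p1$axis == "c", ], spacing = 10)
  d2 <- spherical_density(p2[p2$axis == "c", ], spacing = 10)
  # a 90 degree rotation about lab y maps lon -> lon + 90 at equal lat
  d1_shift <- d1
  d1_shift$lon <- ((d1$lon + 90 + 180) %% 360) - 180
  merged <- merge(d1_shift, d2, by = c("lat", "lon"))
  expect_equal(merged$density.x, merged$density.y, tolerance = 1e-6)
})
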
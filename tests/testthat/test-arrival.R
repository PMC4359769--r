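test_that("half-height upper bound: triangle, monotone fallback, errors", {
  G <- dense_tac(triangle_fun)
  expect_equal(half_height_upper_bound(G), 450, tolerance = 1e-2)

  rising <- dense_tac(function(t) t / 600)
  expect_equal(half_height_upper_bound(rising),
               max(rising$schedule$mid_time))

  expect_error(half_height_upper_bound(dense_tac(function(t) 0 * t)),
               "unfittable")
})

test_that("upper bound tracks the analytic half-crossing of the bolus profile", {
  truth <- sim_truth(v = 0.368, s = 0.00084)
  sim <- observe_plant(truth)
  for (i in c(1, 4, 6)) {
    kf <- solve_trapping_rate(rebase_to_administration(sim$curves[[i]], 60))
    ub <- half_height_upper_bound(kf$G)
    # falling half-height of the delayed smoothed rectangle:
    # x/v + 3 sigma + duration (trapped pedestal shifts it only slightly)
    analytic <- truth$roi_positions_mm[i] / truth$v +
      3 * truth$dispersion_sigma0_s + truth$admin_duration_s
    expect_lt(abs(ub - analytic), 60)  # within one (1 min) frame
  }
})

test_that("mean arrival time reproduces centroids of simple shapes", {
  # rectangle on [100, 200): centroid 150
  G <- dense_tac(rect_fun, t_end = 300)
  expect_equal(mean_arrival_time(G, 200), 150, tolerance = 0.01)
  # symmetric triangle, untruncated: centroid 300
  tri <- dense_tac(triangle_fun)
  expect_equal(mean_arrival_time(tri, Inf), 300, tolerance = 0.01)
})

test_that("truncated-triangle arrival time matches dense quadrature", {
  tri <- dense_tac(triangle_fun)
  # independent oracle: brute-force quadrature at dt = 0.01 s
  tt <- seq(0, 450, by = 0.01)
  g <- triangle_fun(tt)
  oracle <- sum(tt * g) / sum(g)
  expect_equal(mean_arrival_time(tri, 450), oracle, tolerance = 1e-3)
})

test_that("mean arrival time is translation-equivariant and scale-invariant", {
  f <- function(t) exp(-(t - 250)^2 / (2 * 40^2))
  G <- dense_tac(f, t_end = 600)
  base <- mean_arrival_time(G, 400)
  # scale invariance: exact
  G10 <- tac(G$schedule, 10 * G$values)
  expect_equal(mean_arrival_time(G10, 400), base, tolerance = 1e-12)
  # translation by 60 s (curve vanishes at its leading samples)
  Gshift <- dense_tac(function(t) f(t - 60), t_end = 660)
  expect_equal(mean_arrival_time(Gshift, 460), base + 60, tolerance = 1e-6)
})

test_that("arrival time is nondecreasing in the upper bound for unimodal curves", {
  G <- dense_tac(triangle_fun)
  ubs <- seq(150, 600, by = 50)
  mats <- vapply(ubs, function(ub) mean_arrival_time(G, ub), numeric(1))
  expect_true(all(diff(mats) > 0))
})

test_that("leading-edge half-height arrival behaves on simple shapes", {
  expect_equal(half_height_arrival_time(dense_tac(triangle_fun)), 150,
               tolerance = 1)
  expect_equal(half_height_arrival_time(dense_tac(rect_fun, t_end = 300)),
               100, tolerance = 1)
  # two synthetic positions delta-x apart: edge times differ by delta-x / v
  truth <- sim_truth(v = 0.4, s = 0.0005)
  t_dense <- seq(0, 1200, by = 1)
  sched <- frame_schedule(t_dense, rep(1, length(t_dense)))
  edges <- vapply(c(10, 26), function(x) {
    half_height_arrival_time(
      tac(sched, free_curve_at_position(truth, x, sched$mid_time)))
  }, numeric(1))
  expect_equal(diff(edges), 16 / 0.4, tolerance = 0.5)
})

test_that("velocity regression: exact lines, two points, degeneracy", {
  v <- fit_velocity(c(100, 200, 300), c(10, 20, 30))
  expect_equal(v$V_mm_s, 0.1)
  expect_equal(v$intercept_mm, 0)
  expect_equal(v$r_squared, 1)
  v2 <- fit_velocity(c(120, 220), c(8, 33))
  expect_equal(v2$V_mm_s, 25 / 100)
  expect_error(fit_velocity(c(100, 100), c(5, 10)), "degenerate")
  expect_error(fit_velocity(100, 5), "at least 2")
})

test_that("trapping per unit length reproduces the reference ratios", {
  expect_equal(round(trapping_per_length(0.000287, 0.326), 5), 0.00088)
  expect_equal(round(trapping_per_length(0.000280, 0.214), 5), 0.00131)
  expect_equal(trapping_per_length(0, 1), 0)
  expect_error(trapping_per_length(1e-4, 0), "positive")
  expect_error(trapping_per_length(1e-4, -0.2), "positive")
})

test_that("unit conversions match the reporting conventions and round-trip", {
  expect_equal(convert_units(0.368, "mm/s", "cm/min"), 2.208)
  expect_equal(convert_units(0.000253, "1/s", "1/min"), 0.01518)
  expect_equal(convert_units(0.00084, "1/mm", "1/cm"), 0.0084)
  expect_equal(convert_units(0.015, "fraction", "percent"), 1.5)
  pairs <- list(c("1/s", "1/min"), c("mm/s", "cm/min"),
                c("1/mm", "1/cm"), c("fraction", "percent"))
  for (p in pairs) {
    x <- pi
    expect_equal(convert_units(convert_units(x, p[1], p[2]), p[2], p[1]), x)
  }
  expect_error(convert_units(1, "mm/s", "1/min"), "unsupported")
})
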
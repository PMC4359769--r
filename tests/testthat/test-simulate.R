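test_that("pure advection conserves the bolus; trapping attenuates it exponentially", {
  t <- seq(0, 2000, by = 1)
  free0 <- sim_truth(v = 0.3, s = 0)
  areas <- vapply(c(0, 10, 25), function(x) {
    sum(free_curve_at_position(free0, x, t))
  }, numeric(1))
  # equal up to the ~1e-4 acausal tail clipped at t = 0 near the node
  expect_equal(areas[2] / areas[1], 1, tolerance = 1e-4)
  expect_equal(areas[3] / areas[1], 1, tolerance = 1e-4)

  trapping <- sim_truth(v = 0.3, s = 0.001)
  a1 <- sum(free_curve_at_position(trapping, 10, t))
  a2 <- sum(free_curve_at_position(trapping, 22, t))
  expect_equal(a2 / a1, exp(-0.001 * 12), tolerance = 1e-6)
})

test_that("bolus argmax moves at exactly the transport velocity", {
  truth <- sim_truth(v = 0.45, s = 0.0008)
  t <- seq(0, 1500, by = 0.1)
  tmax <- vapply(c(5, 23), function(x) {
    t[which.max(free_curve_at_position(truth, x, t))]
  }, numeric(1))
  expect_equal(diff(tmax), 18 / 0.45, tolerance = 0.2)
})

test_that("trapped curve integrates the free curve with rate s*v", {
  truth <- sim_truth(v = 0.3, s = 0.001)
  t <- seq(0, 3000, by = 1)
  B <- trapped_curve_at_position(truth, 15, t)
  expect_true(all(diff(B) >= 0))
  G <- free_curve_at_position(truth, 15, t)
  expect_equal(B[length(B)] / sum(diff(t) * (G[-1] + G[-length(G)]) / 2),
               0.3 * 0.001, tolerance = 1e-6)
  expect_equal(trapped_curve_at_position(sim_truth(v = 0.3, s = 0), 15, t),
               rep(0, length(t)))
})

test_that("observation is reproducible under a fixed seed", {
  truth <- sim_truth(v = 0.368, s = 0.00084, noise_cv = 0.05, rng_seed = 99)
  s1 <- observe_plant(truth)
  s2 <- observe_plant(truth)
  expect_identical(lapply(s1$curves, `[[`, "values"),
                   lapply(s2$curves, `[[`, "values"))
  expect_length(s1$curves, 6)
  expect_length(s1$curves[[1]]$values, 28)
})

test_that("noise-free mean arrival times are linear in position before binning", {
  truth <- sim_truth(v = 0.35, s = 0.0007)
  sched <- frame_schedule(seq(0, 1799), rep(1, 1800))
  xs <- seq(5, 30, by = 5)
  mats <- vapply(xs, function(x) {
    G <- tac(sched, free_curve_at_position(truth, x, sched$mid_time))
    mean_arrival_time(G, half_height_upper_bound(G))
  }, numeric(1))
  fit <- lm(mats ~ xs)
  expect_equal(unname(coef(fit)[2]), 1 / 0.35, tolerance = 1e-3)
  expect_gt(summary(fit)$r.squared, 1 - 1e-8)
})

test_that("the full pipeline recovers the study-scale parameters from clean data", {
  for (truth in reference_truths()) {
    sim <- observe_plant(truth)
    fit <- fit_transport(sim$curves, sim$manifest)
    sv_true <- truth$s * truth$v
    expect_equal(fit$sv_mean, sv_true, tolerance = 0.05)
    expect_equal(fit$V_mm_s, truth$v, tolerance = 0.02)
    expect_equal(fit$s_per_mm, truth$s, tolerance = 0.07)
  }
})

test_that("simulated cohorts are reproducible and span the study design", {
  c1 <- simulate_cohort(n_plants = 3, seed = 11)
  c2 <- simulate_cohort(n_plants = 3, seed = 11)
  expect_length(c1, 3)
  expect_identical(c1[[2]]$curves[[1]]$values, c2[[2]]$curves[[1]]$values)
  for (sim in c1) {
    n <- length(sim$truth$roi_positions_mm)
    expect_true(n >= 5 && n <= 8)
    expect_true(sim$truth$v >= 0.214 && sim$truth$v <= 0.566)
    expect_true(sim$truth$s >= 0.00034 && sim$truth$s <= 0.00131)
    expect_true(sim$manifest$administration_duration_s %in% c(180, 240, 300))
    expect_length(sim$curves, n)
  }
  expect_identical(vapply(c1, function(s) s$manifest$plant_id, character(1)),
                   c("sim1", "sim2", "sim3"))
})
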
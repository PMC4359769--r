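test_that("degenerate trapping inputs give identically zero trapped curves", {
  t <- seq(0, 1000, by = 10)
  expect_equal(trapped_march(t, runif(length(t)), 0), rep(0, length(t)))
  expect_equal(trapped_march(t, rep(0, length(t)), 0.001),
               rep(0, length(t)))
  expect_error(trapped_march(t, rep(1, length(t)), -0.1), "non-negative")
})

test_that("march on constant M matches the closed form c(1 - exp(-sv t))", {
  t <- 0:1000
  c0 <- 2.5
  B <- trapped_march(t, rep(c0, length(t)), 0.001)
  expect_equal(B, c0 * (1 - exp(-0.001 * t)), tolerance = 1e-4)
})

test_that("march agrees with a refined-grid stiff ODE solve on the real schedule", {
  skip_if_not_installed("deSolve")
  sim <- observe_plant(sim_truth(v = 0.368, s = 0.00084))
  M <- rebase_to_administration(sim$curves[[3]], 60)
  tm <- M$schedule$mid_time
  Mfun <- approxfun(c(0, tm), c(0, M$values), rule = 2)
  ode_oracle <- function(sv) {
    grid <- sort(unique(c(seq(0, max(tm), length.out = 100 * length(tm)), tm)))
    sol <- deSolve::lsoda(c(B = 0), grid,
                          function(t, y, p) list(sv * (Mfun(t) - y)),
                          NULL, rtol = 1e-10, atol = 1e-14)
    sol[match(tm, sol[, 1]), 2]
  }
  # at the trapping-rate scale observed in stems the march is well inside
  # 1e-3 of the true solution; the error grows as (sv * frame)^2
  for (sv in c(1e-4, 2.5e-4, 6e-4)) {
    rel <- max(abs(trapped_march(tm, M$values, sv) - ode_oracle(sv))) /
      max(ode_oracle(sv))
    expect_lt(rel, 1e-3)
  }
  rel_fast <- max(abs(trapped_march(tm, M$values, 2e-3) - ode_oracle(2e-3))) /
    max(ode_oracle(2e-3))
  expect_lt(rel_fast, 1e-2)
})

test_that("B(t_f; sv) is nondecreasing in sv where the solver brackets roots", {
  sched <- standard_frame_schedule()
  set.seed(7)
  # global monotonicity holds for nondecreasing M (B always lags M, so a
  # faster rate can only trap more by t_f) ...
  for (rep in 1:5) {
    vals <- cumsum(runif(28)) * runif(1, 0.5, 2)
    svs <- seq(0, 2e-3, length.out = 25)
    Btf <- vapply(svs, function(sv) {
      B <- trapped_march(sched$mid_time, vals, sv)
      approx(sched$mid_time, B, xout = 3300)$y
    }, numeric(1))
    expect_true(all(diff(Btf) >= -1e-12))
  }
  # ... and locally, around the physical root, for bolus-shaped curves
  # (beyond ~1/t_f the early overshoot starts to decay back toward M(t_f))
  sim <- observe_plant(sim_truth(v = 0.368, s = 0.00084))
  M <- rebase_to_administration(sim$curves[[3]], 60)
  svs <- seq(0, 4e-4, length.out = 25)
  Btf <- vapply(svs, function(sv) {
    B <- trapped_march(M$schedule$mid_time, M$values, sv)
    approx(M$schedule$mid_time, B, xout = 3300)$y
  }, numeric(1))
  expect_true(all(diff(Btf) > 0))
})

test_that("conservation and irreversibility hold for fitted curves", {
  sim <- observe_plant(sim_truth(v = 0.3, s = 0.001))
  M <- rebase_to_administration(sim$curves[[2]], 60)
  fit <- solve_trapping_rate(M)
  # G + B = M exactly at every frame
  expect_identical(fit$G$values + fit$B$values, M$values)
  # clean data: M >= B throughout, so B is nondecreasing
  expect_true(all(M$values - fit$B$values >= -1e-12))
  expect_true(all(diff(fit$B$values) >= -1e-12))
  # final condition met to solver tolerance
  expect_lt(abs(fit$residual), 1e-6 * max(M$values))
})

test_that("the solver recovers the generator's trapping rate within 1%", {
  truth <- sim_truth(v = 0.368, s = 0.000253 / 0.368)  # sv_true = 0.000253
  sim <- observe_plant(truth)
  for (cv in sim$curves[c(1, 4, 6)]) {
    fit <- solve_trapping_rate(rebase_to_administration(cv, 60))
    expect_equal(fit$sv, 0.000253, tolerance = 0.01)
  }
})

test_that("constant curves: target 1 cannot be met, target 0.8 has a closed form", {
  t <- seq(0, 3400, by = 1)
  M <- tac(frame_schedule(t, rep(1, length(t))), rep(3, length(t)))
  expect_error(solve_trapping_rate(M, t_f = 3300),
               "inconsistent with irreversible trapping")
  fit <- solve_trapping_rate(M, t_f = 3300, target_fraction = 0.8)
  expect_equal(fit$sv, -log(0.2) / 3300, tolerance = 1e-3)
})

test_that("unfittable curves are reported", {
  sched <- standard_frame_schedule()
  expect_error(solve_trapping_rate(tac(sched, rep(0, 28))), "unfittable")
  expect_error(solve_trapping_rate(tac(sched, rep(1, 28)),
                                   target_fraction = 1.5), "\\(0, 1]")
})

test_that("sensitivity sweep: sv is nondecreasing in the target fraction", {
  sim <- observe_plant(sim_truth(v = 0.25, s = 0.0008))
  M <- rebase_to_administration(sim$curves[[3]], 60)
  fits <- sensitivity_fraction_sweep(M, fractions = c(0.5, 0.8, 1))
  svs <- vapply(fits, `[[`, numeric(1), "sv")
  expect_true(all(diff(svs) > 0))
  # a sweep over [1.0] reproduces the plain solve
  expect_equal(sensitivity_fraction_sweep(M, fractions = 1)[[1]]$sv,
               solve_trapping_rate(M)$sv)
})
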
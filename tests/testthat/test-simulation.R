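test_that("an untreated typical patient holds the baseline indefinitely", {
  pop <- population_parameters()
  traj <- simulate_individual(pop, untreated_regimen(),
                              grid = seq(0, 24, 0.25))
  expect_true(all(abs(traj$plt_total - 90.5) < 1e-5))
  expect_true(all(abs(traj$plt_pat - 90.5) < 1e-5))
  expect_true(all(traj$plt_gt == 0))
})

test_that("the graft cascade matches a matrix-exponential oracle when linear", {
  # gamma = 0 and hct0 = 0 make the graft side a linear compartment chain:
  # Graft1 -> Graft2 -> HSC_GT (self-renewing) -> TR1..TR3 -> PLT_GT
  pop <- population_parameters(gamma = 0, hct0 = 0)
  traj <- simulate_individual(pop, typical_regimen(),
                              grid = seq(-30, 60, 0.5), full_state = TRUE)
  kgr <- 2 / 1.5
  kgt <- transit_rate(7.0, 3)
  A <- matrix(0, 7, 7)  # states: Graft1, Graft2, HSC_GT, TR1..3, PLT_GT
  A[1, 1] <- -kgr
  A[2, 1] <- kgr; A[2, 2] <- -kgr
  A[3, 2] <- kgr                     # production cancels elimination at
  A[4, 3] <- kgt; A[4, 4] <- -kgt    # gamma = 0, hct = 0
  A[5, 4] <- kgt; A[5, 5] <- -kgt
  A[6, 5] <- kgt; A[6, 6] <- -kgt
  A[7, 6] <- kgt; A[7, 7] <- -kgt
  x0 <- c(72.4, 0, 0, 0, 0, 0, 0)
  ts <- seq(0.5, 60, 0.5)
  oracle <- t(vapply(ts, function(t)
    as.numeric(Matrix::expm(A * t) %*% x0), numeric(7)))
  sim <- traj$state[match(ts, traj$time),
                    c("Graft1", "Graft2", "HSC_GT", "TR1_GT", "TR2_GT",
                      "TR3_GT", "PLT_GT")]
  # < 0.1% relative error wherever the oracle is not essentially zero
  big <- oracle > 1e-6 * 72.4
  expect_lt(max(abs(sim[big] - oracle[big]) / oracle[big]), 1e-3)
})

test_that("total platelets are the patient plus graft contributions, >= 0", {
  pop <- population_parameters()
  set.seed(4)
  for (i in 1:5) {
    ind <- sample_individual_parameters(pop, seed = 100 + i)
    reg <- if (i %% 2) atg_regimen() else typical_regimen()
    sim <- simulate_with_transfusions(ind, reg, generate_tp_series(seed = i))
    traj <- sim$trajectory
    expect_equal(traj$plt_total, traj$plt_pat + traj$plt_gt)
    expect_true(all(traj$plt_total > -1e-8))
    expect_true(all(traj$plt_pat > -1e-8))
    expect_true(all(traj$plt_gt > -1e-8))
  }
})

test_that("log-normal IIV reproduces the published coefficients of variation", {
  pop <- population_parameters()
  # all CVs zero: the individual equals the typical subject exactly
  pop0 <- population_parameters(iiv_cv = setNames(
    numeric(length(pop$theta)), names(pop$theta)))
  ind0 <- sample_individual_parameters(pop0, seed = 5)
  expect_identical(ind0$values, pop0$theta)
  # Monte-Carlo check of the omega^2 = log(1 + CV^2) mapping for graft10
  om <- iiv_omega(pop)[["graft10"]]
  set.seed(42)
  draws <- 72.4 * exp(rnorm(1e5, 0, om))
  expect_lt(abs(sd(draws) / mean(draws) - 0.829), 0.03 * 0.829 + 0.02)
  # fixed seed reproduces the draw exactly
  a <- sample_individual_parameters(pop, seed = 77)
  b <- sample_individual_parameters(pop, seed = 77)
  expect_identical(a$values, b$values)
})

test_that("population simulation is seed-stable and respects zero IIV", {
  pop <- population_parameters()
  g <- seq(-30, 40, 0.5)
  s1 <- simulate_population(pop, n = 3, seed = 9, grid = g)
  s2 <- simulate_population(pop, n = 3, seed = 9, grid = g)
  expect_identical(lapply(s1$trajectories, `[[`, "plt_total"),
                   lapply(s2$trajectories, `[[`, "plt_total"))
  pop0 <- population_parameters(iiv_cv = setNames(
    numeric(length(pop$theta)), names(pop$theta)))
  s0 <- simulate_population(pop0, n = 1, seed = 1, grid = g)
  ref <- simulate_individual(pop0, typical_regimen(), grid = g)
  expect_equal(s0$trajectories[[1]]$plt_total, ref$plt_total,
               tolerance = 1e-12)
})

test_that("residual error has the configured spread and floors at zero", {
  pop <- population_parameters()
  traj <- simulate_individual(pop, untreated_regimen(),
                              grid = seq(0, 10, 0.25))
  # zero-variance error returns the model prediction
  obs0 <- add_residual_error(traj, c(1, 2, 3),
                             error_model = list(prop = 0, add = 0), seed = 1)
  expect_equal(obs0$platelet, trajectory_at(traj, c(1, 2, 3)))
  # proportional 20% at ~90.5: sample SD close to 0.2 * 90.5
  obs <- add_residual_error(traj, rep(5, 1e4),
                            error_model = list(prop = 0.2, add = 0), seed = 2)
  expect_lt(abs(sd(obs$platelet) - 0.2 * 90.5), 0.05 * 0.2 * 90.5)
  # flooring: a huge additive error never yields negative counts
  obs2 <- add_residual_error(traj, rep(5, 1000),
                             error_model = list(prop = 0, add = 500), seed = 3)
  expect_true(all(obs2$platelet >= 0))
  expect_true(any(obs2$platelet == 0))
  expect_error(add_residual_error(traj, 99), "span")
})

test_that("nadir and engraftment readouts are stable under grid refinement", {
  pop <- population_parameters()
  for (reg in list(typical_regimen(), atg_regimen())) {
    t4 <- simulate_individual(pop, reg, grid = seq(-30, 180, 0.25))
    t8 <- simulate_individual(pop, reg, grid = seq(-30, 180, 0.125))
    expect_lte(abs(nadir_day(t4) - nadir_day(t8)), 0.5)
    expect_lte(abs(trajectory_engraftment(t4) - trajectory_engraftment(t8)),
               0.5)
  }
})
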
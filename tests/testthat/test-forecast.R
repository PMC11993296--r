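test_that("weekly observation selection mirrors the forecasting data rule", {
  s <- noise_free_subject()
  w <- observations_for_cutoff(s, 28, mode = "weekly")
  expect_setequal(w$time, c(-14, -7, -3, 0, 7, 14, 21, 28))
  w14 <- observations_for_cutoff(s, 14, mode = "weekly")
  expect_setequal(w14$time, c(-14, -7, -3, 0, 7, 14))
  a <- observations_for_cutoff(s, 14, mode = "all")
  expect_setequal(a$time, s$observations$time[s$observations$time <= 14])
})

test_that("the MAP objective reduces to its two penalty limits", {
  pop <- population_parameters()
  s <- noise_free_subject()
  eta <- setNames(c(0.3, -0.1, 0.2, 0, -0.25, 0.15, 0.1, -0.2),
                  iiv_parameters(pop))
  obs <- observations_for_cutoff(s, 28)
  ind <- realize_parameters(pop, eta)
  traj <- simulate_individual(ind, s$regimen,
                              grid = sort(unique(c(-30, 0, obs$time))))
  f <- trajectory_at(traj, obs$time)
  s2 <- (0.2 * f)^2 + 2^2
  wls <- sum((obs$platelet - f)^2 / s2 + log(s2))
  # the objective is the weighted least-squares part plus the eta penalty
  expect_equal(map_objective(eta, s, pop, 28),
               wls + sum(eta^2 / iiv_omega(pop)^2), tolerance = 1e-6)
  # omega -> infinity: the penalty vanishes (omega grows only with the
  # log of the CV, so the check is absolute)
  pop_wide <- population_parameters(iiv_cv = setNames(
    rep(1e6, 8), iiv_parameters(pop)))
  expect_lt(abs(map_objective(eta, s, pop_wide, 28) - wls), 0.05)
  # omega -> 0 forces the estimate to the population prior
  pop_tight <- population_parameters(iiv_cv = setNames(
    rep(1e-4, 8), iiv_parameters(pop)))
  m <- map_estimate(s, pop_tight, 28)
  expect_lt(max(abs(m$eta)), 1e-4)
  expect_error(map_objective(eta, structure(list(
    observations = data.frame(time = 100, platelet = 50),
    regimen = s$regimen, covariates = NULL), class = "plt_subject"),
    pop, 28), "population")
})

test_that("noise-free typical data is explained with nearly no shrinkage", {
  pop <- population_parameters()
  s <- noise_free_subject()  # data generated at eta = 0, no noise
  m <- map_estimate(s, pop, 28)
  expect_lt(max(abs(m$eta)), 0.15)
  fc <- forecast(s, pop, 28, interval = FALSE)
  post <- s$observations[s$observations$time > 28, ]
  rel <- abs(trajectory_at(fc$trajectory, post$time) - post$platelet) /
    post$platelet
  expect_lt(max(rel), 0.05)
})

test_that("MAP estimation shrinks relative to unpenalized least squares", {
  # scalar case: only graft10 carries IIV
  pop1 <- population_parameters(iiv_cv = setNames(
    c(82.9, numeric(7)),
    c("graft10", "baseline_plt_pat", "rho", "day1_boost",
      "transfusion_boost", "mmt_gt", "gamma", "hct0")))
  s <- noise_free_subject(eta = c(graft10 = 0.7), pop = pop1)
  m_map <- map_estimate(s, pop1, 28)
  pop_free <- population_parameters(iiv_cv = setNames(
    c(1e6, numeric(7)),
    c("graft10", "baseline_plt_pat", "rho", "day1_boost",
      "transfusion_boost", "mmt_gt", "gamma", "hct0")))
  m_ls <- map_estimate(s, pop_free, 28)
  expect_lte(abs(m_map$eta[["graft10"]]), abs(m_ls$eta[["graft10"]]) + 1e-6)
  expect_gt(m_ls$eta[["graft10"]], 0.5)  # the data are informative
})

test_that("a subject without total-protein data forecasts as covariate-free", {
  pop <- population_parameters()
  s <- noise_free_subject()
  s2 <- s
  s2$covariates <- covariate_series(numeric(0), numeric(0))
  f1 <- forecast(s, pop, 14, interval = FALSE)
  f2 <- forecast(s2, pop, 14, interval = FALSE)
  expect_equal(f1$pred_mean, f2$pred_mean, tolerance = 1e-10)
})

test_that("prediction intervals are ordered, degenerate without noise, and
           widen with residual variance", {
  pop <- population_parameters()
  s <- noise_free_subject()
  m <- map_estimate(s, pop, 28)
  iv <- prediction_interval(s, pop, m, n_samples = 100, seed = 4,
                            grid = seq(28, 180, 4))
  expect_true(all(iv$lower <= iv$median + 1e-9))
  expect_true(all(iv$median <= iv$upper + 1e-9))
  # degenerate: no IIV and no residual error collapses onto the prediction
  pop0 <- population_parameters(
    iiv_cv = setNames(numeric(8), iiv_parameters(pop)),
    residual_error = list(prop = 0, add = 0))
  m0 <- map_estimate(s, pop0, 28)
  iv0 <- prediction_interval(s, pop0, m0, n_samples = 50, seed = 1,
                             grid = seq(30, 60, 10))
  pred <- trajectory_at(simulate_individual(pop0, s$regimen), iv0$time)
  expect_equal(iv0$lower, pred, tolerance = 1e-6)
  expect_equal(iv0$upper, pred, tolerance = 1e-6)
  # widening monotone in the residual variance
  pop_big <- population_parameters(residual_error = list(prop = 0.5, add = 10))
  m2 <- map_estimate(s, pop_big, 28)
  iv2 <- prediction_interval(s, pop_big, m2, n_samples = 100, seed = 4,
                             grid = seq(28, 180, 4))
  expect_gt(mean(iv2$upper - iv2$lower), mean(iv$upper - iv$lower))
})

test_that("day-28 estimates are calibrated against the simulated truth", {
  # MAP estimates shrink towards the prior, so the regression of estimate
  # on truth is attenuated by construction; the calibration property of a
  # posterior-mode estimator is that truth regressed on the estimate has
  # unit slope (E[eta | eta_hat] = eta_hat under a correct prior)
  ec <- eval_cohort()
  sub <- ec$subjects[1:200]
  fit <- ec$fits[1:200]
  for (par in c("graft10", "mmt_gt")) {
    true_eta <- vapply(sub, function(s) s$true_params$eta[[par]], numeric(1))
    est_eta <- vapply(fit, function(f) f[["28"]]$eta[[par]], numeric(1))
    b <- coef(lm(true_eta ~ est_eta))[2]
    expect_gt(b, 0.8)
    expect_lt(b, 1.2)
    expect_gt(cor(true_eta, est_eta), 0.3)  # the data are informative
  }
})

test_that("later cutoffs forecast the observed future at least as well", {
  # deviations are compared on the common prediction period and summarized
  # by the median: the observation-normalized ratio explodes for subjects
  # whose observed counts approach zero, which otherwise dominates the mean
  ec <- eval_cohort()
  mrd <- vapply(ec$cutoffs, function(co)
    median(vapply(ec$fits, function(f) f[[as.character(co)]]$mrd, numeric(1)),
           na.rm = TRUE), numeric(1))
  expect_lte(mrd[which(ec$cutoffs == 28)], mrd[which(ec$cutoffs == 7)])
  expect_lt(mrd[which(ec$cutoffs == 28)], 2)  # adequate absolute accuracy
})
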
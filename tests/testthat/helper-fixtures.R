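# Shared fixtures. The evaluation cohort and its MAP fits are expensive
# (hundreds of ODE fits), so they are computed once per test run and shared
# by the forecasting, outcome-ordering and recovery tests.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

typical_regimen <- function(...) treatment_regimen(...)

# a regimen whose conditioning and transplant lie far beyond the simulated
# window: the subject stays untreated over the grid of interest
untreated_regimen <- function()
  treatment_regimen(conditioning_start = 290, conditioning_stop = 294,
                    transplant_time = 295)

atg_regimen <- function(...)
  treatment_regimen(atg_doses = data.frame(time = c(-4, -3, -2), dose = 800),
                    ...)

# A noise-free subject simulated from known individual parameters under the
# default treatment; observations on the weekly-and-pre-HCT pattern used by
# the forecaster plus a dense post-day-29 tail for outcome scoring.
noise_free_subject <- function(eta = NULL, pop = population_parameters(),
                               regimen = typical_regimen(),
                               times = c(-14, -7, -3, 0, 7, 14, 21, 28,
                                         seq(35, 180, by = 7))) {
  ind <- realize_parameters(pop, eta)
  traj <- simulate_individual(ind, regimen)
  obs <- data.frame(time = times, platelet = trajectory_at(traj, times))
  structure(list(id = "nf", observations = obs, regimen = regimen,
                 covariates = NULL, true_params = ind,
                 true_label = classify_thrombocytopenia(obs),
                 truth_trajectory = traj),
            class = "plt_subject")
}

# 240 default-condition synthetic subjects with MAP fits at all four
# prediction-day cutoffs; scores are predicted trailing means, mae the mean
# relative deviation of the forecast profile against post-cutoff data.
eval_cohort <- function() fixture("eval_cohort", {
  pop <- population_parameters()
  subjects <- generate_cohort(240, seed = 97)$subjects
  cutoffs <- c(7, 14, 21, 28)
  fits <- lapply(subjects, function(s) {
    per <- lapply(cutoffs, function(co) {
      fc <- forecast(s, pop, cutoff_day = co, interval = FALSE)
      post <- s$observations[s$observations$time >= 29, , drop = FALSE]
      list(cutoff = co, score = fc$score, pred_mean = fc$pred_mean,
           eta = fc$map$eta,
           mrd = if (nrow(post))
             mean_relative_deviation(trajectory_at(fc$trajectory, post$time),
                                     post$platelet) else NA_real_)
    })
    names(per) <- as.character(cutoffs)
    per
  })
  list(pop = pop, subjects = subjects, fits = fits, cutoffs = cutoffs,
       labels = vapply(subjects, `[[`, logical(1), "true_label"))
})
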
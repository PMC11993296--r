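#' Observations entering a MAP fit at a given cutoff
#'
#' Reproduces the data situation of forecasting from day `cutoff_day`: all
#' pre-HCT platelet measurements plus, in `"weekly"` mode (the default),
#' the measurement closest to each of day +7, +14, ... up to the cutoff
#' (within `tol` days); in `"all"` mode every measurement up to the cutoff.
#'
#' @param subject a `plt_subject`.
#' @param cutoff_day prediction day (> 0).
#' @param mode `"weekly"` or `"all"`.
#' @param tol matching tolerance for weekly sampling, days.
#' @return data frame with columns `time`, `platelet`.
#' @export
observations_for_cutoff <- function(subject, cutoff_day,
                                    mode = c("weekly", "all"), tol = 1.5) {
  mode <- match.arg(mode)
  obs <- subject$observations
  pre <- obs[obs$time <= 0, , drop = FALSE]
  if (mode == "all") {
    post <- obs[obs$time > 0 & obs$time <= cutoff_day, , drop = FALSE]
  } else {
    idx <- integer(0)
    for (d in seq(7, cutoff_day, by = 7)) {
      cand <- which(obs$time > 0 & abs(obs$time - d) <= tol)
      if (length(cand)) idx <- c(idx, cand[which.min(abs(obs$time[cand] - d))])
    }
    post <- obs[unique(idx), , drop = FALSE]
  }
  out <- rbind(pre[, c("time", "platelet")], post[, c("time", "platelet")])
  out[order(out$time), , drop = FALSE]
}

# Regimen as known at the prediction day: transfusions only up to the cutoff.
regimen_at_cutoff <- function(regimen, cutoff_day) {
  regimen$transfusion_times <-
    regimen$transfusion_times[regimen$transfusion_times <= cutoff_day]
  regimen
}

#' MAP objective: -2 x log-posterior of the random effects
#'
#' `sum_i[(y_i - f_i(eta))^2 / s_i^2 + log(s_i^2)] + eta' Omega^-1 eta`, with
#' `f` the model prediction under `eta`, `s_i^2` the residual variance
#' evaluated at the prediction, and `Omega` the diagonal IIV covariance from
#' the population %CVs. Only data available at the cutoff contribute
#' ([observations_for_cutoff()], transfusions and total protein up to the
#' cutoff).
#'
#' @param eta numeric vector of random effects on the log scale, ordered as
#'   [iiv_parameters()].
#' @param subject a `plt_subject`.
#' @param pop a `plt_population`.
#' @param cutoff_day prediction day.
#' @param mode observation-selection mode, see [observations_for_cutoff()].
#' @param control a [sim_control()].
#' @return the scalar objective value.
#' @export
map_objective <- function(eta, subject, pop, cutoff_day, mode = "weekly",
                          control = sim_control()) {
  prep <- map_prepare(subject, pop, cutoff_day, mode)
  map_objective_prepared(eta, prep, control)
}

# Precomputes everything that does not depend on eta: the observation set,
# the censored regimen/covariates, the compiled-parameter template, the
# segment time vectors, and the transfusion impulse-response sums at the
# observation times (K_PAT, alpha and K_INT carry no IIV, so those sums are
# constant across eta and scale only with the realized transfusion_boost).
map_prepare <- function(subject, pop, cutoff_day, mode = "weekly") {
  obs <- observations_for_cutoff(subject, cutoff_day, mode)
  if (!nrow(obs))
    stop("no usable observations at cutoff day ", cutoff_day,
         "; use the population (prior) prediction instead")
  reg <- regimen_at_cutoff(subject$regimen, cutoff_day)
  cov <- censor_covariates(subject$covariates, cutoff_day)
  omega <- iiv_omega(pop)
  theta <- pop$theta
  ctl <- sim_control()
  p0 <- plt_parms_vector(theta, reg, cov, ctl$clamp, ctl$fb_cap)
  # pre-transplant integration is segmented at the hard discontinuities
  # (conditioning window bounds, ATG dose times) so the solver never steps
  # across them
  disc <- c(reg$conditioning_start, reg$conditioning_stop,
            if (!is.null(reg$atg_doses)) reg$atg_doses$time)
  disc <- sort(unique(disc[disc > -30 & disc < 0]))
  bounds <- c(-30, disc, 0)
  t_obs_pre <- obs$time[obs$time <= 0]
  pre_segments <- lapply(seq_len(length(bounds) - 1), function(k) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    inner <- t_obs_pre[t_obs_pre > t0 & t_obs_pre < t1]
    times <- unique(c(t0, sort(inner), t1))
    list(times = times,
         keep = match(t_obs_pre[t_obs_pre >= t0 & t_obs_pre < t1 |
                                  (k == length(bounds) - 1 &
                                     t_obs_pre == t1)], times))
  })
  t_post <- sort(unique(c(0, obs$time[obs$time > 0])))
  tr <- reg$transfusion_times
  s_obs <- if (length(tr))
    transfusion_contribution(obs$time, tr, 1, theta, reg)
  else numeric(nrow(obs))
  list(obs = obs, regimen = reg, covariates = cov, pop = pop,
       omega = omega, cutoff_day = cutoff_day,
       p0 = p0, pre_segments = pre_segments, t_post = t_post,
       n_pre = length(t_obs_pre),
       i_post = match(obs$time[obs$time > 0], t_post),
       related = reg$donor_relation == "related",
       s_obs = s_obs, theta = theta)
}

map_objective_prepared <- function(eta, prep, control = sim_control()) {
  th <- prep$theta
  e <- function(nm) {
    i <- match(nm, names(prep$omega))
    if (is.na(i)) 1 else exp(eta[[i]])
  }
  baseline <- th[["baseline_plt_pat"]] * e("baseline_plt_pat")
  rho <- min(th[["rho"]] * e("rho"), 1)
  day1 <- th[["day1_boost"]] * e("day1_boost") *
    if (prep$related) th[["sibling_boost_ratio"]] else 1
  tboost <- th[["transfusion_boost"]] * e("transfusion_boost")
  graft10 <- th[["graft10"]] * e("graft10")
  mmt_gt <- th[["mmt_gt"]] * e("mmt_gt")
  gamma <- th[["gamma"]] * e("gamma")
  hct0 <- th[["hct0"]] * e("hct0")

  p <- prep$p0
  p[2] <- (th[["n_transit"]] + 1) / mmt_gt
  p[4] <- rho
  p[8] <- gamma
  p[9] <- graft10
  y0 <- numeric(14)
  y0[1:5] <- baseline
  solve_seg <- function(y, times) {
    o <- try(suppressWarnings(
      deSolve::lsoda(y, times, "plt_derivs", p, dllname = "pltrecon",
                     initfunc = "plt_initmod", rtol = control$rtol,
                     atol = control$atol, hmax = control$hmax,
                     maxsteps = 50000)),
      silent = TRUE)
    if (inherits(o, "try-error") || nrow(o) < length(times) ||
        any(!is.finite(o[, c(6, 15)])))
      return(NULL)
    o
  }
  y <- y0
  f_pre <- numeric(prep$n_pre)
  n_filled <- 0
  for (seg in prep$pre_segments) {
    o <- solve_seg(y, seg$times)
    if (is.null(o)) return(1e10)  # extreme eta: solver breakdown
    y <- o[nrow(o), -1]
    if (length(seg$keep)) {
      f_pre[n_filled + seq_along(seg$keep)] <- (o[, 6] + o[, 15])[seg$keep]
      n_filled <- n_filled + length(seg$keep)
    }
  }
  y[5] <- y[5] + day1      # PLT_PAT transplant-day boost
  y[7] <- y[7] + hct0      # HCT effect
  y[8] <- y[8] + graft10   # Graft1
  f_post <- numeric(0)
  if (length(prep$t_post) > 1) {
    o2 <- solve_seg(y, prep$t_post)
    if (is.null(o2)) return(1e10)
    f_post <- (o2[, 6] + o2[, 15])[prep$i_post]
  }
  f <- c(f_pre, f_post) + tboost * prep$s_obs
  err <- prep$pop$residual_error
  s2 <- (err$prop * f)^2 + err$add^2
  sum((prep$obs$platelet - f)^2 / s2 + log(s2)) +
    sum(eta^2 / prep$omega^2)
}

#' MAP estimation of individual random effects
#'
#' Minimizes [map_objective()] over the random effects of the eight
#' IIV-carrying parameters, starting from the population prior (`eta = 0`).
#'
#' @inheritParams map_objective
#' @param reltol relative convergence tolerance on the objective.
#' @return object of class `plt_map`: list with `params` (the MAP
#'   `plt_individual`), `eta`, `objective`, `convergence` (0 = converged),
#'   and the fit inputs.
#' @export
map_estimate <- function(subject, pop, cutoff_day, mode = "weekly",
                         control = sim_control(), reltol = 1e-6) {
  prep <- map_prepare(subject, pop, cutoff_day, mode)
  k <- length(prep$omega)
  if (k == 0)
    return(structure(list(params = realize_parameters(pop),
                          eta = setNames(numeric(0), character(0)),
                          objective = NA_real_, convergence = 0,
                          prep = prep, pop = pop, cutoff_day = cutoff_day,
                          mode = mode),
                     class = "plt_map"))
  fit <- nlminb(rep(0, k), map_objective_prepared, prep = prep,
                control = list(rel.tol = reltol, iter.max = 200),
                lower = -5 * prep$omega, upper = 5 * prep$omega)
  eta <- setNames(fit$par, names(prep$omega))
  structure(list(params = realize_parameters(pop, eta), eta = eta,
                 objective = fit$objective,
                 convergence = fit$convergence,
                 prep = prep, pop = pop, cutoff_day = cutoff_day,
                 mode = mode),
            class = "plt_map")
}

#' @export
print.plt_map <- function(x, ...) {
  cat(sprintf("MAP fit at cutoff day +%g (%s data): objective %.2f%s\n",
              x$cutoff_day, x$mode, x$objective,
              if (x$convergence != 0) " [not converged]" else ""))
  print(signif(x$eta, 3))
  invisible(x)
}

#' Forecast a subject's 180-day platelet profile
#'
#' MAP-estimates the individual parameters from data available at
#' `cutoff_day`, then simulates the full profile to day 180. The
#' total-protein effect is neutral after the cutoff (uninformed covariate),
#' and only transfusions up to the cutoff enter the prediction. The
#' thrombocytopenia call is the predicted trailing mean (last 12 predicted
#' values at the subject's in-window measurement times) compared against
#' 75e9/L; the ROC risk score is that mean negated.
#'
#' @inheritParams map_estimate
#' @param interval compute a Monte-Carlo prediction interval.
#' @param level interval level (0.95).
#' @param n_samples posterior samples for the interval.
#' @param seed seed for the interval sampling.
#' @param grid output grid.
#' @return object of class `plt_forecast`: list with `trajectory`, `map`,
#'   `pred_mean` (predicted trailing mean), `score`, `call`
#'   (thrombocytopenia yes/no), and `interval` (data frame `time`, `lower`,
#'   `upper`) when requested.
#' @export
forecast <- function(subject, pop, cutoff_day, mode = "weekly",
                     control = sim_control(), interval = TRUE, level = 0.95,
                     n_samples = 200, seed = 1,
                     grid = seq(-30, 180, 0.25)) {
  map <- map_estimate(subject, pop, cutoff_day, mode, control)
  reg <- regimen_at_cutoff(subject$regimen, cutoff_day)
  cov <- censor_covariates(subject$covariates, cutoff_day)
  traj <- simulate_individual(map$params, reg, cov, grid, control)
  stimes <- subject$observations$time[subject$observations$time >= 29 &
                                        subject$observations$time <= 180]
  pred_mean <- if (length(stimes))
    mean(tail(trajectory_at(traj, stimes), 12)) else NA_real_
  iv <- NULL
  if (interval)
    iv <- prediction_interval(subject, pop, map, level = level,
                              n_samples = n_samples, seed = seed,
                              grid = seq(max(0, cutoff_day - 7), 180, 1),
                              control = control)
  structure(list(cutoff_day = cutoff_day, map = map, trajectory = traj,
                 pred_mean = pred_mean, score = -pred_mean,
                 call = if (is.na(pred_mean)) NA else pred_mean < 75,
                 interval = iv),
            class = "plt_forecast")
}

#' @export
print.plt_forecast <- function(x, ...) {
  cat(sprintf(
    "Forecast from day +%g: predicted trailing mean %.1f x10^9/L -> %s\n",
    x$cutoff_day, x$pred_mean,
    if (is.na(x$call)) "no label" else if (x$call)
      "thrombocytopenia" else "no thrombocytopenia"))
  invisible(x)
}

#' Monte-Carlo prediction interval around a MAP forecast
#'
#' Laplace approximation: random effects are sampled from a normal centered
#' at the MAP estimate with covariance `2 H^-1` (`H` the numerical Hessian of
#' the -2 log-posterior); each sample is simulated and perturbed with
#' residual error, and per-time quantiles are returned. If the Hessian is not
#' positive definite the prior covariance is used instead (prior-predictive
#' fallback).
#'
#' @param subject a `plt_subject`.
#' @param pop a `plt_population`.
#' @param map_result a `plt_map` from [map_estimate()].
#' @param level interval level in (0, 1).
#' @param n_samples number of Monte-Carlo samples.
#' @param seed integer seed.
#' @param grid prediction time grid.
#' @param control a [sim_control()].
#' @return data frame with columns `time`, `lower`, `median`, `upper`.
#' @export
prediction_interval <- function(subject, pop, map_result, level = 0.95,
                                n_samples = 200, seed = 1,
                                grid = seq(0, 180, 1),
                                control = sim_control()) {
  stopifnot(level > 0, level < 1)
  prep <- map_result$prep
  omega <- prep$omega
  k <- length(omega)
  H <- try(optimHess(map_result$eta,
                     function(e) map_objective_prepared(e, prep, control)),
           silent = TRUE)
  cov_eta <- NULL
  if (!inherits(H, "try-error")) {
    ch <- try(chol(solve(H / 2)), silent = TRUE)
    if (!inherits(ch, "try-error")) cov_eta <- ch
  }
  if (is.null(cov_eta)) cov_eta <- diag(omega, k)  # prior fallback
  set.seed(as.integer(seed))
  reg <- regimen_at_cutoff(subject$regimen, map_result$cutoff_day)
  cov <- censor_covariates(subject$covariates, map_result$cutoff_day)
  err <- pop$residual_error
  sims <- matrix(NA_real_, n_samples, length(grid))
  for (s in seq_len(n_samples)) {
    eta <- map_result$eta + drop(rnorm(k) %*% cov_eta)
    ind <- realize_parameters(pop, setNames(eta, names(omega)))
    tr <- simulate_individual(ind, reg, cov,
                              grid = sort(unique(c(-30, grid))),
                              control = control)
    f <- trajectory_at(tr, grid)
    sims[s, ] <- pmax(f + rnorm(length(f), 0, sqrt((err$prop * f)^2 +
                                                     err$add^2)), 0)
  }
  a <- (1 - level) / 2
  q <- apply(sims, 2, quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
  data.frame(time = grid, lower = q[1, ], median = q[2, ], upper = q[3, ])
}
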
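#' Integration settings
#'
#' @param rtol,atol relative / absolute solver tolerances (stiff-capable
#'   `lsoda`; integration is restarted at every bolus so events are exact
#'   discontinuities).
#' @param clamp feedback floor for `PLT_GT` inside the feedback ratio
#'   (1e9/L). The ratio `(Graft1_0 / PLT_GT)^gamma` diverges at `PLT_GT = 0`;
#'   the floor applies inside the ratio only.
#' @param fb_cap upper bound on the feedback multiplier
#'   `(Graft1_0 / PLT_GT)^gamma` (numerical guard: extreme `gamma` draws
#'   from the prior would otherwise make the system too stiff to solve).
#' @param hmax maximum solver step, days. The solver is restarted at every
#'   hard discontinuity (boluses, the conditioning window, ATG doses);
#'   `hmax` additionally bounds the step across the milder total-protein
#'   steps so no structural change is skipped between sparse output times.
#' @param use_compiled use the compiled right-hand side (identical to the R
#'   reference in [derivatives()], ~50x faster).
#' @return a list of control settings.
#' @export
sim_control <- function(rtol = 1e-8, atol = 1e-10, clamp = 1e-3,
                        fb_cap = 1000, hmax = 2, use_compiled = TRUE) {
  list(rtol = rtol, atol = atol, clamp = clamp, fb_cap = fb_cap,
       hmax = hmax, use_compiled = use_compiled)
}

#' Simulate one subject's platelet trajectory
#'
#' Deterministically integrates the 14-compartment system for one parameter
#' realization, honoring the full bolus schedule ([event_schedule()]) and the
#' time-varying total-protein effect.
#'
#' @param params a `plt_individual` (or `plt_population` for the typical
#'   subject).
#' @param regimen a [treatment_regimen()].
#' @param covariates optional [covariate_series()].
#' @param grid output time grid, days (default 0.25-day spacing over
#'   \[-30, 180\]). Event times may lie between grid points.
#' @param control a [sim_control()].
#' @param full_state keep the full 14-column state matrix.
#' @return a `plt_trajectory`: list with `time`, `plt_pat`, `plt_gt`,
#'   `plt_total` (and `state` if requested).
#' @examples
#' traj <- simulate_individual(population_parameters(), treatment_regimen(),
#'                             grid = seq(-30, 40, 0.25))
#' range(traj$plt_total)
#' @export
simulate_individual <- function(params, regimen, covariates = NULL,
                                grid = seq(-30, 180, 0.25),
                                control = sim_control(), full_state = FALSE) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  ev <- event_schedule(params, regimen)
  if (any(ev$time < grid[1]))
    stop("event at day ", min(ev$time), " lies before the simulation start (",
         grid[1], ")")
  ev <- ev[ev$time <= grid[length(grid)], , drop = FALSE]
  out <- integrate_model(param_values(params), regimen, covariates, grid, ev,
                         control)
  traj <- structure(
    list(time = out[, "time"],
         plt_pat = out[, "PLT_PAT"],
         plt_gt = out[, "PLT_GT"],
         plt_total = out[, "PLT_PAT"] + out[, "PLT_GT"],
         state = if (full_state) out[, plt_state_names, drop = FALSE],
         params = params, regimen = regimen),
    class = "plt_trajectory")
  traj
}

# Piecewise integration with boluses applied as exact discontinuities: the
# solver is restarted at every event time, and the reported value at an
# event time is the pre-bolus state. The linear parts of the patient chain
# are treated in closed form: the ATG amount is the analytic dose
# superposition (evaluated inside the RHS), and platelet-transfusion boluses
# are added to PLT_PAT afterwards through the exact impulse response of its
# elimination (exp(-K_PAT [t - tj + alpha * int ATG])). Only graft, HCT and
# transplant-day platelet boluses restart the solver.
integrate_model <- function(values, regimen, covariates, grid, ev, control,
                            y0 = NULL) {
  if (is.null(y0)) {
    y0 <- setNames(numeric(14), plt_state_names)
    y0[1:5] <- values[["baseline_plt_pat"]]
  }
  tmin <- grid[1]
  tmax <- grid[length(grid)]
  ev <- ev[ev$time >= tmin & ev$time <= tmax, , drop = FALSE]
  transf <- ev[ev$type == "transfusion", , drop = FALSE]
  ev <- ev[!ev$type %in% c("transfusion", "atg") & ev$time < tmax, ,
           drop = FALSE]
  ev_idx <- match(ev$compartment, plt_state_names)
  disc <- c(ev$time, regimen$conditioning_start, regimen$conditioning_stop,
            if (!is.null(regimen$atg_doses)) regimen$atg_doses$time)
  disc <- disc[disc > tmin & disc < tmax]
  breaks <- unique(c(tmin, sort(unique(disc)), tmax))

  if (isTRUE(control$use_compiled)) {
    p <- plt_parms_vector(values, regimen, covariates, control$clamp,
                          control$fb_cap)
    solve_seg <- function(y, times)
      deSolve::lsoda(y, times, "plt_derivs", p, dllname = "pltrecon",
                     initfunc = "plt_initmod", rtol = control$rtol,
                     atol = control$atol, hmax = control$hmax,
                     maxsteps = 50000)
  } else {
    ind <- structure(list(values = values, eta = NULL),
                     class = "plt_individual")
    doses <- regimen$atg_doses
    rhs <- function(t, y, parms) {
      y <- pmax(y, 0)
      if (!is.null(doses))
        y[["ATG"]] <- atg_profile(t, doses, values[["atg_kint"]])
      d <- derivatives(t, y, ind, regimen, covariates,
                       clamp = control$clamp, fb_cap = control$fb_cap)
      d[["ATG"]] <- 0
      list(d)
    }
    solve_seg <- function(y, times)
      deSolve::lsoda(y, times, rhs, NULL, rtol = control$rtol,
                     atol = control$atol, hmax = control$hmax,
                     maxsteps = 50000)
  }

  y <- y0
  apply_events <- function(y, at) {
    hit <- which(ev$time == at)
    for (j in hit) y[ev_idx[j]] <- y[ev_idx[j]] + ev$amount[j]
    y
  }
  y <- apply_events(y, tmin)
  segs <- vector("list", length(breaks) - 1)
  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]
    t1 <- breaks[k + 1]
    if (k > 1) y <- apply_events(y, t0)
    times <- c(t0, grid[grid > t0 & grid < t1], t1)
    o <- solve_seg(y, times)
    if (attr(o, "istate")[1] < 0)
      stop("ODE solver failed; last successful time ", o[nrow(o), 1])
    y <- o[nrow(o), -1]
    # the row at t0 (post-event) is replaced by the previous segment's
    # pre-event row; the row at t1 is pre-event for the next segment
    keep <- if (k == 1) TRUE else o[, 1] > t0
    segs[[k]] <- o[keep & o[, 1] %in% grid, , drop = FALSE]
  }
  out <- do.call(rbind, segs)
  if (nrow(transf)) {
    add <- transfusion_contribution(out[, 1], transf$time, transf$amount,
                                    values, regimen)
    out[, "PLT_PAT"] <- out[, "PLT_PAT"] + add
  }
  if (!is.null(regimen$atg_doses) && nrow(regimen$atg_doses))
    out[, "ATG"] <- atg_profile(out[, 1], regimen$atg_doses,
                                values[["atg_kint"]])
  out
}

# Exact response of PLT_PAT to transfusion boluses: each bolus decays with
# the platelet elimination rate K_PAT * (1 + alpha * ATG(t)); the ATG
# integral is available in closed form from the dose history. A bolus
# contributes for t strictly greater than its time (pre-bolus readout at the
# event time itself).
transfusion_contribution <- function(t, tr_times, amounts, values, regimen) {
  kpat <- transit_rate(values[["mmt_pat"]], values[["n_transit"]])
  alpha <- values[["atg_alpha"]]
  kint <- values[["atg_kint"]]
  doses <- regimen$atg_doses
  int_atg <- function(a, b) {
    if (is.null(doses) || !nrow(doses)) return(0)
    sum(doses$dose / kint * (exp(-kint * pmax(0, a - doses$time)) -
                               exp(-kint * pmax(0, b - doses$time))))
  }
  amounts <- rep_len(amounts, length(tr_times))
  vapply(t, function(ti) {
    act <- which(tr_times < ti)
    if (!length(act)) return(0)
    sum(vapply(act, function(j)
      amounts[j] * exp(-kpat * (ti - tr_times[j]) -
                         kpat * alpha * int_atg(tr_times[j], ti)),
      numeric(1)))
  }, numeric(1))
}

#' @export
print.plt_trajectory <- function(x, ...) {
  cat(sprintf(
    "Platelet trajectory: %d time points on [%g, %g] d; final PLT %.1f x10^9/L\n",
    length(x$time), min(x$time), max(x$time), tail(x$plt_total, 1)))
  invisible(x)
}

#' @export
as.data.frame.plt_trajectory <- function(x, ...) {
  data.frame(time = x$time, plt_pat = x$plt_pat, plt_gt = x$plt_gt,
             plt_total = x$plt_total)
}

#' Read a trajectory at given times
#'
#' Linear interpolation on the simulation grid; the daily readout convention
#' of the package is the value at `t = d` exactly.
#'
#' @param traj a `plt_trajectory`.
#' @param t times, days.
#' @param what one of `"plt_total"`, `"plt_pat"`, `"plt_gt"`.
#' @return numeric vector of platelet counts.
#' @export
trajectory_at <- function(traj, t, what = "plt_total") {
  approx(traj$time, traj[[what]], xout = t, rule = 2)$y
}

#' Day of the platelet nadir
#'
#' Locates the minimum of the total platelet count on the daily grid,
#' starting at `from` (default: conditioning onset).
#'
#' @param traj a `plt_trajectory`.
#' @param from first day considered.
#' @param to last day considered.
#' @return integer day of the minimum.
#' @export
nadir_day <- function(traj, from = traj$regimen$conditioning_start,
                      to = floor(max(traj$time))) {
  days <- seq(ceiling(from), to, by = 1)
  v <- trajectory_at(traj, days)
  days[which.min(v)]
}

#' Simulate a virtual population
#'
#' Draws `n` subjects from the population prior (log-normal IIV) and
#' simulates each deterministically. Per-subject seeds are derived from the
#' master seed by counter, so results do not depend on execution order.
#'
#' @param pop a `plt_population`.
#' @param n number of subjects (>= 1).
#' @param seed master seed.
#' @param regimen_generator function of a per-subject seed returning
#'   `list(regimen = , covariates = )`; by default every subject receives the
#'   reference regimen (conditioning -6..-2, unrelated donor, no ATG, no
#'   transfusions).
#' @param grid,control as in [simulate_individual()].
#' @return list with elements `trajectories` (list of `plt_trajectory`) and
#'   `parameters` (list of `plt_individual`).
#' @export
simulate_population <- function(pop, n, seed,
                                regimen_generator = NULL,
                                grid = seq(-30, 180, 0.25),
                                control = sim_control()) {
  stopifnot(n >= 1)
  if (is.null(regimen_generator))
    regimen_generator <- function(subject_seed) list(regimen = treatment_regimen(),
                                                     covariates = NULL)
  trajs <- vector("list", n)
  pars <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    ind <- sample_individual_parameters(pop, seed = si)
    rc <- regimen_generator(derive_seed(si, 1L))
    trajs[[i]] <- tryCatch(
      simulate_individual(ind, rc$regimen, rc$covariates, grid, control),
      error = function(e) stop("subject ", i, ": ", conditionMessage(e)))
    pars[[i]] <- ind
  }
  list(trajectories = trajs, parameters = pars)
}

#' Sample noisy observations from a trajectory
#'
#' Perturbs model predictions at the requested times with the residual-error
#' model (combined proportional + additive by default) and floors the result
#' at 0.
#'
#' @param traj a `plt_trajectory`.
#' @param times observation times within the trajectory span.
#' @param error_model list with `prop` and `add`; defaults to the model
#'   attached to the trajectory's parameters, else 20% + 2e9/L.
#' @param seed integer seed.
#' @return data frame with columns `time` and `platelet`.
#' @export
add_residual_error <- function(traj, times, error_model = NULL, seed = NULL) {
  if (any(times < min(traj$time) | times > max(traj$time)))
    stop("observation times outside the trajectory span")
  if (is.null(error_model))
    error_model <- traj$params$residual_error %||% list(prop = 0.2, add = 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  f <- trajectory_at(traj, times)
  sdv <- sqrt((error_model$prop * f)^2 + error_model$add^2)
  data.frame(time = times, platelet = pmax(f + rnorm(length(f), 0, sdv), 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate with threshold-triggered platelet transfusions
#'
#' Replays clinical transfusion practice inside the simulation: on each day
#' in `window` where the (pre-bolus) total platelet count falls below
#' `threshold`, a transfusion bolus of the subject's `transfusion_boost` is
#' added to `PLT_PAT`, and integration continues.
#'
#' @param params,regimen,covariates,grid,control as [simulate_individual()].
#' @param threshold transfusion trigger, 1e9/L (default 12).
#' @param window two-element numeric, days in which transfusions are given
#'   (default day +1 to +30).
#' @return list with `trajectory` (a `plt_trajectory`) and
#'   `transfusion_times` (integer days).
#' @export
simulate_with_transfusions <- function(params, regimen, covariates = NULL,
                                       grid = seq(-30, 180, 0.25),
                                       control = sim_control(),
                                       threshold = 12, window = c(1, 30)) {
  values <- param_values(params)
  base <- simulate_individual(params, regimen, covariates, grid, control)
  days <- seq(ceiling(window[1]), floor(window[2]), by = 1)
  boost <- values[["transfusion_boost"]]
  new_tr <- numeric(0)
  for (d in days) {
    tot <- trajectory_at(base, d)
    if (length(new_tr))
      tot <- tot + transfusion_contribution(d, new_tr, boost, values,
                                            regimen)
    if (tot < threshold) new_tr <- c(new_tr, d)
  }
  if (length(new_tr)) {
    add <- transfusion_contribution(base$time, new_tr, boost, values,
                                    regimen)
    base$plt_pat <- base$plt_pat + add
    base$plt_total <- base$plt_total + add
    if (!is.null(base$state))
      base$state[, "PLT_PAT"] <- base$state[, "PLT_PAT"] + add
    base$regimen <- within_regimen_transfusions(regimen, new_tr)
  }
  list(trajectory = base, transfusion_times = new_tr)
}

within_regimen_transfusions <- function(regimen, times) {
  regimen$transfusion_times <- sort(unique(c(regimen$transfusion_times, times)))
  regimen
}

#' Export trajectories as a tidy data frame
#'
#' @param trajectories list of `plt_trajectory`.
#' @param ids optional subject identifiers.
#' @return data frame with columns `subject`, `time`, `plt_pat`, `plt_gt`,
#'   `plt_total`.
#' @export
trajectories_to_df <- function(trajectories, ids = seq_along(trajectories)) {
  do.call(rbind, Map(function(tr, id) {
    cbind(subject = id, as.data.frame(tr))
  }, trajectories, ids))
}
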
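#' Configuration of the synthetic cohort generator
#'
#' Encodes the study conditions the generator emulates: treatment mix,
#' conditioning and ATG schedule, platelet sampling density, the
#' total-protein process, and the transfusion rule.
#'
#' @param prop_atg proportion of ATG-treated subjects (0.574).
#' @param prop_related proportion of related-donor transplants (0.268).
#' @param conditioning two-element numeric, conditioning window (-6, -2).
#' @param atg_dose daily ATG dose, mg (800).
#' @param atg_days ATG dosing days (-4, -3, -2).
#' @param target_median_obs target median number of platelet measurements
#'   per subject over \[-30, 180\] (58).
#' @param tp_start mean total-protein level, g/dL (5.43).
#' @param tp_sd stationary between/within-subject SD of the total-protein
#'   process, g/dL (0.96; places the 10th percentile near 4.2).
#' @param tp_revert mean-reversion rate of the process, 1/day (0.05).
#' @param tp_cadence measurement spacing of total protein, days (3.5).
#' @param transfusion_threshold trigger threshold, 1e9/L (12).
#' @param transfusion_window days in which transfusions occur (1, 30).
#' @return a list of class `plt_cohort_config`.
#' @export
cohort_config <- function(prop_atg = 0.574, prop_related = 0.268,
                          conditioning = c(-6, -2), atg_dose = 800,
                          atg_days = c(-4, -3, -2),
                          target_median_obs = 58,
                          tp_start = 5.43, tp_sd = 0.96, tp_revert = 0.05,
                          tp_cadence = 3.5,
                          transfusion_threshold = 12,
                          transfusion_window = c(1, 30)) {
  stopifnot(prop_atg >= 0, prop_atg <= 1, prop_related >= 0,
            prop_related <= 1, target_median_obs >= 1)
  structure(as.list(environment()), class = "plt_cohort_config")
}

#' Synthetic total-protein series
#'
#' Mean-reverting (Ornstein-Uhlenbeck-type) random walk sampled at the
#' configured cadence over \[-7, 180\]: stationary mean `tp_start`,
#' stationary SD `tp_sd`, reversion rate `tp_revert`. With the defaults the
#' pooled marginal distribution has median near 5.43 g/dL and 10th
#' percentile near 4.2 g/dL.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return a [covariate_series()].
#' @export
generate_tp_series <- function(config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  times <- seq(-7, 180, by = config$tp_cadence)
  n <- length(times)
  x <- numeric(n)
  x[1] <- rnorm(1, config$tp_start, config$tp_sd)
  if (n > 1) {
    phi <- exp(-config$tp_revert * diff(times))
    for (i in 2:n)
      x[i] <- config$tp_start + phi[i - 1] * (x[i - 1] - config$tp_start) +
        rnorm(1, 0, config$tp_sd * sqrt(1 - phi[i - 1]^2))
  }
  covariate_series(times, pmin(pmax(x, 2.5), 10))
}

#' Transfusion days from a simulated truth trajectory
#'
#' Scans the daily readout of a trajectory: a transfusion event is placed on
#' each day inside `window` whose platelet value lies strictly below
#' `threshold`. For truth generation with feedback of the boluses into the
#' simulation, use [simulate_with_transfusions()].
#'
#' @param traj a `plt_trajectory`.
#' @param threshold trigger threshold, 1e9/L (12).
#' @param window two-element numeric, days (1, 30).
#' @return numeric vector of transfusion days.
#' @export
transfusion_trigger <- function(traj, threshold = 12, window = c(1, 30)) {
  days <- seq(ceiling(window[1]), floor(window[2]), by = 1)
  v <- trajectory_at(traj, days)
  days[v < threshold]
}

#' Impute transfusions from observed platelet counts
#'
#' The record-free imputation rule: one transfusion per observation inside
#' the window with a value strictly below the threshold, placed at the
#' observation time.
#'
#' @param observations data frame with `time` and `platelet`, time-sorted.
#' @param threshold imputation threshold, 1e9/L (12).
#' @param window two-element numeric, days (1, 30).
#' @return numeric vector of imputed transfusion times.
#' @export
impute_transfusions <- function(observations, threshold = 12,
                                window = c(1, 30)) {
  if (is.unsorted(observations$time)) stop("observations must be time-sorted")
  i <- observations$time >= window[1] & observations$time <= window[2] &
    observations$platelet < threshold
  observations$time[i]
}

# Candidate observation days: daily in the early in-hospital phase, every
# third day to day +99, weekly afterwards, weekly pre-admission.
observation_schedule <- function() {
  c(seq(-28, -14, by = 7), seq(-7, 42, by = 1), seq(45, 99, by = 3),
    seq(106, 180, by = 7))
}

#' Generate one synthetic subject
#'
#' Draws individual parameters from the prior, assigns treatment flags
#' (ATG, donor relation) and a total-protein series, simulates the
#' noise-free truth with threshold-triggered transfusions, samples
#' observation times (thinned towards the target median count), adds
#' residual error, and records the truth for recovery testing.
#'
#' @param config a [cohort_config()].
#' @param pop a `plt_population`.
#' @param seed integer seed.
#' @param id subject identifier.
#' @param keep_truth retain the full noise-free truth trajectory (element
#'   `truth_trajectory`).
#' @return object of class `plt_subject`: list with `id`, `observations`
#'   (`time`, `platelet`, `truth`), `regimen` (including triggered
#'   transfusions), `covariates`, `true_params`, `true_label`.
#' @export
generate_subject <- function(config = cohort_config(),
                             pop = population_parameters(), seed = 1,
                             id = 1L, keep_truth = FALSE) {
  set.seed(as.integer(seed))
  omega <- iiv_omega(pop)
  eta <- setNames(rnorm(length(omega), 0, omega), names(omega))
  ind <- realize_parameters(pop, eta)
  atg <- runif(1) < config$prop_atg
  related <- runif(1) < config$prop_related
  regimen <- treatment_regimen(
    conditioning_start = config$conditioning[1],
    conditioning_stop = config$conditioning[2],
    atg_doses = if (atg) data.frame(time = config$atg_days,
                                    dose = config$atg_dose),
    donor_relation = if (related) "related" else "unrelated")
  covariates <- generate_tp_series(config)

  sim <- simulate_with_transfusions(
    ind, regimen, covariates,
    threshold = config$transfusion_threshold,
    window = config$transfusion_window)
  truth <- sim$trajectory
  regimen <- truth$regimen  # carries the triggered transfusion times

  sched <- observation_schedule()
  keep_p <- min(1, config$target_median_obs / length(sched))
  times <- sched[runif(length(sched)) < keep_p]
  if (!any(times <= 0)) times <- sort(c(-7, times))
  if (length(times) < 2) times <- c(-7, 0, 7, 14, 21, 28)
  f <- trajectory_at(truth, times)
  err <- pop$residual_error
  y <- pmax(f + rnorm(length(f), 0, sqrt((err$prop * f)^2 + err$add^2)), 0)
  obs <- data.frame(time = times, platelet = y, truth = f)
  true_label <- classify_thrombocytopenia(
    data.frame(time = times, platelet = f))

  structure(list(id = id, observations = obs, regimen = regimen,
                 covariates = covariates, true_params = ind,
                 true_label = true_label,
                 truth_trajectory = if (keep_truth) truth),
            class = "plt_subject")
}

#' @export
print.plt_subject <- function(x, ...) {
  cat(sprintf(
    "Synthetic subject %s: %d observations, %s donor, %s, %d transfusion(s)\n",
    x$id, nrow(x$observations), x$regimen$donor_relation,
    if (is.null(x$regimen$atg_doses)) "no ATG" else "ATG",
    length(x$regimen$transfusion_times)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' @param n number of subjects.
#' @param config a [cohort_config()].
#' @param pop a `plt_population`.
#' @param seed master seed; per-subject seeds are derived by counter.
#' @param keep_truth retain full truth trajectories (see
#'   [generate_subject()]).
#' @return object of class `plt_cohort`: list with `subjects`, `config`,
#'   `seed`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(5, seed = 1)
#' table(vapply(coh$subjects, `[[`, logical(1), "true_label"))
#' }
#' @export
generate_cohort <- function(n, config = cohort_config(),
                            pop = population_parameters(), seed = 1,
                            keep_truth = FALSE) {
  subjects <- lapply(seq_len(n), function(i)
    generate_subject(config, pop, seed = derive_seed(seed, i), id = i,
                     keep_truth = keep_truth))
  structure(list(subjects = subjects, config = config, seed = seed),
            class = "plt_cohort")
}

#' @export
print.plt_cohort <- function(x, ...) {
  lab <- vapply(x$subjects, `[[`, logical(1), "true_label")
  cat(sprintf(
    "Synthetic cohort: %d subjects, %d thrombocytopenic (%.0f%%), seed %d\n",
    length(x$subjects), sum(lab, na.rm = TRUE),
    100 * mean(lab, na.rm = TRUE), x$seed))
  invisible(x)
}
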
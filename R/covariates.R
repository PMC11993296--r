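#' First-order ATG elimination
#'
#' Closed-form decay of the virtual ATG amount between doses:
#' `amount * exp(-kint * dt)`.
#'
#' @param amount ATG amount (mg, >= 0).
#' @param kint elimination rate constant, 1/day (> 0).
#' @param dt elapsed time, days (>= 0).
#' @return remaining amount.
#' @examples
#' atg_elimination(800, 0.35, log(2) / 0.35)  # one half-life -> 400
#' @export
atg_elimination <- function(amount, kint, dt) {
  if (any(amount < 0)) stop("amount must be non-negative")
  if (any(kint <= 0)) stop("kint must be positive")
  if (any(dt < 0)) stop("dt must be non-negative")
  amount * exp(-kint * dt)
}

#' ATG amount over time from a dosing history
#'
#' Superposition of first-order decays from each bolus dose; used as an
#' analytic cross-check of the integrated ATG compartment.
#'
#' @param t times to evaluate, days.
#' @param doses data frame with columns `time` and `dose` (mg).
#' @param kint elimination rate constant, 1/day.
#' @return ATG amount at each `t`.
#' @export
atg_profile <- function(t, doses, kint) {
  vapply(t, function(ti) {
    active <- doses$time <= ti
    sum(atg_elimination(doses$dose[active], kint, ti - doses$time[active]))
  }, numeric(1))
}

#' ATG effect on platelet elimination
#'
#' Linear concentration-effect model: platelet elimination is multiplied by
#' `1 + alpha * ATG(t)`.
#'
#' @param atg ATG amount (>= 0).
#' @param alpha slope, 1/mg.
#' @return elimination multiplier (>= 1 for non-negative inputs).
#' @examples
#' platelet_elimination_multiplier(0, 0.01)    # 1
#' platelet_elimination_multiplier(800, 0.01)  # 9
#' @export
platelet_elimination_multiplier <- function(atg, alpha) {
  if (any(atg < 0)) stop("atg must be non-negative")
  m <- 1 + alpha * atg
  if (any(m < 0)) stop("elimination multiplier must be non-negative")
  m
}

#' Total-protein effect on graft HSC proliferation
#'
#' Power model centered at the population median:
#' `(tp / tp_median)^tp_exponent`.
#'
#' @param tp total protein, g/dL (> 0).
#' @param tp_median centering constant, g/dL (default 5.43).
#' @param tp_exponent effect exponent (default 0.197).
#' @return proliferation multiplier.
#' @examples
#' total_protein_multiplier(5.43)  # 1
#' total_protein_multiplier(4.2)   # 0.9506
#' @export
total_protein_multiplier <- function(tp, tp_median = 5.43,
                                     tp_exponent = 0.197) {
  if (any(tp <= 0)) stop("total protein must be positive")
  (tp / tp_median)^tp_exponent
}

#' Transplant-day platelet boost by donor relation
#'
#' The day-0 platelet bolus is `day1_boost` for unrelated donors and
#' `day1_boost * sibling_boost_ratio` (2.75 by default) for related donors.
#'
#' @param donor_relation `"related"` or `"unrelated"`.
#' @param params a `plt_individual` or `plt_population`.
#' @return bolus amount, 1e9/L.
#' @examples
#' day1_boost_amount("unrelated", population_parameters())  # 20.1
#' day1_boost_amount("related", population_parameters())    # 55.275
#' @export
day1_boost_amount <- function(donor_relation, params) {
  v <- param_values(params)
  if (!donor_relation %in% c("related", "unrelated"))
    stop("donor_relation must be 'related' or 'unrelated'")
  v[["day1_boost"]] *
    if (donor_relation == "related") v[["sibling_boost_ratio"]] else 1
}

# Step function (time, multiplier) of the total-protein effect: LOCF between
# measurements, neutral before the first one and after the cutoff day.
tp_step <- function(covariates, tp_median, tp_exponent) {
  if (is.null(covariates) || !length(covariates$time))
    return(list(time = numeric(0), mult = numeric(0)))
  tm <- covariates$time
  mult <- total_protein_multiplier(covariates$total_protein, tp_median,
                                   tp_exponent)
  if (!is.null(covariates$cutoff_day)) {
    keep <- tm <= covariates$cutoff_day
    tm <- tm[keep]; mult <- mult[keep]
    if (length(tm)) {
      tm <- c(tm, covariates$cutoff_day)
      mult <- c(mult, 1)
    }
  }
  list(time = tm, mult = mult)
}

# The multiplier at a single time, matching the compiled step function.
tp_multiplier_at <- function(t, covariates, tp_median, tp_exponent) {
  st <- tp_step(covariates, tp_median, tp_exponent)
  if (!length(st$time)) return(1)
  i <- findInterval(t, st$time)
  if (i == 0) 1 else st$mult[i]
}
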
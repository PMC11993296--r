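#' Treatment regimen of one subject
#'
#' Bundles the event times that drive the model: the conditioning window
#' (days of first and last chemo/radiotherapy dose), ATG doses, the
#' transplant day (time origin, day 0), platelet transfusion times, and the
#' donor relation.
#'
#' @param conditioning_start,conditioning_stop first and last day of
#'   conditioning (days relative to transplant; `start < stop <= transplant`).
#' @param atg_doses data frame with columns `time` (day) and `dose` (mg), or
#'   `NULL` for no ATG.
#' @param transplant_time transplant day (0 by convention).
#' @param transfusion_times numeric vector of platelet-transfusion days.
#' @param donor_relation `"related"` or `"unrelated"`.
#' @return an object of class `plt_regimen`.
#' @examples
#' treatment_regimen(atg_doses = data.frame(time = -4:-2, dose = 800),
#'                   donor_relation = "unrelated")
#' @export
treatment_regimen <- function(conditioning_start = -6, conditioning_stop = -2,
                              atg_doses = NULL, transplant_time = 0,
                              transfusion_times = numeric(0),
                              donor_relation = c("unrelated", "related")) {
  donor_relation <- match.arg(donor_relation)
  if (!is.null(atg_doses)) {
    if (!all(c("time", "dose") %in% names(atg_doses)))
      stop("atg_doses needs columns 'time' and 'dose'")
    if (any(atg_doses$dose <= 0)) stop("ATG doses must be positive")
  }
  if (conditioning_start >= conditioning_stop)
    stop("conditioning_start must be before conditioning_stop")
  if (conditioning_stop > transplant_time)
    stop("conditioning must end at or before the transplant")
  structure(list(conditioning_start = conditioning_start,
                 conditioning_stop = conditioning_stop,
                 atg_doses = atg_doses,
                 transplant_time = transplant_time,
                 transfusion_times = sort(as.numeric(transfusion_times)),
                 donor_relation = donor_relation),
            class = "plt_regimen")
}

#' @export
print.plt_regimen <- function(x, ...) {
  cat(sprintf("Regimen: conditioning [%g, %g], transplant day %g, %s donor\n",
              x$conditioning_start, x$conditioning_stop, x$transplant_time,
              x$donor_relation))
  if (!is.null(x$atg_doses))
    cat(sprintf("  ATG: %d dose(s), total %g mg\n", nrow(x$atg_doses),
                sum(x$atg_doses$dose)))
  if (length(x$transfusion_times))
    cat(sprintf("  transfusions at day(s) %s\n",
                paste(x$transfusion_times, collapse = ", ")))
  invisible(x)
}

#' Time-varying total-protein covariate series
#'
#' Ordered serum total-protein measurements for one subject. The model uses
#' them as a step function (last observation carried forward); the multiplier
#' is neutral (1) before the first measurement and, when `cutoff_day` is set,
#' after that day -- the convention used when forecasting with the covariate
#' uninformed beyond the prediction day.
#'
#' @param time numeric vector of measurement days (strictly increasing).
#' @param total_protein total protein, g/dL (positive).
#' @param cutoff_day optional day after which the effect is neutralized.
#' @return an object of class `plt_covariates`.
#' @examples
#' covariate_series(c(-5, 3, 10), c(5.4, 4.8, 5.1))
#' @export
covariate_series <- function(time = numeric(0), total_protein = numeric(0),
                             cutoff_day = NULL) {
  if (length(time) != length(total_protein))
    stop("time and total_protein must have equal length")
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("covariate times must be strictly increasing")
  if (any(total_protein <= 0)) stop("total protein must be positive")
  structure(list(time = as.numeric(time),
                 total_protein = as.numeric(total_protein),
                 cutoff_day = cutoff_day),
            class = "plt_covariates")
}

#' @export
print.plt_covariates <- function(x, ...) {
  cat(sprintf("Total-protein series: %d measurement(s)", length(x$time)))
  if (!is.null(x$cutoff_day)) cat(sprintf(", neutral after day %g", x$cutoff_day))
  cat("\n")
  invisible(x)
}

# Restrict a covariate series to the forecasting convention: observations up
# to `cutoff` inform the effect, everything later is neutral.
censor_covariates <- function(covariates, cutoff) {
  if (is.null(covariates)) return(NULL)
  keep <- covariates$time <= cutoff
  covariate_series(covariates$time[keep], covariates$total_protein[keep],
                   cutoff_day = cutoff)
}
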
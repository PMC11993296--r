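#' Read a NONMEM-style event-record dataset
#'
#' The dataset is a CSV with one row per observation or dose event and
#' columns:
#' \describe{
#'   \item{id}{subject identifier}
#'   \item{time}{decimal days relative to transplant (day 0)}
#'   \item{evid}{0 = observation row, 1 = dose-event row}
#'   \item{cmt}{event target: `"ATG"` (dose in mg) or `"TRANSFUSION"`
#'     (platelet transfusion; the bolus amount is the model's
#'     `transfusion_boost` parameter, `amt` records the number of units)}
#'   \item{amt}{event amount}
#'   \item{dv}{platelet count, 1e9/L (observation rows)}
#'   \item{tp}{serum total protein, g/dL (optional; rows with a value form
#'     the covariate series)}
#'   \item{donor_relation, conditioning_start, conditioning_stop}{subject
#'     constants, repeated on every row}
#' }
#'
#' @param path CSV file path.
#' @return list of `plt_subject` objects (without simulation truth), one per
#'   unique `id`, rows time-sorted.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "time", "evid", "cmt", "amt", "dv",
                "donor_relation", "conditioning_start", "conditioning_stop")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"tp" %in% names(df)) df$tp <- NA_real_
  if (any(!is.finite(df$time)))
    stop("non-finite time in row(s) ",
         paste(head(which(!is.finite(df$time))), collapse = ", "),
         " (column 'time')")
  bad_evid <- which(!df$evid %in% c(0, 1))
  if (length(bad_evid))
    stop("invalid evid in row ", bad_evid[1], " (column 'evid'): ",
         df$evid[bad_evid[1]])
  bad_obs <- which(df$evid == 0 & is.na(df$dv) & is.na(df$tp))
  if (length(bad_obs))
    stop("observation row ", bad_obs[1], " has neither dv nor tp")
  bad_ev <- which(df$evid == 1 & (is.na(df$amt) | is.na(df$cmt) |
                                    df$cmt == ""))
  if (length(bad_ev))
    stop("event row ", bad_ev[1], " lacks amt or cmt")
  obs_rows <- df$evid == 0 & !is.na(df$dv)
  n_dup <- sum(duplicated(df[obs_rows, c("id", "time")])) +
    sum(duplicated(df[df$evid == 1, c("id", "time", "cmt")]))
  if (n_dup > 0)
    warning(n_dup, " duplicate observation/event row(s) kept")

  lapply(split(df, df$id), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    obs <- d[d$evid == 0 & !is.na(d$dv), c("time", "dv")]
    names(obs) <- c("time", "platelet")
    tp <- d[!is.na(d$tp), c("time", "tp")]
    atg <- d[d$evid == 1 & d$cmt == "ATG", c("time", "amt")]
    trf <- d[d$evid == 1 & d$cmt == "TRANSFUSION", "time"]
    regimen <- treatment_regimen(
      conditioning_start = d$conditioning_start[1],
      conditioning_stop = d$conditioning_stop[1],
      atg_doses = if (nrow(atg)) data.frame(time = atg$time,
                                            dose = atg$amt),
      transfusion_times = trf,
      donor_relation = d$donor_relation[1])
    covariates <- if (nrow(tp)) covariate_series(tp$time, tp$tp)
    structure(list(id = d$id[1], observations = obs, regimen = regimen,
                   covariates = covariates, true_params = NULL,
                   true_label = NULL),
              class = "plt_subject")
  })
}

#' Write subjects as a NONMEM-style event-record dataset
#'
#' Inverse of [read_dataset()]; the written file round-trips to the same
#' logical content (numbers are written at full double precision).
#'
#' @param subjects list of `plt_subject` (or a `plt_cohort`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(subjects, path) {
  if (inherits(subjects, "plt_cohort")) subjects <- subjects$subjects
  if (inherits(subjects, "plt_subject")) subjects <- list(subjects)
  rows <- lapply(subjects, function(s) {
    reg <- s$regimen
    base <- data.frame(id = s$id, time = s$observations$time, evid = 0,
                       cmt = "", amt = NA_real_,
                       dv = s$observations$platelet, tp = NA_real_)
    if (!is.null(s$covariates) && length(s$covariates$time))
      base <- rbind(base, data.frame(id = s$id, time = s$covariates$time,
                                     evid = 0, cmt = "", amt = NA_real_,
                                     dv = NA_real_,
                                     tp = s$covariates$total_protein))
    if (!is.null(reg$atg_doses) && nrow(reg$atg_doses))
      base <- rbind(base, data.frame(id = s$id, time = reg$atg_doses$time,
                                     evid = 1, cmt = "ATG",
                                     amt = reg$atg_doses$dose,
                                     dv = NA_real_, tp = NA_real_))
    if (length(reg$transfusion_times))
      base <- rbind(base, data.frame(id = s$id,
                                     time = reg$transfusion_times,
                                     evid = 1, cmt = "TRANSFUSION", amt = 1,
                                     dv = NA_real_, tp = NA_real_))
    base$donor_relation <- reg$donor_relation
    base$conditioning_start <- reg$conditioning_start
    base$conditioning_stop <- reg$conditioning_stop
    base[order(base$time, base$evid), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(0), time = numeric(0), evid = numeric(0),
                      cmt = character(0), amt = numeric(0), dv = numeric(0),
                      tp = numeric(0), donor_relation = character(0),
                      conditioning_start = numeric(0),
                      conditioning_stop = numeric(0))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
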
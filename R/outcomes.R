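#' Classify post-HCT thrombocytopenia
#'
#' The study endpoint: a subject is thrombocytopenic if the mean of the last
#' `k` platelet measurements inside the evaluation window (day +29 to the
#' latest measurement within +180 by default) is strictly below `threshold`.
#' Subjects with fewer than `k` in-window values use all available ones;
#' subjects with none get an undefined label (`NA`).
#'
#' @param observations data frame with columns `time` and `platelet`,
#'   time-sorted.
#' @param window_start,window_end evaluation window, days (29 and 180).
#' @param k number of trailing measurements averaged (12).
#' @param threshold thrombocytopenia threshold, 1e9/L (75).
#' @return `TRUE`, `FALSE`, or `NA` (no in-window measurement).
#' @examples
#' obs <- data.frame(time = seq(100, 155, 5), platelet = rep(74, 12))
#' classify_thrombocytopenia(obs)  # TRUE
#' @export
classify_thrombocytopenia <- function(observations, window_start = 29,
                                      window_end = 180, k = 12,
                                      threshold = 75) {
  stopifnot(all(c("time", "platelet") %in% names(observations)))
  if (is.unsorted(observations$time)) stop("observations must be time-sorted")
  v <- observations$platelet[observations$time >= window_start &
                               observations$time <= window_end]
  if (!length(v)) return(NA)
  mean(tail(v, k)) < threshold
}

#' Trailing-mean thrombocytopenia score
#'
#' The continuous quantity behind [classify_thrombocytopenia()]: the mean of
#' the last `k` in-window values. For ROC analysis the score is used negated
#' (larger = more at risk).
#'
#' @inheritParams classify_thrombocytopenia
#' @return the trailing mean, or `NA` if no in-window value exists.
#' @export
thrombocytopenia_score <- function(observations, window_start = 29,
                                   window_end = 180, k = 12) {
  if (is.unsorted(observations$time)) stop("observations must be time-sorted")
  v <- observations$platelet[observations$time >= window_start &
                               observations$time <= window_end]
  if (!length(v)) return(NA_real_)
  mean(tail(v, k))
}

#' Platelet engraftment day
#'
#' First day `d` such that the daily platelet counts at `d`, `d + 1`, ...,
#' `d + run - 1` are all at or above `threshold` (20e9/L by default; the
#' conventional definition uses three consecutive days).
#'
#' @param platelets daily platelet counts.
#' @param days consecutive integer days the counts belong to (defaults to
#'   `0, 1, ...`); gaps are an error -- resample the series first.
#' @param threshold engraftment threshold, 1e9/L.
#' @param run required number of consecutive days.
#' @return the engraftment day, or `NA` if the criterion is never met.
#' @examples
#' engraftment_day(c(21, 19, 22, 23, 24), days = 5:9)  # 7
#' @export
engraftment_day <- function(platelets, days = seq_along(platelets) - 1,
                            threshold = 20, run = 3) {
  if (length(platelets) != length(days)) stop("length mismatch")
  if (length(days) > 1 && any(diff(days) != 1))
    stop("days must be consecutive integers; resample the series first")
  ok <- platelets >= threshold
  if (length(ok) < run) return(NA_real_)
  for (j in seq_len(length(ok) - run + 1)) {
    if (all(ok[j:(j + run - 1)])) return(days[j])
  }
  NA_real_
}

#' Engraftment day of a simulated trajectory
#'
#' Applies [engraftment_day()] to the daily readout of a trajectory. Because
#' simulated counts at day 0 still contain pre-transplant platelets, the scan
#' is anchored at the post-HCT daily nadir: the reported day is the first
#' sustained recovery at or after the minimum (see the methods vignette).
#'
#' @param traj a `plt_trajectory` covering at least day 0 to `to`.
#' @param to last day considered (180).
#' @param threshold,run as in [engraftment_day()].
#' @return engraftment day, or `NA`.
#' @export
trajectory_engraftment <- function(traj, to = 180, threshold = 20, run = 3) {
  days <- 0:to
  v <- trajectory_at(traj, days)
  anchor <- which.min(v)
  engraftment_day(v[anchor:length(v)], days[anchor:length(v)],
                  threshold = threshold, run = run)
}

#' Mean relative deviation between predicted and observed profiles
#'
#' `mean(|pred - obs| / obs)` over paired values; zero-valued observations
#' are skipped with a warning.
#'
#' @param predicted,observed numeric vectors at common times.
#' @return the mean relative deviation.
#' @examples
#' mean_relative_deviation(c(50, 100), c(100, 100))  # 0.25
#' @export
mean_relative_deviation <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  keep <- observed > 0
  if (any(!keep)) warning(sum(!keep), " zero observation(s) skipped")
  mean(abs(predicted[keep] - observed[keep]) / observed[keep])
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) AUROC with midrank tie handling; the probability that
#' a randomly chosen case scores higher than a randomly chosen control.
#'
#' @param scores numeric risk scores (larger = more at risk).
#' @param labels logical or 0/1 outcome labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))  # 1
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels))
    stop("both outcome classes must be present")
  r <- suppressMessages(pROC::roc(response = labels, predictor = scores,
                                  direction = "<", quiet = TRUE))
  as.numeric(pROC::auc(r))
}

#' Percentile bootstrap confidence interval for the AUROC
#'
#' Resamples subjects with replacement `n_boot` times; resamples with a
#' single outcome class are skipped and counted.
#'
#' @param scores,labels as in [auroc()].
#' @param n_boot number of bootstrap resamples (1000).
#' @param level confidence level (0.95).
#' @param seed integer seed.
#' @return list with `lower`, `upper`, `point`, `n_skipped`.
#' @export
bootstrap_auroc_ci <- function(scores, labels, n_boot = 1000, level = 0.95,
                               seed = 1) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  point <- auroc(scores, labels)
  set.seed(as.integer(seed))
  n <- length(scores)
  vals <- numeric(0)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (!any(labels[idx]) || all(labels[idx])) {
      skipped <- skipped + 1L
      next
    }
    vals <- c(vals, auroc(scores[idx], labels[idx]))
  }
  a <- (1 - level) / 2
  ci <- quantile(vals, c(a, 1 - a), names = FALSE)
  list(lower = ci[1], upper = ci[2], point = point, n_skipped = skipped)
}

#' Cross-validated forecasting performance on a cohort
#'
#' Splits a cohort into `n_folds` subject-level folds and computes, per fold
#' and per prediction-day cutoff, the MAP-forecast AUROC for thrombocytopenia
#' (risk score: negated predicted trailing mean; label: observed series).
#' Folds lacking one of the outcome classes are flagged with `NA`.
#'
#' @param cohort a `plt_cohort` (see [generate_cohort()]) or list of
#'   `plt_subject`.
#' @param pop a `plt_population` prior.
#' @param n_folds number of folds (5).
#' @param cutoffs prediction-day cutoffs (7, 14, 21, 28).
#' @param seed integer seed governing fold assignment.
#' @param ... passed to [forecast()].
#' @return data frame with columns `fold`, `cutoff`, `auroc`, `n`,
#'   `n_cases`.
#' @export
crossvalidate <- function(cohort, pop, n_folds = 5,
                          cutoffs = c(7, 14, 21, 28), seed = 1, ...) {
  subjects <- if (inherits(cohort, "plt_cohort")) cohort$subjects else cohort
  n <- length(subjects)
  if (n < n_folds) stop("cohort smaller than the number of folds")
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(n_folds), n))
  res <- list()
  for (co in cutoffs) {
    sc <- vapply(subjects, function(s)
      forecast(s, pop, cutoff_day = co, interval = FALSE, ...)$score,
      numeric(1))
    lab <- vapply(subjects, function(s)
      classify_thrombocytopenia(s$observations), logical(1))
    for (f in seq_len(n_folds)) {
      i <- fold == f & !is.na(lab)
      a <- if (sum(lab[i]) == 0 || all(lab[i])) NA_real_
           else auroc(sc[i], lab[i])
      res[[length(res) + 1]] <- data.frame(fold = f, cutoff = co, auroc = a,
                                           n = sum(i), n_cases = sum(lab[i]))
    }
  }
  do.call(rbind, res)
}

#' Evaluate forecasting performance on a cohort
#'
#' For each cutoff: MAP forecasts for every subject, thrombocytopenia AUROC
#' with bootstrap CI, and per-subject mean relative deviations of the
#' predicted profile against the observations in the common prediction
#' period (day +29 to the latest measurement). Deviations are summarized by
#' their median as well as their mean: the observation-normalized ratio is
#' unstable for subjects with near-zero observed counts, which can dominate
#' the mean.
#'
#' @inheritParams crossvalidate
#' @param n_boot bootstrap resamples for the CI.
#' @return object of class `plt_evaluation`: list with `per_cutoff` (data
#'   frame), `mrd` (list of per-subject deviations per cutoff), `labels`.
#' @export
evaluate_cohort <- function(cohort, pop, cutoffs = c(7, 14, 21, 28),
                            n_boot = 1000, seed = 1, ...) {
  subjects <- if (inherits(cohort, "plt_cohort")) cohort$subjects else cohort
  lab <- vapply(subjects, function(s)
    classify_thrombocytopenia(s$observations), logical(1))
  rows <- list()
  mrds <- list()
  for (co in cutoffs) {
    fc <- lapply(subjects, forecast, pop = pop, cutoff_day = co,
                 interval = FALSE, ...)
    sc <- vapply(fc, `[[`, numeric(1), "score")
    ok <- !is.na(lab) & !is.na(sc)
    ci <- bootstrap_auroc_ci(sc[ok], lab[ok], n_boot = n_boot,
                             seed = derive_seed(seed, co))
    # deviations are evaluated on the common prediction period (day +29
    # to the latest measurement) so cutoffs are compared on equal footing
    mrd <- mapply(function(f, s) {
      post <- s$observations[s$observations$time >= 29, , drop = FALSE]
      if (!nrow(post)) return(NA_real_)
      mean_relative_deviation(trajectory_at(f$trajectory, post$time),
                              post$platelet)
    }, fc, subjects)
    rows[[length(rows) + 1]] <- data.frame(
      cutoff = co, auroc = ci$point, lower = ci$lower, upper = ci$upper,
      median_mrd = median(mrd, na.rm = TRUE),
      mean_mrd = mean(mrd, na.rm = TRUE), n = sum(ok), n_cases = sum(lab[ok]))
    mrds[[as.character(co)]] <- mrd
  }
  structure(list(per_cutoff = do.call(rbind, rows), mrd = mrds,
                 labels = lab),
            class = "plt_evaluation")
}

#' @export
print.plt_evaluation <- function(x, ...) {
  cat("Thrombocytopenia-forecast evaluation\n")
  tab <- x$per_cutoff
  tab$auroc <- sprintf("%.3f [%.3f, %.3f]", tab$auroc, tab$lower, tab$upper)
  print(tab[, c("cutoff", "auroc", "median_mrd", "n", "n_cases")],
        row.names = FALSE)
  invisible(x)
}
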
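test_that("thrombocytopenia is the strict trailing-12 mean below 75", {
  t12 <- seq(120, 175, by = 5)
  expect_true(classify_thrombocytopenia(
    data.frame(time = t12, platelet = rep(74, 12))))
  expect_false(classify_thrombocytopenia(
    data.frame(time = t12, platelet = rep(75, 12))))
  # only the last 12 in-window values count
  obs <- data.frame(time = seq(30, 125, by = 5),
                    platelet = c(rep(40, 8), rep(100, 12)))
  expect_false(classify_thrombocytopenia(obs))
  # values outside the window are ignored; an empty window is undefined
  expect_true(is.na(classify_thrombocytopenia(
    data.frame(time = c(-5, 10, 20), platelet = c(200, 10, 10)))))
  # fewer than 12 in-window values: all available ones are used
  expect_true(classify_thrombocytopenia(
    data.frame(time = c(40, 60), platelet = c(50, 60))))
  expect_error(classify_thrombocytopenia(
    data.frame(time = c(50, 40), platelet = c(1, 2))), "sorted")
})

test_that("engraftment is the first of three consecutive days at 20 or above", {
  expect_equal(engraftment_day(rep(25, 20), days = 10:29), 10)
  expect_equal(engraftment_day(c(21, 19, 22, 23, 24), days = 5:9), 7)
  expect_true(is.na(engraftment_day(rep(19.9, 50))))
  expect_equal(engraftment_day(c(20, 20, 19, 20, 20, 20), days = 0:5), 3)
  expect_error(engraftment_day(c(20, 20, 20), days = c(1, 2, 4)),
               "consecutive")
})

test_that("mean relative deviation is observation-normalized and absolute", {
  expect_equal(mean_relative_deviation(c(5, 5), c(5, 5)), 0)
  expect_equal(mean_relative_deviation(c(10, 20), c(5, 10)), 1)
  expect_equal(mean_relative_deviation(c(50, 100), c(100, 100)), 0.25)
  expect_warning(v <- mean_relative_deviation(c(1, 2), c(0, 4)), "skipped")
  expect_equal(v, 0.5)
})

test_that("AUROC equals exhaustive pair counting, with midrank ties", {
  pair_count_auroc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
  }
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.2, 0.8, 0.1), c(1, 0, 0, 1)),
               pair_count_auroc(c(0.9, 0.2, 0.8, 0.1), c(1, 0, 0, 1)))
  s <- c(0.5, 0.5, 0.7, 0.1, 0.5, 0.9)
  l <- c(1, 0, 1, 0, 0, 1)
  expect_equal(auroc(s, l), pair_count_auroc(s, l))
  set.seed(8)
  s2 <- rnorm(4000); l2 <- rbinom(4000, 1, 0.4)  # independent of the score
  expect_lt(abs(auroc(s2, l2) - 0.5), 0.03)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "classes")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(9)
  s <- rnorm(200)
  l <- rbinom(200, 1, plogis(1.5 * s))
  a <- auroc(s, l)
  expect_equal(auroc(exp(s), l), a)
  expect_equal(auroc(atan(s) * 3 - 2, l), a)
})

test_that("the bootstrap CI is reproducible, covers the point estimate, and
           narrows with sample size", {
  set.seed(10)
  make <- function(n) {
    s <- rnorm(n)
    list(s = s, l = rbinom(n, 1, plogis(2 * s)))
  }
  d <- make(60)
  ci1 <- bootstrap_auroc_ci(d$s, d$l, n_boot = 400, seed = 3)
  ci2 <- bootstrap_auroc_ci(d$s, d$l, n_boot = 400, seed = 3)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$point)
  expect_gte(ci1$upper, ci1$point)
  d2 <- make(600)
  ci3 <- bootstrap_auroc_ci(d2$s, d2$l, n_boot = 400, seed = 3)
  expect_lt(ci3$upper - ci3$lower, ci1$upper - ci1$lower)
})

test_that("thrombocytopenia prediction improves with later cutoffs", {
  # the study's cutoff ordering, averaged over 20 replicate synthetic
  # cohorts of 12 subjects each
  ec <- eval_cohort()
  groups <- split(seq_along(ec$subjects), (seq_along(ec$subjects) - 1) %/% 12)
  auc_by_cutoff <- vapply(as.character(ec$cutoffs), function(co) {
    per_cohort <- vapply(groups, function(idx) {
      sc <- vapply(ec$fits[idx], function(f) f[[co]]$score, numeric(1))
      lab <- ec$labels[idx]
      ok <- !is.na(sc) & !is.na(lab)
      if (sum(lab[ok]) == 0 || all(lab[ok])) return(NA_real_)
      auroc(sc[ok], lab[ok])
    }, numeric(1))
    mean(per_cohort, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(auc_by_cutoff) >= -0.015))
  expect_gt(auc_by_cutoff[["28"]], auc_by_cutoff[["7"]])
})

test_that("cross-validation is deterministic and flags degenerate folds", {
  ec <- eval_cohort()
  sub <- ec$subjects[1:20]
  pop <- ec$pop
  cv1 <- crossvalidate(sub, pop, n_folds = 4, cutoffs = 7, seed = 2)
  cv2 <- crossvalidate(sub, pop, n_folds = 4, cutoffs = 7, seed = 2)
  expect_identical(cv1, cv2)
  cv3 <- crossvalidate(sub, pop, n_folds = 4, cutoffs = 7, seed = 3)
  expect_equal(sum(cv3$n_cases), sum(cv1$n_cases))  # labels are fixed
  expect_equal(sum(cv3$n), sum(cv1$n))
  # a fold with a single outcome class yields a flagged (NA) AUROC
  same_label <- sub[which(ec$labels[1:20] == FALSE)[1:4]]
  cv4 <- crossvalidate(same_label, pop, n_folds = 2, cutoffs = 7, seed = 1)
  expect_true(all(is.na(cv4$auroc)))
})
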
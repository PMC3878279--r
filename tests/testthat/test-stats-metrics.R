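# Evaluation battery: confusion metrics, kappa, ROC/AUC, cutoff
# determination, Mann-Whitney, Spearman, CV — each against an independent
# oracle.

test_that("a perfect classifier scores 1.0 on every metric and kappa", {
  ct <- confusion_table(tp = 10, fn = 0, fp = 0, tn = 10)
  m <- screening_metrics(ct)
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv", "accuracy")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1, accuracy = 1))
  expect_equal(cohen_kappa(ct), 1)
  expect_equal(cohen_kappa(confusion_table(50, 0, 0, 50)), 1)
})

test_that("metrics with empty margins are undefined, never zero", {
  m <- screening_metrics(confusion_table(tp = 0, fn = 0, fp = 2, tn = 8))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$ppv, 0)  # tp + fp = 2 here, so defined (and genuinely 0)
  m2 <- screening_metrics(confusion_table(tp = 0, fn = 0, fp = 0, tn = 8))
  expect_true(is.na(m2$sensitivity) && is.na(m2$ppv))
  expect_equal(m2$accuracy, 1)
  expect_error(screening_metrics(confusion_table(0, 0, 0, 0)),
               class = "ana_domain_error")
})

test_that("kappa stays in [-1, 1], is 1 only without discordance, and ~0 under shuffling", {
  set.seed(19)
  for (i in 1:50) {
    ct <- confusion_table(sample(0:30, 1), sample(0:30, 1),
                          sample(0:30, 1), sample(1:30, 1))
    k <- cohen_kappa(ct)
    if (!is.na(k)) {
      expect_gte(k, -1); expect_lte(k, 1)
      if (ct$fp == 0 && ct$fn == 0) expect_equal(k, 1)
      if (k == 1) expect_true(ct$fp == 0 && ct$fn == 0)
    }
  }
  # independent raters: expected kappa 0
  kbar <- mean(replicate(300, {
    truth <- runif(100) < 0.5
    pred <- runif(100) < 0.5
    cohen_kappa(confusion_table(sum(pred & truth), sum(!pred & truth),
                                sum(pred & !truth), sum(!pred & !truth)))
  }))
  expect_lt(abs(kbar), 0.02)
})

test_that("kappa interpretation bands switch at 0.4 and 0.75", {
  expect_equal(kappa_interpretation(0.39), "poor")
  expect_equal(kappa_interpretation(0.4), "fair to good")
  expect_equal(kappa_interpretation(0.75), "fair to good")
  expect_equal(kappa_interpretation(0.751), "excellent")
})

test_that("AUC equals the tie-adjusted pairwise comparison probability", {
  # perfectly separated scores
  r <- roc_curve(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  # random small instances, with heavy ties, against the double loop
  set.seed(5)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(1:4, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
    expect_equal(roc_curve(scores, labels)$auc, auc_pairwise(scores, labels),
                 tolerance = 1e-12)
  }
  # label-independent scores hover around chance
  set.seed(6)
  aucs <- replicate(60, roc_curve(rnorm(80), runif(80) < 0.5)$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), class = "ana_domain_error")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(40)
  scores <- c(rnorm(30, 1.3, 0.2), rnorm(30, 1.1, 0.2))
  labels <- rep(c(TRUE, FALSE), each = 30)
  expect_equal(roc_curve(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("the accuracy curve matches brute-force reclassification", {
  set.seed(9)
  scores <- round(rnorm(30, 1.3, 0.25), 2)
  labels <- runif(30) < 0.5
  labels[1:2] <- c(TRUE, FALSE)
  curve <- accuracy_curve(scores, labels)
  for (i in seq_len(nrow(curve))) {
    expect_equal(curve$accuracy[i], accuracy_at(scores, labels, curve$cutoff[i]))
  }
  expect_error(accuracy_curve(scores, rep(FALSE, 30)), class = "ana_domain_error")
})

test_that("the calibrated cutoff maximises accuracy with a smallest-cutoff tie-break", {
  res <- determine_cutoff(c(1.0, 1.1, 1.5, 1.6), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$cutoff, 1.3)
  expect_equal(res$accuracy_at_cutoff, 1)
  expect_equal(res$criterion, "max-accuracy")

  set.seed(27)
  for (i in 1:20) {
    scores <- round(rnorm(25, 1.3, 0.3), 2)
    labels <- c(TRUE, FALSE, runif(23) < 0.5)
    res <- determine_cutoff(scores, labels)
    cand <- c(-Inf, (function(s) (s[-1] + s[-length(s)]) / 2)(sort(unique(scores))), Inf)
    accs <- vapply(cand, function(t) accuracy_at(scores, labels, t), numeric(1))
    expect_equal(res$accuracy_at_cutoff, max(accs))
    expect_equal(res$cutoff, cand[which.max(accs)])  # ties -> smallest
    # consistency: the confusion table induced by the cutoff reproduces it
    pred <- scores >= res$cutoff
    ct <- confusion_table(sum(pred & labels), sum(!pred & labels),
                          sum(pred & !labels), sum(!pred & !labels))
    expect_equal(screening_metrics(ct)$accuracy, res$accuracy_at_cutoff)
  }
})

test_that("cutoff recovery on a cohort built around a known boundary", {
  set.seed(81)
  scores <- c(rnorm(103, 1.13, 0.06), pmax(rnorm(134, 2.06, 1.18), 1.3))
  labels <- rep(c(FALSE, TRUE), c(103, 134))
  res <- determine_cutoff(scores, labels)
  expect_lt(abs(res$cutoff - 1.25), 0.1)
})

test_that("Youden calibration maximises sensitivity + specificity - 1", {
  set.seed(55)
  scores <- round(rnorm(40, 1.3, 0.3), 2)
  labels <- c(TRUE, FALSE, runif(38) < 0.4)
  res <- determine_cutoff(scores, labels, criterion = "youden")
  j_at <- function(t) {
    mean(scores[labels] >= t) - mean(scores[!labels] >= t)
  }
  cand <- c(-Inf, (function(s) (s[-1] + s[-length(s)]) / 2)(sort(unique(scores))), Inf)
  expect_equal(j_at(res$cutoff), max(vapply(cand, j_at, numeric(1))))
})

test_that("Mann-Whitney matches exact enumeration and wilcox on larger samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 of the 20 assignments are as extreme

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  set.seed(31)
  for (i in 1:10) {
    a <- round(runif(sample(2:6, 1), 0, 4))  # ties likely
    b <- round(runif(sample(2:6, 1), 0, 4))
    got <- mann_whitney_u(a, b)
    want <- mw_exact_brute(a, b)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  # tie-free large samples: normal approximation equals wilcox.test's
  set.seed(32)
  a <- rnorm(25); b <- rnorm(30, 0.4)
  got <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), 1:3), class = "ana_domain_error")
})

test_that("FI distributions as observed in screening separate with p < 0.0001", {
  set.seed(3)
  neg <- rnorm(100, 1.13, 0.06)
  pos <- pmax(rnorm(100, 2.06, 1.18), 1)
  expect_lt(mann_whitney_u(pos, neg)$p, 1e-4)
})

test_that("Spearman matches rank-then-Pearson and the t-approximation", {
  x <- 1:10
  expect_equal(spearman_rho(x, x^2)$rho, 1)
  expect_equal(spearman_rho(x, -x - 3)$rho, -1)
  expect_equal(spearman_rho(x, x^2)$p, 0)

  set.seed(44)
  for (i in 1:10) {
    x <- round(rnorm(15), 1)
    y <- round(rnorm(15) + 0.4 * x, 1)
    got <- spearman_rho(x, y)
    expect_equal(got$rho, spearman_brute(x, y), tolerance = 1e-12)
    ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), class = "ana_domain_error")
})

test_that("the CV is the percent ratio of sample SD to mean", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 100 * sqrt(2) / 2)
  expect_error(coefficient_of_variation(c(3)), class = "ana_domain_error")
  expect_error(coefficient_of_variation(c(-1, 1)), class = "ana_domain_error")
  # replicate FI wells at a relative spread of 8.6% land near that CV
  for (seed in c(2, 12, 33)) {
    set.seed(seed)
    reps <- rnorm(10, 1.33, 0.086 * 1.33)
    cv <- coefficient_of_variation(reps)
    expect_gt(cv, 6); expect_lt(cv, 11)
  }
})
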
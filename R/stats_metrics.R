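# Evaluation battery for screening performance against the visual read:
# confusion-table metrics, Cohen's kappa, ROC/AUC, accuracy-vs-cutoff
# calibration, Mann-Whitney U, Spearman rank correlation, coefficient of
# variation. The positive-call convention is score >= threshold throughout,
# matching classify().

#' 2x2 confusion table (visual read = truth, algorithm = prediction)
#'
#' @param tp,fn,fp,tn Nonnegative counts: visually positive wells called
#'   positive/negative by the algorithm (`tp`/`fn`) and visually negative
#'   wells called positive/negative (`fp`/`tn`).
#' @return An object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    ana_domain_error("confusion counts must be nonnegative")
  }
  structure(as.list(counts), class = "confusion_table")
}

#' Screening performance metrics from a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive values `tp/(tp+fp)` and `tn/(tn+fn)`, and accuracy —
#' the proportion of all wells on which the algorithm agrees with the
#' visual read, `(tp+tn)/total`. A metric whose denominator is zero is
#' reported as `NA` (undefined), never as 0.
#'
#' @param table A [confusion_table()].
#' @return An object of class `screening_metrics` with fields
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
screening_metrics <- function(table) {
  if (!inherits(table, "confusion_table")) ana_format_error("table must be a confusion_table")
  tp <- table$tp; fn <- table$fn; fp <- table$fp; tn <- table$tn
  total <- tp + fn + fp + tn
  if (total <= 0) ana_domain_error("empty confusion table")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp),
         ppv = ratio(tp, tp + fp),
         npv = ratio(tn, tn + fn),
         accuracy = (tp + tn) / total),
    class = "screening_metrics")
}

#' Cohen's kappa for visual/algorithm agreement
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (tp+tn)/total` and chance agreement
#' `p_e = [(tp+fn)(tp+fp) + (tn+fp)(tn+fn)] / total^2`. Kappa is 0 when
#' agreement is at chance level and 1 when agreement is perfect. If
#' `p_e = 1` (both raters constant) kappa is 1 under perfect agreement and
#' undefined (`NA`) otherwise.
#'
#' @param table A [confusion_table()].
#' @return Kappa in \[-1, 1\], or `NA` when undefined.
#' @export
cohen_kappa <- function(table) {
  if (!inherits(table, "confusion_table")) ana_format_error("table must be a confusion_table")
  tp <- table$tp; fn <- table$fn; fp <- table$fp; tn <- table$tn
  total <- tp + fn + fp + tn
  if (total <= 0) ana_domain_error("empty confusion table")
  p_o <- (tp + tn) / total
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / total^2
  if (p_e == 1) return(if (p_o == 1) 1 else NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Qualitative agreement band for a kappa value
#'
#' Conventional interpretation bands: below 0.4 "poor", 0.4 to 0.75
#' "fair to good", above 0.75 "excellent".
#'
#' @param kappa Kappa value in \[-1, 1\].
#' @return One of `"poor"`, `"fair to good"`, `"excellent"`.
#' @export
kappa_interpretation <- function(kappa) {
  if (!is.finite(kappa) || kappa < -1 || kappa > 1) ana_domain_error("kappa must be in [-1, 1]")
  if (kappa < 0.4) "poor" else if (kappa <= 0.75) "fair to good" else "excellent"
}

# Candidate thresholds for a score vector: midpoints between consecutive
# sorted unique scores, bracketed by -Inf (call everything positive) and
# +Inf (call nothing positive). Invariant to monotone relabeling.
threshold_candidates <- function(scores) {
  s <- sort(unique(scores))
  mids <- if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  c(-Inf, mids, Inf)
}

check_two_classes <- function(scores, labels) {
  if (length(scores) != length(labels)) ana_domain_error("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) ana_domain_error("scores and labels must be complete")
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) ana_domain_error("both classes must be present")
  labels
}

#' ROC curve and AUC for FI scores against visual labels
#'
#' Sweeps thresholds over the midpoints of consecutive sorted unique scores
#' plus infinite sentinels, calling a well positive when its score is at or
#' above the threshold. AUC is the trapezoidal area over
#' (1 - specificity, sensitivity), which equals the tie-adjusted
#' probability that a random positive scores above a random negative
#' (ties counted half).
#'
#' @param scores Numeric FI values.
#' @param labels Truth labels (logical, or coercible; TRUE = visually
#'   positive). Both classes must be present.
#' @return An object of class `roc_curve`: `points` (data frame with
#'   `threshold`, `sensitivity`, `fpr`, ordered by threshold) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_two_classes(scores, labels)
  thr <- threshold_candidates(scores)
  pos <- scores[labels]; neg <- scores[!labels]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  ord <- order(fpr, sens)  # increasing FPR for integration
  x <- fpr[ord]; y <- sens[ord]
  auc <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  structure(
    list(points = data.frame(threshold = thr, sensitivity = sens, fpr = fpr),
         auc = auc),
    class = "roc_curve")
}

#' Accuracy as a function of the FI cutoff
#'
#' Accuracy — correct calls over total wells — evaluated at every candidate
#' threshold of the ROC sweep.
#'
#' @inheritParams roc_curve
#' @return Data frame with columns `cutoff` and `accuracy`.
#' @export
accuracy_curve <- function(scores, labels) {
  labels <- check_two_classes(scores, labels)
  thr <- threshold_candidates(scores)
  acc <- vapply(thr, function(t) mean((scores >= t) == labels), numeric(1))
  data.frame(cutoff = thr, accuracy = acc)
}

#' Determine the screening cutoff from labelled FI scores
#'
#' Default criterion `"max-accuracy"`: the candidate cutoff maximising
#' accuracy, ties broken towards the smallest cutoff (favouring
#' sensitivity). Alternative `"youden"`: maximise Youden's J
#' (sensitivity + specificity - 1), same tie-break.
#'
#' @inheritParams roc_curve
#' @param criterion `"max-accuracy"` (default) or `"youden"`.
#' @return An object of class `cutoff_result`: `cutoff`,
#'   `accuracy_at_cutoff`, `criterion`.
#' @export
determine_cutoff <- function(scores, labels, criterion = c("max-accuracy", "youden")) {
  criterion <- match.arg(criterion)
  labels <- check_two_classes(scores, labels)
  curve <- accuracy_curve(scores, labels)
  if (criterion == "max-accuracy") {
    objective <- curve$accuracy
  } else {
    roc <- roc_curve(scores, labels)
    objective <- roc$points$sensitivity - roc$points$fpr
  }
  best <- which(objective == max(objective))[1]  # candidates sorted ascending
  structure(
    list(cutoff = curve$cutoff[best],
         accuracy_at_cutoff = curve$accuracy[best],
         criterion = criterion),
    class = "cutoff_result")
}

#' Mann-Whitney U test for a shift between two FI groups
#'
#' U is computed from the rank sum of the first group with average ranks on
#' ties. When both groups have at most 8 observations the two-sided p-value
#' is found by exact enumeration of all group assignments (valid under
#' ties); otherwise the normal approximation with tie-corrected variance
#' and continuity correction is used.
#'
#' @param group_a,group_b Numeric vectors, both nonempty.
#' @return List with `U` (for `group_a`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) ana_domain_error("both groups must be nonempty")
  if (anyNA(group_a) || anyNA(group_b)) ana_domain_error("groups must be complete")
  n1 <- length(group_a); n2 <- length(group_b); n <- n1 + n2
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n1 <= 8L && n2 <= 8L) {
    sets <- combn(n, n1)
    u_all <- apply(sets, 2, function(ix) sum(rk[ix])) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = u, p = 1))
    dev <- abs(u - mu)
    z <- max(dev - 0.5, 0) / sqrt(sigma2)  # continuity correction towards the mean
    p <- min(1, 2 * pnorm(-z))
  }
  list(U = u, p = p)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of the average-ranked data (ties
#' allowed); the two-sided p-value uses
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `rho` and `p` (two-sided).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) ana_domain_error("x and y differ in length")
  n <- length(x)
  if (n < 3L) ana_domain_error("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) ana_domain_error("x and y must be complete")
  if (sd(x) == 0 || sd(y) == 0) ana_domain_error("rho undefined for a constant vector")
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(t_stat), df = n - 2))
}

#' Coefficient of variation of replicate FI measurements
#'
#' `100 * sd / mean` in percent, with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector, n >= 2, nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) ana_domain_error("need at least 2 values")
  if (anyNA(values)) ana_domain_error("values must be complete")
  m <- mean(values)
  if (m == 0) ana_domain_error("CV undefined for zero mean")
  100 * sd(values) / m
}
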
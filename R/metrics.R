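#' Binary confusion table
#'
#' Container for the four counts of a two-class contingency table. For the
#' movement-detection stage the positive class is movement (negative: rest);
#' for the laterality stage the positive class is a left-cued movement
#' (negative: right). All evaluation statistics in this package are functions
#' of this table.
#'
#' @param tp,fp,tn,fn Non-negative counts of true positives, false
#'   positives, true negatives and false negatives.
#' @return An object of class `confusion_table`.
#' @examples
#' ct <- confusion_table(tp = 40, fp = 10, tn = 30, fn = 20)
#' basic_rates(ct)$sensitivity
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("confusion table entries must be finite and non-negative")
  if (sum(counts) < 1) stop("confusion table must contain at least one count")
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(m)
  invisible(x)
}

# Tally a binary confusion table from truth/prediction vectors coded 0/1.
tally_confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion_table(tp = sum(truth == 1 & predicted == 1),
                  fp = sum(truth == 0 & predicted == 1),
                  tn = sum(truth == 0 & predicted == 0),
                  fn = sum(truth == 1 & predicted == 0))
}

# Add two confusion tables (micro pooling across folds).
add_confusion <- function(a, b) {
  confusion_table(a$tp + b$tp, a$fp + b$fp, a$tn + b$tn, a$fn + b$fn)
}

#' Basic classification rates from a confusion table
#'
#' Computes overall accuracy, sensitivity (detection rate, TPR), specificity
#' (TNR), overall error rate (OER = 1 - accuracy), false positive and false
#' negative rates, and precision. Any rate whose denominator is zero is
#' reported as an explicit not-a-value with a reason attribute.
#'
#' @param ct A [confusion_table()].
#' @return Named list of rates in `[0, 1]`.
#' @export
basic_rates <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  total <- ct$tp + ct$fp + ct$tn + ct$fn
  pos <- ct$tp + ct$fn
  neg <- ct$tn + ct$fp
  ppred <- ct$tp + ct$fp
  rate <- function(num, den, what)
    if (den > 0) num / den else undefined_metric(sprintf("empty %s", what))
  list(
    accuracy    = (ct$tp + ct$tn) / total,
    sensitivity = rate(ct$tp, pos, "positive class"),
    specificity = rate(ct$tn, neg, "negative class"),
    oer         = (ct$fp + ct$fn) / total,
    fpr         = rate(ct$fp, neg, "negative class"),
    fnr         = rate(ct$fn, pos, "positive class"),
    precision   = rate(ct$tp, ppred, "predicted-positive set")
  )
}

#' F-measure and g-means
#'
#' The F-measure is the harmonic mean of precision and sensitivity; gmean-1
#' is the geometric mean of sensitivity and precision and gmean-2 the
#' geometric mean of sensitivity and specificity, the two balanced-
#' performance summaries used alongside the F-measure.
#'
#' @param ct A [confusion_table()].
#' @return List with `f_measure`, `gmean1`, `gmean2`.
#' @export
f_and_gmeans <- function(ct) {
  r <- basic_rates(ct)
  undef <- Filter(is_undefined_metric,
                  r[c("precision", "sensitivity", "specificity")])
  if (length(undef) > 0) {
    u <- undefined_metric(attr(undef[[1]], "reason"))
    return(list(f_measure = u, gmean1 = u, gmean2 = u))
  }
  p <- r$precision; se <- r$sensitivity; sp <- r$specificity
  f <- if (p + se > 0) 2 * p * se / (p + se)
       else undefined_metric("precision + sensitivity = 0")
  list(f_measure = f, gmean1 = sqrt(se * p), gmean2 = sqrt(se * sp))
}

#' Matthews correlation coefficient
#'
#' Correlation between predicted and true binary labels,
#' \deqn{MCC = \frac{TP\,TN - FP\,FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' +1 is perfect prediction, 0 chance-level, -1 total disagreement.
#'
#' @param ct A [confusion_table()].
#' @return Value in `[-1, 1]`, or an undefined-metric signal when a marginal
#'   is zero.
#' @export
mcc <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  m <- c(ct$tp + ct$fp, ct$tp + ct$fn, ct$tn + ct$fp, ct$tn + ct$fn)
  if (any(m == 0)) return(undefined_metric("zero marginal"))
  (ct$tp * ct$tn - ct$fp * ct$fn) / sqrt(prod(m))
}

#' Area under the ROC curve (closed form)
#'
#' The single-threshold closed form
#' \deqn{AUC = \tfrac12\left(\frac{TP}{TP+FN} + \frac{TN}{TN+FP}\right),}
#' i.e. the mean of sensitivity and specificity; identical to balanced
#' accuracy expressed as a proportion.
#'
#' @param ct A [confusion_table()].
#' @return Value in `[0, 1]`.
#' @export
auc_formula <- function(ct) {
  r <- basic_rates(ct)
  if (is_undefined_metric(r$sensitivity) || is_undefined_metric(r$specificity))
    return(undefined_metric("empty class"))
  (r$sensitivity + r$specificity) / 2
}

#' Balanced accuracy
#'
#' `BACC = (TPR + TNR) / 2`, reported as a percentage. Satisfies
#' `bacc(ct) == 100 * auc_formula(ct)` identically.
#'
#' @param ct A [confusion_table()].
#' @return Percentage in `[0, 100]`.
#' @export
bacc <- function(ct) {
  a <- auc_formula(ct)
  if (is_undefined_metric(a)) return(a)
  100 * a
}

#' Cohen's kappa with large-sample standard error
#'
#' Chance-corrected agreement \eqn{\kappa = (p_0 - p_e)/(1 - p_e)} from a
#' square confusion matrix (rows: truth, columns: prediction), where
#' \eqn{p_0} is the observed accuracy and \eqn{p_e = \sum_i n_{i+} n_{+i} /
#' N^2} the expected chance agreement from the marginals. The standard error
#' uses the standard large-sample form
#' \eqn{\varphi(\kappa) = \sqrt{p_0 (1 - p_0)} / ((1 - p_e)\sqrt{N})}; the
#' 95% confidence interval is \eqn{\kappa \pm 1.96\,\varphi(\kappa)} and the
#' agreement is flagged above chance when its lower bound exceeds zero.
#'
#' @param m Square numeric matrix of counts (C classes).
#' @return List with `kappa`, `se`, `ci` (length-2), `above_chance`, `p0`,
#'   `pe`, `n`.
#' @export
kappa_with_se <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0) || any(!is.finite(m))) stop("counts must be finite and >= 0")
  n <- sum(m)
  if (n < 1) stop("confusion matrix must contain at least one count")
  p0 <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe >= 1) return(list(kappa = undefined_metric("pe = 1"), se = NA_real_,
                           ci = c(NA_real_, NA_real_), above_chance = NA,
                           p0 = p0, pe = pe, n = n))
  k <- (p0 - pe) / (1 - pe)
  se <- sqrt(p0 * (1 - p0) / n) / (1 - pe)
  ci <- k + c(-1, 1) * 1.96 * se
  list(kappa = k, se = se, ci = ci, above_chance = ci[1] > 0,
       p0 = p0, pe = pe, n = n)
}

#' Unified desirability of a classifier across subjects
#'
#' Composite mean/spread statistic over six per-subject performance vectors:
#' `D1` is the product of mean/sd ratios of precision, sensitivity and
#' specificity; `D2` the product over gmean-1, gmean-2 and F-measure;
#' `D = (D1 * D2)^(1/6)`, the geometric mean of the six ratios. Larger
#' values reward simultaneously high and stable performance.
#'
#' @param precision,sensitivity,specificity,gmean1,gmean2,f_measure Numeric
#'   vectors (one entry per subject or per fold), each of length >= 2.
#' @return List with `d1`, `d2`, `d`.
#' @export
desirability <- function(precision, sensitivity, specificity,
                         gmean1, gmean2, f_measure) {
  vs <- list(precision = precision, sensitivity = sensitivity,
             specificity = specificity, gmean1 = gmean1, gmean2 = gmean2,
             f_measure = f_measure)
  for (nm in names(vs)) {
    v <- vs[[nm]]
    if (length(v) < 2) stop(sprintf("`%s` needs length >= 2", nm))
    if (stats::sd(v) == 0)
      return(list(d1 = undefined_metric(sprintf("zero spread in %s", nm)),
                  d2 = undefined_metric(sprintf("zero spread in %s", nm)),
                  d  = undefined_metric(sprintf("zero spread in %s", nm))))
  }
  ratio <- function(v) mean(v) / stats::sd(v)
  d1 <- ratio(precision) * ratio(sensitivity) * ratio(specificity)
  d2 <- ratio(gmean1) * ratio(gmean2) * ratio(f_measure)
  list(d1 = d1, d2 = d2, d = (d1 * d2)^(1 / 6))
}

#' Full metrics report for one binary evaluation
#'
#' Bundles every statistic computed from a single confusion table: the basic
#' rates, F-measure and g-means, MCC, AUC (closed form), balanced accuracy,
#' and Cohen's kappa with standard error and 95% CI (from the implied 2x2
#' agreement matrix).
#'
#' @param ct A [confusion_table()].
#' @return Object of class `metrics_report` (a named list).
#' @export
metrics_report <- function(ct) {
  r <- basic_rates(ct)
  fg <- f_and_gmeans(ct)
  m2 <- matrix(c(ct$tp, ct$fn, ct$fp, ct$tn), 2, 2, byrow = TRUE)
  kp <- kappa_with_se(m2)
  structure(c(r, fg,
              list(mcc = mcc(ct), auc = auc_formula(ct), bacc = bacc(ct),
                   kappa = kp$kappa, kappa_se = kp$se, kappa_ci95 = kp$ci,
                   kappa_above_chance = kp$above_chance,
                   confusion = ct)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  fmt <- function(v) {
    if (is_undefined_metric(v)) paste0("NA (", attr(v, "reason"), ")")
    else format(round(unclass(v), digits))
  }
  cat("Binary classification metrics\n")
  for (nm in c("accuracy", "sensitivity", "specificity", "oer", "fpr", "fnr",
               "precision", "f_measure", "gmean1", "gmean2", "mcc", "auc",
               "bacc", "kappa", "kappa_se"))
    cat(sprintf("  %-12s %s\n", nm, fmt(x[[nm]])))
  cat(sprintf("  kappa 95%% CI [%.4f, %.4f]%s\n", x$kappa_ci95[1],
              x$kappa_ci95[2],
              if (isTRUE(x$kappa_above_chance)) " (above chance)" else ""))
  invisible(x)
}
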
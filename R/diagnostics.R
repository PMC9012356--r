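#' Empirical ROC curve and AUC
#'
#' Builds the empirical ROC over all distinct thresholds (midpoints between
#' consecutive distinct scores, plus sentinels) and computes the AUC as the
#' tie-corrected pairwise probability (Mann-Whitney statistic divided by
#' `n1 * n0`), which equals the trapezoidal area under the empirical curve.
#' The DeLong structural components and standard error are computed alongside.
#'
#' @param scores numeric marker values, one per subject.
#' @param labels logical/0-1; `TRUE` = diseased (positive class).
#' @param direction `"lower"` (default; lower score indicates disease, the
#'   convention for the MCP ratio and volume) or `"higher"`.
#' @return object of class `roc_result`: `thresholds` (score scale), `tpr`,
#'   `fpr`, `auc`, `auc_se`, `ci_95`, `direction`, counts, and the DeLong
#'   components `v10`, `v01`.
#' @export
roc_auc <- function(scores, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  x <- if (direction == "lower") -scores else scores
  # curve over thresholds t: predict diseased when x >= t
  ux <- sort(unique(x))
  cuts <- c(Inf, rev(if (length(ux) > 1)
    (ux[-1] + ux[-length(ux)]) / 2 else numeric(0)), -Inf)
  tpr <- vapply(cuts, function(t) mean(x[labels] >= t), 0)
  fpr <- vapply(cuts, function(t) mean(x[!labels] >= t), 0)
  r <- rank(x)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cmp <- delong_components(x[labels], x[!labels])
  se <- sqrt(stats::var(cmp$v10) / n1 + stats::var(cmp$v01) / n0)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  thresholds <- if (direction == "lower") -cuts else cuts
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                 auc = auc, auc_se = se, ci_95 = ci,
                 direction = direction, n_pos = n1, n_neg = n0,
                 v10 = cmp$v10, v01 = cmp$v01),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), %d diseased / %d not, %s = diseased\n",
              x$auc, x$ci_95[1], x$ci_95[2], x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

# Placement values: v10[i] = P-hat(X_i beats a random control), v01[j] likewise
delong_components <- function(xpos, xneg) {
  psi <- outer(xpos, xneg, function(a, b)
    (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' DeLong confidence interval for one AUC
#' @param scores,labels,direction as in [roc_auc()].
#' @param level confidence level (default 0.95).
#' @return list with `auc`, `se`, `ci` (truncated to `[0, 1]`).
#' @export
auc_ci <- function(scores, labels, direction = c("lower", "higher"),
                   level = 0.95) {
  r <- roc_auc(scores, labels, direction)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = r$auc, se = r$auc_se,
       ci = pmin(pmax(r$auc + c(-1, 1) * z * r$auc_se, 0), 1))
}

#' DeLong test comparing two correlated AUCs
#'
#' Paired comparison of two markers measured on the same subjects, using the
#' structural-components variance/covariance estimator and a two-sided normal
#' reference. Identical score vectors give `z = 0, p = 1` by construction.
#'
#' @param scores_a,scores_b the two markers (same subjects, same order).
#' @param labels logical/0-1 disease indicators.
#' @param direction per [roc_auc()]; applied to both markers.
#' @return list with `auc_a`, `auc_b`, `var_a`, `var_b`, `cov_ab`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("paired scores require equal lengths")
  ra <- roc_auc(scores_a, labels, direction)
  rb <- roc_auc(scores_b, labels, direction)
  n1 <- ra$n_pos; n0 <- ra$n_neg
  var_a <- stats::var(ra$v10) / n1 + stats::var(ra$v01) / n0
  var_b <- stats::var(rb$v10) / n1 + stats::var(rb$v01) / n0
  cov_ab <- stats::cov(ra$v10, rb$v10) / n1 + stats::cov(ra$v01, rb$v01) / n0
  vd <- var_a + var_b - 2 * cov_ab
  diff <- ra$auc - rb$auc
  if (vd < 1e-14) {
    if (abs(diff) < 1e-12) {
      z <- 0; p <- 1
    } else {
      stop(sprintf(
        "degenerate variance of the AUC difference (%.3g) with nonzero difference %.3g",
        vd, diff))
    }
  } else {
    z <- diff / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ra$auc, auc_b = rb$auc, var_a = var_a, var_b = var_b,
       cov_ab = cov_ab, z = z, p = p)
}

#' Closest-to-corner operating point of a ROC curve
#'
#' Returns the threshold minimising the Euclidean distance
#' `sqrt((1 - TPR)^2 + FPR^2)` to the upper-left corner. Ties are broken
#' toward higher specificity (lower FPR), then toward the lower threshold on
#' the score scale.
#'
#' @param roc a [roc_auc()] result.
#' @return list with `threshold` (score scale), `tpr`, `fpr`, `sensitivity`,
#'   `specificity`, `distance`.
#' @export
optimal_cutoff <- function(roc) {
  if (!inherits(roc, "roc_result")) stop("`roc` must be a roc_result")
  d <- sqrt((1 - roc$tpr)^2 + roc$fpr^2)
  eps <- 1e-12
  best <- which(d <= min(d) + eps)
  if (length(best) > 1) best <- best[roc$fpr[best] <= min(roc$fpr[best]) + eps]
  if (length(best) > 1) {
    thr <- roc$thresholds[best]
    fin <- thr[is.finite(thr)]
    best <- if (length(fin)) best[which(thr == min(fin))[1]] else best[1]
  }
  i <- best[1]
  list(threshold = roc$thresholds[i], tpr = roc$tpr[i], fpr = roc$fpr[i],
       sensitivity = roc$tpr[i], specificity = 1 - roc$fpr[i],
       distance = d[i])
}

#' Exact (Clopper-Pearson) confidence interval for a proportion
#'
#' Beta-quantile form of the exact tail-inversion interval; the lower bound
#' is 0 at `x = 0` and the upper bound 1 at `x = n`.
#'
#' @param x successes, `0 <= x <= n`.
#' @param n trials, `n >= 1`.
#' @param alpha two-sided error rate (default 0.05).
#' @return numeric `c(lo, hi)` on the proportion scale.
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  if (n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("need integer counts with 0 <= x <= n, n >= 1")
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}

#' Confusion-table diagnostic metrics with exact CIs
#'
#' Sensitivity, specificity, positive and negative predictive value, and
#' overall accuracy, each in percent with a Clopper-Pearson `1 - alpha`
#' interval. A metric whose denominator is zero is reported as undefined
#' (`NA`), never as 0.
#'
#' @param tp,fn,fp,tn nonnegative integer counts.
#' @param alpha two-sided error rate for the intervals (default 0.05).
#' @return object of class `diagnostic_summary`: a `data.frame` with columns
#'   `metric`, `x`, `n`, `value` (percent), `lo`, `hi` (percent bounds).
#' @export
confusion_metrics <- function(tp, fn, fp, tn, alpha = 0.05) {
  cnt <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be nonnegative integers")
  cell <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    ci <- clopper_pearson(x, n, alpha)
    c(x / n, ci) * 100
  }
  rows <- rbind(
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    ppv = c(tp, tp + fp),
    npv = c(tn, tn + fn),
    accuracy = c(tp + tn, tp + fn + fp + tn))
  out <- t(apply(rows, 1, function(r) cell(r[1], r[2])))
  res <- data.frame(metric = rownames(rows), x = rows[, 1], n = rows[, 2],
                    value = out[, 1], lo = out[, 2], hi = out[, 3],
                    row.names = NULL)
  class(res) <- c("diagnostic_summary", "data.frame")
  res
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    if (is.na(x$value[i])) {
      cat(sprintf("%-12s undefined (denominator 0)\n", x$metric[i]))
    } else {
      cat(sprintf("%-12s %5.1f%% (%.1f-%.1f)  [%d/%d]\n", x$metric[i],
                  x$value[i], x$lo[i], x$hi[i], x$x[i], x$n[i]))
    }
  }
  invisible(x)
}

#' Exact binomial test of an observed accuracy against a reference
#'
#' One-sided lower-tail by default (is the reviewer's accuracy worse than the
#' reference marker's accuracy `p0`?); the two-sided variant uses the
#' minimum-likelihood method.
#'
#' @param correct number of correct classifications.
#' @param n number of cases.
#' @param p0 reference accuracy in (0, 1).
#' @param sided `"less"` (default) or `"two.sided"`.
#' @return the p-value.
#' @export
binomial_accuracy_test <- function(correct, n, p0,
                                   sided = c("less", "two.sided")) {
  sided <- match.arg(sided)
  if (correct < 0 || correct > n || correct != round(correct) || n < 1)
    stop("need integer 0 <= correct <= n")
  if (p0 <= 0 || p0 >= 1) stop("`p0` must lie in (0, 1)")
  stats::binom.test(correct, n, p = p0, alternative = sided)$p.value
}

#' Intraclass correlation coefficient for inter-rater agreement
#'
#' ANOVA mean-squares estimator on a complete subjects x raters matrix.
#' Default is the two-way random-effects, absolute-agreement, single-measure
#' form ICC(2,1); `variant = "consistency"` gives the two-way mixed
#' consistency form ICC(3,1).
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns, no
#'   missing cells.
#' @param variant `"agreement"` (default) or `"consistency"`.
#' @return object of class `icc_result`: `icc`, `variant`, `n_subjects`,
#'   `n_raters`, and the mean squares `msr`, `msc`, `mse`.
#' @export
icc <- function(ratings, variant = c("agreement", "consistency")) {
  variant <- match.arg(variant)
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("ratings matrix must be complete")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < .Machine$double.eps && variant == "agreement" &&
      msc < .Machine$double.eps && mse < .Machine$double.eps)
    stop("zero variance everywhere: ICC undefined")
  est <- switch(variant,
    agreement = {
      den <- msr + (k - 1) * mse + k * (msc - mse) / n
      if (den < .Machine$double.eps) NA_real_
      else (msr - mse) / den
    },
    consistency = {
      den <- msr + (k - 1) * mse
      if (den < .Machine$double.eps) NA_real_ else (msr - mse) / den
    })
  if (is.na(est))
    warning("zero between-subject variance: ICC undefined")
  structure(list(icc = est, variant = variant, n_subjects = n, n_raters = k,
                 msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.3f (%s, single measure), %d subjects x %d raters\n",
              x$icc, x$variant, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Grubbs (maximum studentized deviate) outlier test
#'
#' Single-outlier test: `G = max |x - mean| / sd`, compared with the t-based
#' critical value
#' `(n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` at
#' `t = qt(1 - alpha / (2 n), n - 2)`. With `iterative = TRUE` the test is
#' reapplied to the reduced series after each flagged point until no outlier
#' remains.
#'
#' @param values numeric vector, `n >= 3`, nonconstant.
#' @param alpha significance level (default 0.05).
#' @param iterative remove-and-retest mode (default `FALSE`).
#' @return object of class `outlier_report`: `g`, `critical`, `flagged`
#'   (index into `values`, or `NA`), `alpha`, and in iterative mode
#'   `all_flagged` (possibly empty integer vector).
#' @export
grubbs <- function(values, alpha = 0.05, iterative = FALSE) {
  x <- as.numeric(values)
  if (length(x) < 3) stop("Grubbs test needs n >= 3")
  if (stats::sd(x) == 0) stop("constant series: Grubbs test undefined")
  one_pass <- function(x) {
    n <- length(x)
    g <- max(abs(x - mean(x))) / stats::sd(x)
    t2 <- stats::qt(1 - alpha / (2 * n), n - 2)^2
    crit <- (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
    list(g = g, critical = crit,
         idx = if (g > crit) which.max(abs(x - mean(x))) else NA_integer_)
  }
  first <- one_pass(x)
  all_flagged <- integer(0)
  if (iterative) {
    active <- seq_along(x)
    repeat {
      if (length(active) < 3 || stats::sd(x[active]) == 0) break
      p <- one_pass(x[active])
      if (is.na(p$idx)) break
      all_flagged <- c(all_flagged, active[p$idx])
      active <- active[-p$idx]
    }
  } else if (!is.na(first$idx)) {
    all_flagged <- first$idx
  }
  structure(list(g = first$g, critical = first$critical,
                 flagged = if (length(all_flagged)) all_flagged[1]
                           else NA_integer_,
                 all_flagged = all_flagged, alpha = alpha,
                 n = length(x)),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> G = %.4f, critical(%.3g) = %.4f, %s\n",
              x$g, x$alpha, x$critical,
              if (is.na(x$flagged)) "no outlier"
              else sprintf("flagged index %d", x$flagged)))
  invisible(x)
}
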
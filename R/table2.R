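#' Published visual-rating performance table
#'
#' The reviewer-by-comparison diagnostic metrics (percent) for the three
#' visual signs — MCP hyperintensity, grade-2 hot-cross-bun (HCB), and
#' grade-1-or-2 HCB — for the three pairwise group comparisons, as packaged
#' in `extdata/table2_metrics.csv`. Cells whose defining fraction is 0/0
#' (e.g. PPV when neither true nor false positives occur) are stored as `NA`.
#'
#' @return `data.frame` with columns `sign`, `comparison`, `reviewer`,
#'   `n_pos`, `n_neg`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`.
#' @export
table2_printed <- function() {
  path <- system.file("extdata", "table2_metrics.csv", package = "mcpratio")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reconstruct a confusion table from printed sensitivity/specificity
#'
#' With the group sizes known, the printed (percent, one-decimal) sensitivity
#' and specificity determine the underlying integer counts uniquely:
#' `tp = round(sens/100 * n_pos)`, `tn = round(spec/100 * n_neg)`.
#'
#' @param sensitivity,specificity percents as printed.
#' @param n_pos,n_neg group sizes (positives = the diseased group).
#' @return named integer vector `c(tp, fn, fp, tn)`.
#' @export
reconstruct_confusion <- function(sensitivity, specificity, n_pos, n_neg) {
  tp <- round(sensitivity / 100 * n_pos)
  tn <- round(specificity / 100 * n_neg)
  c(tp = as.integer(tp), fn = as.integer(n_pos - tp),
    fp = as.integer(n_neg - tn), tn = as.integer(tn))
}

#' Recompute every printed performance cell from reconstructed counts
#'
#' For each reviewer/sign/comparison row the confusion table is rebuilt from
#' group sizes plus printed sensitivity and specificity, all five metrics are
#' recomputed with [confusion_metrics()], and the recomputed values (rounded
#' to one decimal, the table's precision) are set against the printed ones.
#' Undefined (0/0) cells are excluded from the match flag.
#'
#' @return `data.frame`: the printed table plus `<metric>_calc` columns and a
#'   logical `match` column.
#' @export
reproduce_table2 <- function() {
  tab <- table2_printed()
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  calc <- matrix(NA_real_, nrow(tab), length(metrics),
                 dimnames = list(NULL, paste0(metrics, "_calc")))
  for (i in seq_len(nrow(tab))) {
    cc <- reconstruct_confusion(tab$sensitivity[i], tab$specificity[i],
                                tab$n_pos[i], tab$n_neg[i])
    cm <- confusion_metrics(cc["tp"], cc["fn"], cc["fp"], cc["tn"])
    calc[i, ] <- round(cm$value[match(metrics, cm$metric)], 1)
  }
  out <- cbind(tab, as.data.frame(calc))
  printed <- as.matrix(tab[metrics])
  out$match <- apply(abs(printed - calc) < 0.05 |
                       (is.na(printed) & is.na(calc)), 1, all)
  out
}

#' Reference accuracies of the quantitative marker per comparison
#'
#' The MCP sT1w/T2w ratio's published classification accuracy (percent) and
#' the number of cases for each pairwise comparison; the reference value
#' `p0` for the binomial accuracy comparisons.
#'
#' @return `data.frame` with `comparison`, `accuracy`, `n`.
#' @export
ratio_reference_accuracy <- function() {
  data.frame(comparison = c("MSAvsSCA3", "MSAvsSCA6", "SCA3vsSCA6"),
             accuracy = c(90.0, 91.7, 66.7),
             n = c(40L, 48L, 24L),
             stringsAsFactors = FALSE)
}

#' Compare reviewer accuracies against the quantitative marker
#'
#' Rebuilds each reviewer's correct-classification count from the printed
#' table and tests it against the ratio marker's accuracy with the one-sided
#' lower-tail exact binomial test.
#'
#' @param sided passed to [binomial_accuracy_test()].
#' @return `data.frame` with `sign`, `comparison`, `reviewer`, `correct`,
#'   `n`, `p0`, `p`.
#' @export
compare_accuracies_table3 <- function(sided = "less") {
  tab <- table2_printed()
  ref <- ratio_reference_accuracy()
  tab <- merge(tab, ref, by = "comparison", suffixes = c("", "_ref"))
  n <- tab$n_pos + tab$n_neg
  correct <- round(tab$accuracy / 100 * n)
  p <- mapply(function(x, nn, p0) binomial_accuracy_test(x, nn, p0, sided),
              correct, n, tab$accuracy_ref / 100)
  res <- data.frame(sign = tab$sign, comparison = tab$comparison,
                    reviewer = tab$reviewer, correct = correct, n = n,
                    p0 = tab$accuracy_ref / 100, p = p)
  res[order(res$sign, res$comparison, res$reviewer), ]
}
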
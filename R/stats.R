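#' Finite-sample chance level for classification accuracy
#'
#' The accuracy threshold that a random classifier exceeds with probability
#' at most `conf_alpha` given a finite test set: `k/n` for the smallest k
#' with `P(Binomial(n, 1/n_classes) <= k - 1) >= 1 - conf_alpha`. Decreases
#' toward `1/n_classes` as n grows, and always strictly exceeds it.
#'
#' @param n_test Number of test samples.
#' @param n_classes Number of classes (default 2).
#' @param conf_alpha Confidence level (default 0.05).
#' @return Accuracy threshold in (1/n_classes, 1].
#' @export
finite_chance_level <- function(n_test, n_classes = 2, conf_alpha = 0.05) {
  stopifnot(n_test >= 1, n_classes >= 2, conf_alpha > 0, conf_alpha < 1)
  (qbinom(1 - conf_alpha, n_test, 1 / n_classes) + 1) / n_test
}

#' One-sample t-tests for accuracy and mean-difference families
#'
#' `ttest_accuracy` tests a set of fold accuracies against the finite chance
#' threshold; `ttest_meandiff` tests class-mean differences against zero.
#' Both are two-sided Student t-tests. Zero-variance input returns `NA` with
#' attribute `degenerate = TRUE` rather than failing.
#'
#' @param accuracies,diffs Numeric vectors (>= 2 values).
#' @param chance Null value for the accuracy test.
#' @return Two-sided p-value.
#' @export
ttest_accuracy <- function(accuracies, chance) {
  if (length(accuracies) < 2L) stop_input("need >= 2 accuracy values")
  if (sd(accuracies) == 0) {
    if (accuracies[1] == chance) return(1)
    return(structure(NA_real_, degenerate = TRUE))
  }
  t.test(accuracies, mu = chance)$p.value
}

#' @rdname ttest_accuracy
#' @export
ttest_meandiff <- function(diffs) {
  if (length(diffs) < 2L) stop_input("need >= 2 mean-difference values")
  if (sd(diffs) == 0) {
    if (diffs[1] == 0) return(1)
    return(structure(NA_real_, degenerate = TRUE))
  }
  t.test(diffs, mu = 0)$p.value
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Sorts the p-values ascending, finds the largest i with
#' `P(i) <= (i/N) * alpha`, and rejects every hypothesis with p <= P(i).
#' Invariant to input order; `NA` p-values are never rejected and do not
#' count toward N.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param alpha FDR level (default 0.01).
#' @return Logical rejection flag per input hypothesis.
#' @export
bh_fdr <- function(pvals, alpha = 0.01) {
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  ok <- !is.na(pvals)
  N <- sum(ok)
  rej <- rep(FALSE, length(pvals))
  if (N == 0) return(rej)
  ps <- sort(pvals[ok])
  pass <- which(ps <= (seq_len(N) / N) * alpha)
  if (!length(pass)) return(rej)
  pk <- ps[max(pass)]
  rej[ok] <- pvals[ok] <= pk
  rej
}

#' Joint significance of decodability and consistency
#'
#' Applies BH-FDR separately to the accuracy p-value family and the
#' mean-difference p-value family (each family spans all ROI x band
#' combinations), then labels a feature jointly significant when both
#' survive. "Significantly above chance" additionally requires the mean
#' accuracy to exceed the chance threshold, so features sitting *below*
#' chance are never flagged.
#'
#' @param results data.frame with one row per (ROI, band) and columns
#'   `p_acc`, `p_diff`, `mean_acc`.
#' @param chance Finite chance threshold used by the accuracy tests.
#' @param alpha FDR level (default 0.01).
#' @return `results` with logical columns `sig_acc`, `sig_diff`,
#'   `sig_joint` appended.
#' @export
joint_significance <- function(results, chance, alpha = 0.01) {
  stopifnot(all(c("p_acc", "p_diff", "mean_acc") %in% names(results)))
  results$sig_acc <- bh_fdr(results$p_acc, alpha) & results$mean_acc > chance
  results$sig_diff <- bh_fdr(results$p_diff, alpha)
  results$sig_joint <- results$sig_acc & results$sig_diff
  results
}

#' Two-way ANOVA of ROI and band effects on accuracy
#'
#' Fixed-effects two-way ANOVA with interaction on fold-level accuracies
#' pooled across participants.
#'
#' @param acc_table data.frame with columns `roi`, `band`, `accuracy`.
#' @return An `anova_result` list with F statistics, p-values and degrees of
#'   freedom for the ROI effect, the band effect, and their interaction.
#' @export
anova_roi_band <- function(acc_table) {
  stopifnot(all(c("roi", "band", "accuracy") %in% names(acc_table)))
  acc_table$roi <- factor(acc_table$roi)
  acc_table$band <- factor(acc_table$band)
  if (nlevels(acc_table$roi) < 2L || nlevels(acc_table$band) < 2L) {
    stop_input("need >= 2 levels per factor")
  }
  cells <- table(acc_table$roi, acc_table$band)
  if (any(cells < 2L)) {
    bad <- which(cells < 2L, arr.ind = TRUE)[1, ]
    stop_input("cell with < 2 replicates: ",
               rownames(cells)[bad[1]], " x ", colnames(cells)[bad[2]])
  }
  fit <- aov(accuracy ~ roi * band, data = acc_table)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  pick <- function(name, col) {
    v <- tab[match(name, rn), col]
    # a numerically zero effect sum-of-squares means no effect: F = 0, p = 1
    if (tab[match(name, rn), "Sum Sq"] < 1e-12) {
      if (col == "F value") v <- 0
      if (col == "Pr(>F)") v <- 1
    }
    v
  }
  structure(list(
    f_roi = pick("roi", "F value"), p_roi = pick("roi", "Pr(>F)"),
    f_band = pick("band", "F value"), p_band = pick("band", "Pr(>F)"),
    f_interaction = pick("roi:band", "F value"),
    p_interaction = pick("roi:band", "Pr(>F)"),
    df = c(roi = pick("roi", "Df"), band = pick("band", "Df"),
           interaction = pick("roi:band", "Df"),
           residual = pick("Residuals", "Df"))
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Two-way ANOVA on fold accuracies\n  ROI:         F(%d) = %.3f, p = %.3g\n  Band:        F(%d) = %.3f, p = %.3g\n  Interaction: F(%d) = %.3f, p = %.3g\n",
              x$df["roi"], x$f_roi, x$p_roi,
              x$df["band"], x$f_band, x$p_band,
              x$df["interaction"], x$f_interaction, x$p_interaction))
  invisible(x)
}
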
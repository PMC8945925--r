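#' A 2x2 classification table
#'
#' Convention: the test is metabolic response (MR vs nMR), the condition is
#' the 3-month outcome (non-progression positive). `tp` counts MR & nPD,
#' `fn` nMR & nPD, `fp` MR & PD, `tn` nMR & PD.
#'
#' @param tp,fn,fp,tn non-negative integer counts, total `> 0`.
#' @return A `two_by_two` list.
#' @export
two_by_two <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("table total must be positive")
  structure(as.list(cells), class = "two_by_two")
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)`, accuracy `(tp+tn)/total`, each as a percentage. A
#' metric with a zero denominator is reported as `NA` (undefined), never 0.
#'
#' @param t a [two_by_two()].
#' @return Named list of percentages: `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`.
#' @export
#' @examples
#' confusion_metrics(two_by_two(20, 4, 1, 5))
confusion_metrics <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  frac <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  with(t, list(
    sensitivity = frac(tp, tp + fn),
    specificity = frac(tn, tn + fp),
    ppv = frac(tp, tp + fp),
    npv = frac(tn, tn + fn),
    accuracy = frac(tp + tn, tp + fn + fp + tn)))
}

#' Crude odds ratio with Woolf confidence interval
#'
#' `OR = (tp*tn)/(fn*fp)`; the 95% CI is
#' `exp(log(OR) +/- 1.96 * sqrt(1/tp + 1/fn + 1/fp + 1/tn))`. With a zero
#' cell the crude OR is undefined; set `haldane = TRUE` to add 0.5 to every
#' cell first.
#'
#' @param t a [two_by_two()].
#' @param haldane apply the Haldane-Anscombe 0.5 correction.
#' @param conf_level confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio <- function(t, haldane = FALSE, conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$tp, t$fn, t$fp, t$tn)
  if (any(cells == 0)) {
    if (!haldane) stop("zero cell: crude odds ratio undefined (set haldane = TRUE)")
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se))
}

#' Disease control rate
#'
#' Percentage of non-progressive patients.
#'
#' @param labels character vector of `"nPD"` / `"PD"` labels.
#' @return Percent.
#' @export
disease_control_rate <- function(labels) {
  if (!length(labels)) stop("no labels")
  bad <- setdiff(unique(labels), c("nPD", "PD"))
  if (length(bad)) stop("labels must be nPD/PD")
  100 * mean(labels == "nPD")
}

#' Mann-Whitney U test
#'
#' Two-sided comparison of two continuous samples. Exact enumeration when
#' both groups have at most 10 observations (and no ties); otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b numeric vectors (each non-empty).
#' @return List with `U` (statistic for `a` vs `b`) and `p`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  exact <- length(a) <= 10 && length(b) <= 10
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Chi-square test of a 2x2 table, with exact fallback
#'
#' Pearson chi-square (without continuity correction); when any expected
#' cell count falls below 5 the Fisher exact test is used instead, and the
#' returned `method` says which path was taken.
#'
#' @param t a [two_by_two()].
#' @return List with `statistic` (`NA` on the Fisher path), `p`, `method`,
#'   `min_expected`.
#' @export
chi_square <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  m <- matrix(c(t$tp, t$fn, t$fp, t$tn), nrow = 2)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(m)
    list(statistic = NA_real_, p = ft$p.value, method = "fisher",
         min_expected = min(expected))
  } else {
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(statistic = unname(ct$statistic), p = ct$p.value,
         method = "chi-square", min_expected = min(expected))
  }
}

#' Spearman rank correlation
#'
#' @param x,y numeric vectors of equal length.
#' @return List with `rho` and `p` (two-sided).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
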
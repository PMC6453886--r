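# Shared statistical primitives. These are deliberately thin, contract-
# checked front-ends over the stats package, so that every downstream stage
# (screen, lipidomics, selectivity, dose-response) applies identical rules.

#' Two-sample Student's t-test
#'
#' Equal-variance two-sample t-test (pooled variance, `n1 + n2 - 2` degrees
#' of freedom), the test used for lipid differential abundance and curve-
#' shift comparisons. A Welch version is available behind `welch = TRUE`.
#'
#' Degenerate input (zero pooled variance) is handled explicitly: equal
#' means give statistic 0 and p 1; unequal means give an infinite statistic
#' and p 0.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @param twoSided if `TRUE` (default) the p-value is two-tailed.
#' @param welch use the unequal-variance (Welch) form.
#' @return list with `statistic`, `p.value`, `method`, `n1`, `n2`.
#' @examples
#' studentTTest(c(1, 2, 3), c(2, 3, 4))
#' @export
studentTTest <- function(groupA, groupB, twoSided = TRUE, welch = FALSE) {
  groupA <- as.numeric(groupA); groupB <- as.numeric(groupB)
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 values")
  method <- if (welch) "Welch t-test" else "Student t-test"
  n1 <- length(groupA); n2 <- length(groupB)
  if (var(groupA) == 0 && var(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(statistic = 0, p.value = 1, method = method,
                  n1 = n1, n2 = n2))
    return(list(statistic = sign(mean(groupA) - mean(groupB)) * Inf,
                p.value = 0, method = method, n1 = n1, n2 = n2))
  }
  ht <- t.test(groupA, groupB, var.equal = !welch,
               alternative = if (twoSided) "two.sided" else "greater")
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       method = method, n1 = n1, n2 = n2)
}

#' Mann-Whitney-Wilcoxon U test
#'
#' Rank-sum test used for the lineage-selectivity comparisons. The U
#' statistic reported is for `groupA`. The p-value is exact (full null
#' enumeration) when `n1 + n2 <= 12` and the data are tie-free; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. Two-sided p-values are doubled and capped at 1.
#'
#' @param groupA,groupB non-empty numeric vectors.
#' @param twoSided two-tailed p-value (default `TRUE`).
#' @return list with `statistic` (U for `groupA`), `p.value`, `method`
#'   (`"exact"` or `"normal approximation"`), `n1`, `n2`.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4, 5))  # U = 0, exact p = 0.2
#' @export
mannWhitneyU <- function(groupA, groupB, twoSided = TRUE) {
  groupA <- as.numeric(groupA); groupB <- as.numeric(groupB)
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  n1 <- length(groupA); n2 <- length(groupB)
  ties <- anyDuplicated(c(groupA, groupB)) > 0
  exact <- (n1 + n2 <= 12) && !ties
  ht <- suppressWarnings(wilcox.test(
    groupA, groupB, exact = exact, correct = TRUE,
    alternative = if (twoSided) "two.sided" else "greater"))
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       method = if (exact) "exact" else "normal approximation",
       n1 = n1, n2 = n2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: the i-th smallest p becomes
#' `min over j >= i of (m/j) * p_(j)`, capped at 1, returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return adjusted p-values, same order and length as `p`.
#' @examples
#' bhAdjust(c(0.02, 0.03))  # both 0.03
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Robust z-scores (median/MAD)
#'
#' `z_i = (x_i - median(x)) / (1.4826 * MAD(x))`, the empirical-null scaling
#' used for per-sgRNA screen enrichment p-values. The 1.4826 factor makes the
#' MAD a consistent estimator of the standard deviation under normality.
#'
#' @param x numeric vector of length >= 3.
#' @return robust z-scores, same length as `x`.
#' @export
robustZ <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("need at least 3 values")
  s <- mad(x)  # stats::mad already includes the 1.4826 consistency constant
  if (s == 0)
    stop("MAD is zero; fall back to a standard-deviation z-score")
  (x - median(x)) / s
}
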
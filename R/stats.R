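# Cohort statistics with the test-selection rule used throughout the
# analysis: variables are inspected for normality (Shapiro-Wilk at alpha
# 0.05 per group); normally distributed unpaired data get a two-tailed
# unpaired Student's t-test, otherwise a Mann-Whitney U test; paired
# normally distributed data get a two-tailed paired Student's t-test
# (paired non-normal differences fall back to the Wilcoxon signed-rank
# test). Bonferroni correction is applied across a caller-defined family.

#' Compare two groups with automatic test selection
#'
#' @param x,y numeric samples (for `paired = TRUE`, paired by position).
#' @param paired paired comparison.
#' @param bonferroniM size of the comparison family; the p-value is
#'   multiplied by `bonferroniM` and capped at 1.
#' @param forceTest override the normality rule: "t", "wilcoxon", or NULL
#'   (automatic).
#' @param alphaNormality Shapiro-Wilk level for the normality gate.
#' @return list with `test` ("unpaired t" / "Mann-Whitney U" /
#'   "paired t" / "Wilcoxon signed-rank"), `statistic`, `p`,
#'   `pAdjusted`, `nPerGroup`, `normal` (the gate's verdict).
#' @export
compareGroups <- function(x, y, paired = FALSE, bonferroniM = 1L,
                          forceTest = NULL, alphaNormality = 0.05) {
  if (paired) {
    if (length(x) != length(y))
      stop("paired comparison needs equal-length samples")
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 2L) stop("need at least 2 complete pairs")
    d <- (x - y)[keep]
    normal <- shapiroNormal(d, alphaNormality)
    useT <- if (is.null(forceTest)) normal else forceTest == "t"
    res <- if (useT) stats::t.test(x[keep], y[keep], paired = TRUE)
           else stats::wilcox.test(x[keep], y[keep], paired = TRUE,
                                   exact = FALSE)
    test <- if (useT) "paired t" else "Wilcoxon signed-rank"
    n <- c(sum(keep), sum(keep))
  } else {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L)
      stop("need at least 2 values per group")
    normal <- shapiroNormal(x, alphaNormality) &&
              shapiroNormal(y, alphaNormality)
    useT <- if (is.null(forceTest)) normal else forceTest == "t"
    res <- if (useT) stats::t.test(x, y, var.equal = TRUE)
           else stats::wilcox.test(x, y, exact = FALSE)
    test <- if (useT) "unpaired t" else "Mann-Whitney U"
    n <- c(length(x), length(y))
  }
  p <- unname(res$p.value)
  list(test = test, statistic = unname(res$statistic), p = p,
       pAdjusted = min(1, p * max(1L, bonferroniM)), nPerGroup = n,
       normal = normal)
}

shapiroNormal <- function(v, alpha) {
  if (length(v) < 3L || stats::sd(v) == 0) return(TRUE)
  n <- length(unique(v))
  if (n < 3L) return(TRUE)
  stats::shapiro.test(v)$p.value > alpha
}

#' Pearson correlation with two-sided p
#'
#' Pearson r with the two-sided p-value from the t distribution with
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return list(r, p, n).
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = unname(ct$p.value), n = length(x))
}
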
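## Scale reliability, association strength, and the one-tailed reporting
## convention.

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a sum scale:
#' `alpha = k/(k-1) * (1 - sum(var_i) / var(total))`.
#'
#' @param items Numeric matrix or data frame, observations x items
#'   (>= 2 items, >= 3 observations).
#' @return Scalar alpha.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100), 50, 2); cronbach_alpha(cbind(x, x))
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  if (ncol(x) < 2L) stop("need at least 2 items")
  if (nrow(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x)) x <- x[stats::complete.cases(x), , drop = FALSE]
  total_var <- var(rowSums(x))
  if (total_var == 0) stop("zero total variance")
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / total_var)
}

#' Cramer's V
#'
#' Association strength for a contingency table:
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))` with the uncorrected Pearson
#' chi-square.
#'
#' @param tab A contingency table or count matrix (>= 2 x 2, counts >= 0).
#' @return Scalar V in `[0, 1]`.
#' @examples
#' cramers_v(matrix(c(10, 0, 0, 10), 2))  # 1
#' @export
cramers_v <- function(tab) {
  x <- as.matrix(tab)
  if (any(x < 0)) stop("counts must be non-negative")
  if (min(dim(x)) < 2L) stop("table must be at least 2 x 2")
  n <- sum(x)
  if (n == 0) stop("all-zero table")
  chi2 <- suppressWarnings(
    stats::chisq.test(x, correct = FALSE)$statistic)
  as.numeric(sqrt(chi2 / (n * (min(dim(x)) - 1))))
}

#' One-tailed p-value under a directional hypothesis
#'
#' Converts a two-tailed p-value to the one-tailed p for a pre-registered
#' direction: half the two-tailed p when the estimate's sign matches the
#' hypothesized direction, and one minus that half otherwise.
#'
#' @param estimate Point estimate.
#' @param p_two Two-tailed p-value.
#' @param direction `"positive"` or `"negative"`: the hypothesized sign.
#' @return One-tailed p-value.
#' @export
one_tailed_p <- function(estimate, p_two, direction = c("positive",
                                                        "negative")) {
  direction <- match.arg(direction)
  matches <- (direction == "positive") == (estimate >= 0)
  ifelse(matches, p_two / 2, 1 - p_two / 2)
}
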
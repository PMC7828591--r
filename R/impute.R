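## Joint-normal multiple imputation and Rubin's rules pooling.

#' Pool estimates across imputations by Rubin's rules
#'
#' Given `m` per-imputation point estimates and their squared standard
#' errors, returns the pooled estimate (the mean), the within-imputation
#' variance `W` (mean of the variances), the between-imputation variance
#' `B` (variance of the estimates), the total variance
#' `T = W + (1 + 1/m) B`, and the normal-reference degrees of freedom
#' `(m - 1) (1 + W / ((1 + 1/m) B))^2` (infinite when `B = 0`).
#'
#' @param estimates Numeric vector of per-imputation estimates (m >= 2).
#' @param within Numeric vector of per-imputation squared standard errors.
#' @return List with `estimate`, `W`, `B`, `T`, `se`, `df`, `statistic`,
#'   `p` (two-tailed, t reference).
#' @examples
#' rubin_pool(c(0.1, 0.2, 0.3), rep(0.01, 3))$T  # 0.0233...
#' @export
rubin_pool <- function(estimates, within) {
  m <- length(estimates)
  stopifnot(m >= 2, length(within) == m, all(within >= 0))
  qbar <- mean(estimates)
  W <- mean(within)
  B <- var(estimates)
  Tv <- W + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  se <- sqrt(Tv)
  stat <- if (se > 0) qbar / se else NA_real_
  list(estimate = qbar, W = W, B = B, T = Tv, se = se, df = df,
       statistic = stat,
       p = if (is.na(stat)) NA_real_ else 2 * pt(-abs(stat), df))
}

impute_once <- function(x, miss, mu, Sigma) {
  ## draw missing cells from the conditional normal given observed cells,
  ## grouped by missingness pattern
  pattern <- apply(miss, 1, function(r) paste(as.integer(r), collapse = ""))
  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    mi <- miss[rows[1], ]
    if (!any(mi)) next
    o <- which(!mi); mset <- which(mi)
    if (!length(o)) {
      x[rows, mset] <- MASS::mvrnorm(length(rows), mu[mset],
                                     Sigma[mset, mset, drop = FALSE])
      next
    }
    Soo <- Sigma[o, o, drop = FALSE]
    Smo <- Sigma[mset, o, drop = FALSE]
    A <- Smo %*% solve(Soo)
    cond_cov <- Sigma[mset, mset, drop = FALSE] - A %*% t(Smo)
    cond_cov <- (cond_cov + t(cond_cov)) / 2
    cmu <- matrix(mu[mset], nrow = length(rows), ncol = length(mset),
                  byrow = TRUE) +
      (x[rows, o, drop = FALSE] -
         matrix(mu[o], nrow = length(rows), ncol = length(o),
                byrow = TRUE)) %*% t(A)
    draw <- MASS::mvrnorm(length(rows), rep(0, length(mset)), cond_cov)
    x[rows, mset] <- cmu + matrix(draw, nrow = length(rows))
  }
  x
}

#' Multiple imputation with Rubin's rules pooling
#'
#' Handles missing-completely-at-random gaps by joint multivariate-normal
#' imputation: for each of `m` completed data sets, the mean vector and
#' covariance matrix are re-estimated from a bootstrap resample of the
#' complete cases (propagating parameter uncertainty), missing cells are
#' drawn from the conditional normal given the observed cells of their
#' row, the user-supplied analysis is run on the completed table, and the
#' per-term estimates are pooled by Rubin's rules.  With no missing cells
#' the pooled result equals the complete-data analysis and the
#' between-imputation variance is zero.
#'
#' @param data A data frame with numeric analysis variables.
#' @param analysis Function taking a completed data frame and returning a
#'   data frame with columns `term`, `estimate`, `se`.
#' @param m Number of imputations (default 20).
#' @param seed Optional integer seed.
#' @param vars Variables forming the imputation model (default: all
#'   numeric columns).
#' @return An object of class `pooled`: data frame with columns `term`,
#'   `estimate`, `se`, `W`, `B`, `T`, `df`, `statistic`, `p`, plus
#'   attribute `m`.
#' @export
impute_and_pool <- function(data, analysis, m = 20, seed = NULL,
                            vars = NULL) {
  stopifnot(is.data.frame(data), is.function(analysis), m >= 2)
  if (is.null(vars))
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  x <- as.matrix(data[vars])
  miss <- is.na(x)
  fully_missing <- vars[colSums(!miss) == 0]
  if (length(fully_missing))
    stop("variable(s) fully missing: ", paste(fully_missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  run <- function(d) {
    res <- analysis(d)
    if (!is.data.frame(res) ||
        !all(c("term", "estimate", "se") %in% names(res)))
      stop("`analysis` must return a data frame with term/estimate/se")
    res
  }

  if (!any(miss)) {
    res <- run(data)
    out <- data.frame(term = res$term, estimate = res$estimate,
                      se = res$se, W = res$se^2, B = 0, T = res$se^2,
                      df = Inf, statistic = res$estimate / res$se,
                      stringsAsFactors = FALSE)
    out$p <- 2 * pnorm(-abs(out$statistic))
    attr(out, "m") <- 0L
    class(out) <- c("pooled", "data.frame")
    return(out)
  }

  cc <- which(stats::complete.cases(x))
  if (length(cc) < length(vars) + 2)
    stop("too few complete cases to estimate the imputation model")

  results <- vector("list", m)
  for (i in seq_len(m)) {
    boot <- x[sample(cc, replace = TRUE), , drop = FALSE]
    mu <- colMeans(boot)
    Sigma <- stats::cov(boot) + diag(1e-8, length(vars))
    xi <- impute_once(x, miss, mu, Sigma)
    di <- data
    di[vars] <- as.data.frame(xi)
    results[[i]] <- run(di)
  }
  terms <- results[[1]]$term
  out <- do.call(rbind, lapply(seq_along(terms), function(j) {
    est <- vapply(results, function(r) r$estimate[j], numeric(1))
    w <- vapply(results, function(r) r$se[j]^2, numeric(1))
    pl <- rubin_pool(est, w)
    data.frame(term = terms[j], estimate = pl$estimate, se = pl$se,
               W = pl$W, B = pl$B, T = pl$T, df = pl$df,
               statistic = pl$statistic, p = pl$p,
               stringsAsFactors = FALSE)
  }))
  attr(out, "m") <- as.integer(m)
  class(out) <- c("pooled", "data.frame")
  out
}

#' @export
print.pooled <- function(x, digits = 4, ...) {
  m <- attr(x, "m")
  cat(if (m > 0) sprintf("Rubin-pooled estimates over %d imputations\n", m)
      else "Complete-data estimates (no missing cells)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
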
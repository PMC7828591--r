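## Hierarchical (blockwise) regression and quartile ANCOVA.

sig_marks <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*",
                       ifelse(p < 0.10, "+", ""))))
}

standardize_df <- function(d) {
  z <- lapply(d, function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) stop("cannot standardize a constant column")
    (x - mean(x)) / s
  })
  as.data.frame(z)
}

#' Hierarchical regression with blockwise entry
#'
#' Fits a sequence of least-squares models on standardized variables,
#' entering the predictor blocks cumulatively (covariates first, symptom
#' domains together at a later step, and so on).  Coefficients are
#' therefore standardized betas; each step reports R-squared, adjusted
#' R-squared, the R-squared increment over the previous step and its
#' F-test.  One-tailed p-values are reported alongside two-tailed ones,
#' halved in the direction of the observed sign (the convention for
#' directional hypotheses).
#'
#' @param data A data frame (a `cohort_table` works as-is); complete cases
#'   over the used variables are analyzed.
#' @param outcome Name of the outcome variable.
#' @param blocks Ordered list of character vectors of predictor names.
#' @return An object of class `hier_reg`: list with `steps` (per-step
#'   coefficient tables), `summary` (per-step R-squared table), `n`,
#'   `outcome`, `blocks`.
#' @examples
#' pre <- cohort_preset_regression("n2")
#' tab <- generate_from_path_model(pre$paths, pre$exo_cor, n = 2000, seed = 1)
#' hierarchical_regression(tab, "n2", pre$blocks)
#' @export
hierarchical_regression <- function(data, outcome, blocks) {
  stopifnot(is.data.frame(data), is.list(blocks), length(blocks) >= 1)
  vars <- c(outcome, unlist(blocks))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("variables absent from data: ", paste(missing_vars, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(d)
  k_total <- length(unlist(blocks))
  if (n <= k_total + 2)
    stop("too few complete cases for the requested predictors")
  z <- standardize_df(d)

  steps <- vector("list", length(blocks))
  summ <- data.frame(step = seq_along(blocks), r_squared = NA_real_,
                     adj_r_squared = NA_real_, delta_r_squared = NA_real_,
                     f_change = NA_real_, df1 = NA_integer_,
                     df2 = NA_integer_, p_change = NA_real_)
  r2_prev <- 0; k_prev <- 0
  for (i in seq_along(blocks)) {
    preds <- unlist(blocks[seq_len(i)])
    X <- as.matrix(z[preds])
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- preds[qx$pivot[seq(qx$rank + 1, ncol(X))]]
      stop("rank-deficient predictor set; collinear: ",
           paste(dropped, collapse = ", "))
    }
    fit <- lm(stats::reformulate(preds, outcome), data = z)
    sm <- summary(fit)
    ct <- sm$coefficients[preds, , drop = FALSE]
    p_two <- ct[, 4]
    steps[[i]] <- data.frame(
      predictor = preds,
      beta = ct[, 1], se = ct[, 2], t = ct[, 3],
      p_two = p_two, p_one = p_two / 2,
      sig = sig_marks(p_two),
      row.names = NULL, stringsAsFactors = FALSE
    )
    r2 <- sm$r.squared
    k <- length(preds)
    q <- k - k_prev
    df2 <- n - k - 1
    f_change <- ((r2 - r2_prev) / q) / ((1 - r2) / df2)
    summ$r_squared[i] <- r2
    summ$adj_r_squared[i] <- 1 - (1 - r2) * (n - 1) / df2
    summ$delta_r_squared[i] <- r2 - r2_prev
    summ$f_change[i] <- f_change
    summ$df1[i] <- q
    summ$df2[i] <- df2
    summ$p_change[i] <- pf(f_change, q, df2, lower.tail = FALSE)
    r2_prev <- r2; k_prev <- k
  }
  structure(list(steps = steps, summary = summ, n = n,
                 outcome = outcome, blocks = blocks),
            class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, digits = 3, ...) {
  cat("Hierarchical regression of", x$outcome,
      sprintf("(n = %d complete cases)\n", x$n))
  for (i in seq_along(x$steps)) {
    s <- x$summary[i, ]
    cat(sprintf(
      "\nStep %d: R2 = %.3f (adj %.3f), dR2 = %.3f, F(%d, %d) = %.2f, p = %.4f\n",
      i, s$r_squared, s$adj_r_squared, s$delta_r_squared, s$df1, s$df2,
      s$f_change, s$p_change))
    st <- x$steps[[i]]
    st[, c("beta", "se", "t", "p_two", "p_one")] <-
      round(st[, c("beta", "se", "t", "p_two", "p_one")], digits)
    print(st, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.hier_reg <- function(object, step = length(object$steps), ...) {
  st <- object$steps[[step]]
  setNames(st$beta, st$predictor)
}

#' Quartile ANCOVA with a lowest-quartile-versus-rest contrast
#'
#' Splits the grouping variable into sample quartiles (boundary ties
#' assigned to the lower group), fits `outcome ~ covariate + quartile` by
#' least squares, and reports the omnibus group F-test (covariate
#' partialled first) with its mean squared error and partial eta squared,
#' plus the planned contrast of the lowest quartile against the mean of
#' the other three, on the same error term.
#'
#' @param data A data frame.
#' @param outcome Outcome variable name.
#' @param group Variable to be quartiled (e.g. a symptom T-score).
#' @param covariate Optional covariate name (e.g. mother's education).
#' @return An object of class `ancova_quartile`: lists `omnibus`
#'   (`f`, `df1`, `df2`, `mse`, `eta_sq_p`, `p`) and `contrast`
#'   (`estimate` = adjusted mean of quartiles 2-4 minus quartile 1, `f`,
#'   `eta_sq_p`, `p_two`, `p_one`), plus `group_n` and `breaks`.
#' @export
quartile_ancova <- function(data, outcome, group, covariate = NULL) {
  vars <- c(outcome, group, covariate)
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  g <- d[[group]]
  if (length(unique(g)) < 4L)
    stop("grouping variable has fewer than 4 distinct values")
  breaks <- quantile(g, probs = 0:4 / 4)
  if (anyDuplicated(breaks))
    stop("tied quartile boundaries produce an empty group; use fewer bins")
  quart <- cut(g, breaks, include.lowest = TRUE, right = TRUE,
               labels = paste0("Q", 1:4))
  if (any(table(quart) == 0L))
    stop("empty quartile after ties; use fewer bins")
  d$.quartile <- quart
  rhs <- c(covariate, ".quartile")
  fit <- lm(stats::reformulate(rhs, outcome), data = d)
  an <- anova(fit)
  ss_grp <- an[".quartile", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  mse <- an["Residuals", "Mean Sq"]
  df2 <- an["Residuals", "Df"]
  omnibus <- list(
    f = an[".quartile", "F value"], df1 = an[".quartile", "Df"], df2 = df2,
    mse = mse, eta_sq_p = ss_grp / (ss_grp + ss_err),
    p = an[".quartile", "Pr(>F)"])

  ## planned contrast: (Q2 + Q3 + Q4)/3 - Q1 on adjusted means.
  ## With treatment coding (Q1 reference) this is the mean of the three
  ## quartile coefficients.
  cf <- coef(fit)
  L <- setNames(rep(0, length(cf)), names(cf))
  L[paste0(".quartileQ", 2:4)] <- 1 / 3
  est <- sum(L * cf)
  se <- sqrt(drop(t(L) %*% vcov(fit) %*% L))
  tval <- est / se
  f_c <- tval^2
  ss_c <- f_c * mse
  p_two <- 2 * pt(-abs(tval), df2)
  contrast <- list(estimate = est, se = se, f = f_c, df1 = 1L, df2 = df2,
                   eta_sq_p = ss_c / (ss_c + ss_err),
                   p_two = p_two, p_one = p_two / 2)
  structure(list(omnibus = omnibus, contrast = contrast,
                 group_n = table(quart), breaks = breaks,
                 outcome = outcome, group = group, covariate = covariate),
            class = "ancova_quartile")
}

#' @export
print.ancova_quartile <- function(x, ...) {
  cat(sprintf("Quartile ANCOVA: %s ~ %s+ quartiles of %s\n", x$outcome,
              if (is.null(x$covariate)) "" else paste0(x$covariate, " "),
              x$group))
  o <- x$omnibus
  cat(sprintf("  omnibus: F(%d, %d) = %.2f, MSE = %.2f, p = %.4f, eta2p = %.3f\n",
              o$df1, o$df2, o$f, o$mse, o$p, o$eta_sq_p))
  cc <- x$contrast
  cat(sprintf(
    "  Q1 vs rest: diff = %.3f, F(1, %d) = %.2f, p(one-tailed) = %.4f, eta2p = %.3f\n",
    cc$estimate, cc$df2, cc$f, cc$p_one, cc$eta_sq_p))
  cat("  group sizes:", paste(sprintf("%s=%d", names(x$group_n), x$group_n),
                              collapse = ", "), "\n")
  invisible(x)
}
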
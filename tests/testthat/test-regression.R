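test_that("single standardized predictor beta equals the zero-order r", {
  set.seed(1)
  x <- rnorm(500); y <- 0.4 * x + rnorm(500)
  d <- data.frame(x = x, y = y)
  h <- hierarchical_regression(d, "y", list("x"))
  expect_equal(unname(coef(h)["x"]), cor(x, y), tolerance = 1e-10)
})

test_that("orthogonal predictors decompose R2 into squared correlations", {
  set.seed(2)
  n <- 4000
  x1 <- rnorm(n); x2 <- rnorm(n)
  x2 <- stats::residuals(lm(x2 ~ x1))  # exactly orthogonal in-sample
  y <- 0.5 * x1 + 0.3 * x2 + rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2, y = y)
  h <- hierarchical_regression(d, "y", list("x1", "x2"))
  r1 <- cor(x1, y); r2 <- cor(x2, y)
  # normal-equations oracle: with orthogonal standardized predictors each
  # beta is its own zero-order r and R2 adds up
  expect_equal(unname(coef(h)), c(r1, r2), tolerance = 1e-10)
  expect_equal(h$summary$r_squared[2], r1^2 + r2^2, tolerance = 1e-10)
})

test_that("stepwise bookkeeping obeys its identities", {
  pre <- cohort_preset_regression("n2")
  tab <- generate_from_path_model(pre$paths, pre$exo_cor, n = 3000, seed = 3)
  h <- hierarchical_regression(tab, "n2", pre$blocks)
  s <- h$summary
  expect_true(all(diff(s$r_squared) >= 0))
  expect_equal(s$delta_r_squared, c(s$r_squared[1], diff(s$r_squared)))
  k <- c(1, 3)  # cumulative predictor counts
  expect_equal(s$adj_r_squared,
               1 - (1 - s$r_squared) * (h$n - 1) / (h$n - k - 1))
  # one-tailed p is half the two-tailed p in the estimate's direction
  st <- h$steps[[2]]
  expect_equal(st$p_one, st$p_two / 2)
  expect_equal(one_tailed_p(-0.3, 0.04, "negative"), 0.02)
  expect_equal(one_tailed_p(-0.3, 0.04, "positive"), 0.98)
})

test_that("collinear predictors raise an informative error", {
  set.seed(4)
  d <- data.frame(x = rnorm(50))
  d$y <- rnorm(50)
  d$x2 <- 2 * d$x
  expect_error(hierarchical_regression(d, "y", list(c("x", "x2"))),
               "collinear.*x2")
  expect_error(hierarchical_regression(d, "y", list("missing_var")),
               "absent")
})

test_that("regression on a calibrated cohort recovers the coefficients", {
  pre <- cohort_preset_regression("n2")
  tab <- generate_from_path_model(pre$paths, pre$exo_cor, n = 30000, seed = 5)
  h <- hierarchical_regression(tab, "n2", pre$blocks)
  b <- coef(h)
  expect_lt(abs(b[["ia_child"]] - 0.31), 0.03)
  expect_lt(abs(b[["hi_child"]] - 0), 0.03)
  expect_lt(abs(b[["mother_edu"]] - (-0.25)), 0.03)
})

test_that("quartile ANCOVA matches a projection sums-of-squares oracle", {
  # fixed 12-row table, 3 per quartile
  d <- data.frame(
    g = 1:12,
    cov = c(2.1, 1.8, 2.5, 3.0, 2.2, 1.5, 2.8, 3.1, 2.0, 1.7, 2.9, 2.4),
    y = c(-3.2, -2.8, -3.5, -1.1, -0.7, -1.4, -0.9, -1.2, -0.6, -1.0,
          -0.8, -1.3))
  a <- quartile_ancova(d, "y", "g", "cov")
  expect_equal(unname(as.numeric(a$group_n)), rep(3, 4))

  # brute-force decomposition by direct projection
  grp <- rep(1:4, each = 3)
  X0 <- cbind(1, d$cov)
  X1 <- cbind(X0, outer(grp, 2:4, `==`) + 0)
  P <- function(X) X %*% solve(t(X) %*% X) %*% t(X)
  y <- d$y
  ss_err <- sum((y - P(X1) %*% y)^2)
  ss_grp <- sum((P(X1) %*% y)^2) - sum((P(X0) %*% y)^2)
  df2 <- nrow(d) - ncol(X1)
  f_oracle <- (ss_grp / 3) / (ss_err / df2)
  expect_equal(a$omnibus$f, f_oracle, tolerance = 1e-10)
  expect_equal(a$omnibus$mse, ss_err / df2, tolerance = 1e-10)
  expect_equal(a$omnibus$eta_sq_p, ss_grp / (ss_grp + ss_err),
               tolerance = 1e-10)

  # contrast oracle: mean of Q2..Q4 effects minus Q1, raw matrix algebra
  beta <- solve(t(X1) %*% X1) %*% t(X1) %*% y
  L <- c(0, 0, 1 / 3, 1 / 3, 1 / 3)
  est <- sum(L * beta)
  varL <- (ss_err / df2) * t(L) %*% solve(t(X1) %*% X1) %*% L
  f_c <- est^2 / as.numeric(varL)
  expect_equal(a$contrast$estimate, est, tolerance = 1e-10)
  expect_equal(a$contrast$f, f_c, tolerance = 1e-10)
  ss_c <- f_c * ss_err / df2
  expect_equal(a$contrast$eta_sq_p, ss_c / (ss_c + ss_err),
               tolerance = 1e-10)
})

test_that("a lone depressed lowest quartile drives the planned contrast", {
  set.seed(6)
  n <- 10000
  g <- rnorm(n)
  cov <- rnorm(n)
  y <- rnorm(n)
  y[g <= quantile(g, 0.25)] <- y[g <= quantile(g, 0.25)] - 1
  a <- quartile_ancova(data.frame(g = g, cov = cov, y = y), "y", "g", "cov")
  expect_lt(a$contrast$p_one, 1e-10)
  expect_gt(a$contrast$estimate, 0.8)
  # the omnibus effect is carried by that contrast: its SS dominates
  expect_gt(a$contrast$f / 3, a$omnibus$f * 0.9)
})

test_that("degenerate groupings are rejected", {
  d <- data.frame(g = rep(1:3, 8), y = rnorm(24))
  expect_error(quartile_ancova(d, "y", "g"), "fewer than 4 distinct")
  d2 <- data.frame(g = c(rep(1, 20), 2:5), y = rnorm(24))
  expect_error(quartile_ancova(d2, "y", "g"), "fewer bins")
})

test_that("identical group means give a null omnibus test", {
  d <- data.frame(g = 1:40, y = rep(1:10, 4))  # every quartile mean 5.5
  a <- quartile_ancova(d, "y", "g")
  expect_lt(a$omnibus$f, 1e-20)
  expect_lt(a$omnibus$eta_sq_p, 1e-20)
})
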
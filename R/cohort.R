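## Synthetic longitudinal cohorts and synthetic ERP epoch sets.
## Every downstream stage of the package is testable on these generators.

#' Nearest positive-definite repair of a correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below `eps` are raised to `eps`, the
#' matrix is reconstructed and rescaled back to unit diagonal.  The repair
#' refuses to paper over genuinely broken inputs: if the most negative
#' eigenvalue lies below `-max_shift` an error is raised rather than a
#' silent large repair.  When a repair is applied a message is emitted.
#'
#' @param R Symmetric correlation matrix (unit diagonal).
#' @param eps Eigenvalue floor.
#' @param max_shift Largest admissible negative eigenvalue magnitude.
#' @return A positive-definite correlation matrix with attribute
#'   `repaired` (logical).
#' @export
nearest_pd <- function(R, eps = 1e-6, max_shift = 0.05) {
  if (!isSymmetric(unname(R), tol = 1e-10))
    stop("correlation matrix is not symmetric")
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  min_ev <- min(e$values)
  if (min_ev >= eps) {
    attr(R, "repaired") <- FALSE
    return(R)
  }
  if (min_ev < -max_shift)
    stop(sprintf(
      "matrix is too far from positive definite (min eigenvalue %.4f < -%.2f)",
      min_ev, max_shift))
  vals <- pmax(e$values, eps)
  Rp <- e$vectors %*% diag(vals) %*% t(e$vectors)
  Rp <- cov2cor(Rp)
  dimnames(Rp) <- dimnames(R)
  message(sprintf(
    "nearest-PD repair applied: min eigenvalue %.2e clipped to %.0e (Frobenius shift %.4f)",
    min_ev, eps, sqrt(sum((Rp - R)^2))))
  attr(Rp, "repaired") <- TRUE
  Rp
}

#' Generate a cohort from a target correlation matrix
#'
#' Multivariate-normal draws with the given correlation structure (after
#' nearest-PD repair if needed), optionally rescaled to per-variable means
#' and SDs.  Marginals are Gaussian; downstream analyses standardize
#' anyway.
#'
#' @param R Target correlation matrix with variable names as dimnames.
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @param means,sds Optional named vectors of marginal means/SDs (defaults
#'   0/1).
#' @return A data frame of class `cohort_table` with attributes `mode`,
#'   `seed`, `repaired`.
#' @examples
#' tab <- generate_from_correlation(cohort_preset_correlations(), 1000, seed = 1)
#' round(cor(tab$n2, tab$ia_child), 2)
#' @export
generate_from_correlation <- function(R, n, seed = NULL,
                                      means = NULL, sds = NULL) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R), n >= 2)
  if (is.null(rownames(R)))
    dimnames(R) <- list(paste0("v", seq_len(nrow(R))),
                        paste0("v", seq_len(nrow(R))))
  if (max(abs(diag(R) - 1)) > 1e-8) stop("diagonal must be 1")
  Rp <- nearest_pd(R)
  if (!is.null(seed)) set.seed(seed)
  x <- MASS::mvrnorm(n, mu = rep(0, nrow(Rp)), Sigma = Rp)
  colnames(x) <- rownames(Rp)
  x <- rescale_columns(x, means, sds)
  out <- as.data.frame(x)
  attr(out, "mode") <- "correlation"
  attr(out, "seed") <- seed
  attr(out, "repaired") <- attr(Rp, "repaired")
  class(out) <- c("cohort_table", "data.frame")
  out
}

rescale_columns <- function(x, means, sds) {
  if (!is.null(sds))
    for (v in names(sds)) if (v %in% colnames(x)) x[, v] <- x[, v] * sds[[v]]
  if (!is.null(means))
    for (v in names(means)) if (v %in% colnames(x)) x[, v] <- x[, v] + means[[v]]
  x
}

topological_order <- function(paths, exogenous) {
  resolved <- exogenous
  order <- character(0)
  pending <- names(paths)
  while (length(pending)) {
    ready <- pending[vapply(pending, function(v)
      all(names(paths[[v]]) %in% resolved), logical(1))]
    if (!length(ready))
      stop("path model is cyclic or references undefined variables: ",
           paste(pending, collapse = ", "))
    order <- c(order, ready)
    resolved <- c(resolved, ready)
    pending <- setdiff(pending, ready)
  }
  order
}

#' Correlation matrix implied by a recursive path model
#'
#' Builds, by path tracing in topological order, the population
#' correlation matrix of a recursive system in which every endogenous
#' variable is a linear combination of standardized parents plus an
#' independent Gaussian disturbance scaled so the variable itself has unit
#' variance.
#'
#' @inheritParams generate_from_path_model
#' @return List with `cor` (full implied correlation matrix),
#'   `disturbance_var` (named, per endogenous variable), `order`
#'   (topological), `exogenous`.
#' @export
path_implied_cor <- function(paths, exo_cor = NULL) {
  stopifnot(is.list(paths), length(paths) >= 1,
            !is.null(names(paths)))
  parents <- unique(unlist(lapply(paths, names)))
  if (is.null(parents)) stop("every path entry needs named coefficients")
  exogenous <- setdiff(parents, names(paths))
  if (is.null(exo_cor)) {
    exo_cor <- diag(length(exogenous))
    dimnames(exo_cor) <- list(exogenous, exogenous)
  }
  if (!all(exogenous %in% rownames(exo_cor)))
    stop("exo_cor must cover all exogenous variables: ",
         paste(setdiff(exogenous, rownames(exo_cor)), collapse = ", "))
  exo_cor <- exo_cor[exogenous, exogenous, drop = FALSE]
  order <- topological_order(paths, exogenous)

  vars <- c(exogenous, order)
  S <- diag(length(vars))
  dimnames(S) <- list(vars, vars)
  S[exogenous, exogenous] <- exo_cor
  dvar <- setNames(numeric(length(order)), order)
  for (y in order) {
    b <- paths[[y]]
    p <- names(b)
    ## cov(y, z) = sum_j b_j cov(p_j, z) for every already-placed z
    placed <- setdiff(vars[seq_len(match(y, vars))], y)
    S[y, placed] <- S[placed, y] <- as.numeric(b %*% S[p, placed, drop = FALSE])
    explained <- as.numeric(b %*% S[p, p, drop = FALSE] %*% b)
    dvar[y] <- 1 - explained
    if (dvar[y] <= 0)
      stop(sprintf(
        "coefficients over-determined: implied disturbance variance of '%s' is %.3f <= 0",
        y, dvar[y]))
  }
  list(cor = S, disturbance_var = dvar, order = order, exogenous = exogenous)
}

#' Generate a cohort from a recursive path model
#'
#' Variables are built in topological order: exogenous variables are drawn
#' jointly normal with correlation `exo_cor`, and each endogenous variable
#' equals the stated linear combination of its (standardized) parents plus
#' a Gaussian disturbance scaled so the variable has unit population
#' variance.  The population standardized path coefficients therefore
#' equal the specified values exactly, so refitting the same structure on
#' a large generated cohort recovers them.
#'
#' @param paths Named list: one entry per endogenous variable, each a named
#'   numeric vector of standardized coefficients on its parents, e.g.
#'   `list(m = c(x = 0.5), y = c(m = 0.4))`.
#' @param exo_cor Correlation matrix among the exogenous variables
#'   (default: identity).
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @param means,sds Optional named marginal rescalings applied after
#'   generation.
#' @return A `cohort_table` data frame with attribute `implied_cor`.
#' @examples
#' tab <- generate_from_path_model(list(m = c(x = 0.5), y = c(m = 0.4)),
#'                                 n = 5000, seed = 1)
#' round(cor(tab$x, tab$y), 2)  # close to 0.5 * 0.4 = 0.20
#' @export
generate_from_path_model <- function(paths, exo_cor = NULL, n, seed = NULL,
                                     means = NULL, sds = NULL) {
  imp <- path_implied_cor(paths, exo_cor)
  if (!is.null(seed)) set.seed(seed)
  q <- length(imp$exogenous)
  x <- matrix(numeric(0), nrow = n, ncol = 0)
  if (q > 0) {
    xe <- MASS::mvrnorm(n, mu = rep(0, q),
                        Sigma = imp$cor[imp$exogenous, imp$exogenous,
                                        drop = FALSE])
    x <- matrix(xe, nrow = n)
    colnames(x) <- imp$exogenous
  }
  for (y in imp$order) {
    b <- paths[[y]]
    yv <- as.numeric(x[, names(b), drop = FALSE] %*% b) +
      rnorm(n, sd = sqrt(imp$disturbance_var[[y]]))
    x <- cbind(x, yv)
    colnames(x)[ncol(x)] <- y
  }
  x <- rescale_columns(x, means, sds)
  out <- as.data.frame(x)
  attr(out, "mode") <- "path"
  attr(out, "seed") <- seed
  attr(out, "implied_cor") <- imp$cor
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Mask cells completely at random
#'
#' MCAR masking: each cell of a listed variable is set to `NA`
#' independently with that variable's rate, emulating item- and
#' instrument-level missingness in longitudinal cohorts.
#'
#' @param table A data frame.
#' @param rates Named numeric vector of per-variable missingness rates in
#'   `[0, 1]`; unlisted variables stay complete.
#' @param seed Optional integer seed.
#' @return The data frame with `NA`s injected.
#' @export
inject_missingness <- function(table, rates, seed = NULL) {
  stopifnot(is.data.frame(table))
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  unknown <- setdiff(names(rates), names(table))
  if (length(unknown)) stop("unknown variables: ",
                            paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  for (v in names(rates)) {
    mask <- runif(nrow(table)) < rates[[v]]
    table[[v]][mask] <- NA
  }
  table
}

#' Generate a synthetic ERP epoch set for one subject
#'
#' Emits clean, baseline-ready epochs carrying a known ground truth.  All
#' trials share a go-locked positive template (Gaussian bump); successful
#' stop trials additionally carry a stop-locked negative N2 deflection — a
#' Gaussian bump centered at `bump_center` ms (default 215) with SD
#' `bump_sd` ms (default 20) and peak `n2_amplitude` microvolts — on the
#' ROI channels only.  Independent Gaussian sensor noise of SD `noise_sd`
#' is added to every sample.  Go RTs are drawn from an ex-Gaussian law so
#' the median split is exercised.  Because the go template is common to
#' both conditions, the stop-minus-slow-go difference wave isolates the
#' injected N2 exactly when `noise_sd = 0`.
#'
#' @param n2_amplitude Peak of the injected N2 deflection, microvolts
#'   (negative for a canonical N2).
#' @param n_stop,n_go Trial counts (defaults 35 successful-stop and 144
#'   go, typical post-artifact-rejection counts for a three-block SST).
#' @param noise_sd Sensor noise SD, microvolts.
#' @param go_rt Length-3 vector (mu, sigma, tau) of the go-RT law, ms.
#' @param sampling_rate Hz; default 250.
#' @param epoch_window ms pair; default `c(-200, 800)`.
#' @param channels Channel labels; defaults to six ROI channels plus two
#'   non-ROI channels.
#' @param roi_channels Channels carrying the N2 deflection.
#' @param bump_center,bump_sd Center and SD of the N2 bump, ms.
#' @param go_template_amp,go_template_center,go_template_sd Shape of the
#'   shared go-locked template.
#' @param seed Optional integer seed.
#' @return An `epoch_set` with attribute `true_n2_window_mean`, the
#'   analytic (sample-grid) mean of the injected bump over 180-250 ms.
#' @export
generate_epoch_set <- function(n2_amplitude = -2, n_stop = 35, n_go = 144,
                               noise_sd = 10,
                               go_rt = c(mu = 480, sigma = 90, tau = 200),
                               sampling_rate = 250,
                               epoch_window = c(-200, 800),
                               channels = c(paste0("ROI", 1:6), "C1", "P1"),
                               roi_channels = paste0("ROI", 1:6),
                               bump_center = 215, bump_sd = 20,
                               go_template_amp = 2, go_template_center = 300,
                               go_template_sd = 50, seed = NULL) {
  stopifnot(n_stop >= 1, n_go >= 1, noise_sd >= 0)
  if (!all(roi_channels %in% channels))
    stop("roi_channels must be a subset of channels")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(epoch_window[1], epoch_window[2], by = 1000 / sampling_rate)
  n_trials <- n_stop + n_go
  n_ch <- length(channels)
  n_s <- length(t)

  template <- go_template_amp * exp(-(t - go_template_center)^2 /
                                      (2 * go_template_sd^2))
  bump <- n2_amplitude * exp(-(t - bump_center)^2 / (2 * bump_sd^2))

  data <- array(rnorm(n_trials * n_ch * n_s, sd = noise_sd),
                dim = c(n_trials, n_ch, n_s))
  for (ch in seq_len(n_ch)) {
    data[, ch, ] <- data[, ch, ] + rep(template, each = n_trials)
    if (channels[ch] %in% roi_channels)
      data[seq_len(n_stop), ch, ] <- data[seq_len(n_stop), ch, ] +
        rep(bump, each = n_stop)
  }
  condition <- c(rep("successful_stop", n_stop), rep("go", n_go))
  rt <- c(rep(NA_real_, n_stop),
          sample_ex_gaussian(n_go, go_rt[[1]], go_rt[[2]], go_rt[[3]]))
  ep <- epoch_set(data, sampling_rate, epoch_window, channels, condition, rt)
  win <- t >= 180 & t <= 250
  attr(ep, "true_n2_window_mean") <- mean(bump[win])
  ep
}
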
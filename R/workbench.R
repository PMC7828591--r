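## End-to-end synthetic study: cohort -> per-subject SST + epochs ->
## SSRT / N2 derivation -> statistics, with deterministic stage seeding
## and a reproducibility manifest.

md5_of <- function(object) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(object), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

#' Configuration of a full synthetic study
#'
#' Bundles everything [run_full_pipeline()] needs: the cohort generator
#' (a correlation matrix or a path-model preset), how the latent
#' inhibition trait maps to the stop-latency law (`ssrt_link`: stop
#' latency in ms = mean + sd * standardized trait), how the latent N2
#' trait maps to the injected deflection (`n2_link`, microvolts), the SST
#' task and race parameters, the epoch generator settings, optional MCAR
#' missingness and multiple-imputation settings, the analysis plan, and a
#' master seed from which all stage seeds are derived.
#'
#' @param n_subjects Number of subjects.
#' @param cohort Either a correlation matrix (correlation mode) or a list
#'   with elements `paths`/`exo_cor` (path mode, e.g.
#'   [cohort_preset_path()]).
#' @param sst `TRUE` to simulate SST sessions and estimate SSRT.
#' @param task,race Task and race-model settings for the SST stage.
#' @param ssrt_link Length-2 vector `c(mean, sd)`: stop latency in ms as
#'   an affine map of the standardized latent inhibition trait (`ssrt`
#'   column).
#' @param erp `TRUE` to generate epochs and derive the N2.
#' @param epochs List of [generate_epoch_set()] arguments (trial counts,
#'   `noise_sd`, ...).
#' @param n2_link Length-2 vector `c(mean, sd)`: injected N2 amplitude in
#'   microvolts as an affine map of the standardized latent N2 trait.
#' @param missingness Optional named rates for [inject_missingness()]
#'   applied to the analysis table.
#' @param mi Number of imputations (0 disables pooling; >= 2 enables it
#'   when missingness is present).
#' @param regression Optional list `list(outcome =, blocks =)` for
#'   [hierarchical_regression()].
#' @param path_formulas Optional formula list for [fit_path_model()].
#' @param seed Master seed; stage seeds are drawn deterministically from
#'   it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_subjects = 100,
                         cohort = cohort_preset_correlations(),
                         sst = TRUE, task = task_config(),
                         race = race_params(),
                         ssrt_link = c(mean = 160, sd = 30),
                         erp = TRUE, epochs = list(),
                         n2_link = c(mean = -0.12, sd = 2.06),
                         missingness = NULL, mi = 0,
                         regression = NULL, path_formulas = NULL,
                         seed = 1) {
  stopifnot(n_subjects >= 2, is.numeric(seed), length(seed) == 1)
  structure(list(
    n_subjects = as.integer(n_subjects), cohort = cohort, sst = isTRUE(sst),
    task = task, race = race, ssrt_link = ssrt_link, erp = isTRUE(erp),
    epochs = epochs, n2_link = n2_link, missingness = missingness,
    mi = as.integer(mi), regression = regression,
    path_formulas = path_formulas, seed = as.integer(seed)
  ), class = "study_config")
}

subject_seed <- function(stage_seed, i) (stage_seed + 7919 * i) %% 2147483647

#' Run the full synthetic study
#'
#' Executes the pipeline: (1) generate the latent cohort; (2) per subject,
#' simulate an SST session whose constant stop latency is the mapped
#' latent inhibition trait, screen it against the race-model assumptions,
#' and estimate the SSRT by the integration method (excluded subjects are
#' listed with reasons); (3) per subject, generate ERP epochs whose
#' injected N2 equals the mapped latent N2 trait and run the
#' stop-minus-slow-go derivation; (4) assemble the analysis table
#' (derived measures replacing the latent ones where derived), inject
#' missingness if configured, and run the configured analyses, pooled
#' over multiple imputations when enabled.  Stage seeds are derived
#' deterministically from the master seed, so identical configurations
#' reproduce identical numeric outputs; a manifest records the seeds,
#' exclusions, and an md5 hash over the per-subject results.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, writes
#'   `behavioral.csv`, `n2.csv`, `analysis.json`, `manifest.json` (each
#'   CSV carries the config hash in a leading comment line).
#' @return An object of class `study_result`: list with `subjects` (per-
#'   subject table), `analyses`, `manifest`.
#' @export
run_full_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(2147483646, 4)
  names(stage_seeds) <- c("cohort", "sst", "erp", "missingness")
  n <- config$n_subjects

  ## stage 1: latent cohort (standardized)
  latent <- if (is.matrix(config$cohort)) {
    generate_from_correlation(config$cohort, n, seed = stage_seeds[["cohort"]])
  } else {
    generate_from_path_model(config$cohort$paths, config$cohort$exo_cor,
                             n, seed = stage_seeds[["cohort"]])
  }
  subjects <- cbind(data.frame(subject = seq_len(n)), latent)

  ## stage 2: SST simulation and SSRT estimation
  exclusions <- data.frame(subject = integer(0), reason = character(0),
                           stringsAsFactors = FALSE)
  if (config$sst) {
    if (!"ssrt" %in% names(latent))
      stop("SST stage needs a latent `ssrt` column in the cohort")
    lk <- config$ssrt_link
    subjects$stop_latency_true <-
      pmax(lk[["mean"]] + lk[["sd"]] * scale(latent$ssrt)[, 1], 1)
    subjects$ssrt_hat <- NA_real_
    subjects$sst_valid <- NA
    for (i in seq_len(n)) {
      pars <- config$race
      pars$stop_mu <- subjects$stop_latency_true[i]
      log <- simulate_session(pars, config$task,
                              seed = subject_seed(stage_seeds[["sst"]], i))
      v <- check_race_assumptions(log)
      subjects$sst_valid[i] <- v$valid
      if (v$valid) {
        subjects$ssrt_hat[i] <- estimate_ssrt(log)$ssrt
      } else {
        exclusions <- rbind(exclusions, data.frame(
          subject = i, reason = paste(v$reasons, collapse = "; "),
          stringsAsFactors = FALSE))
      }
    }
  }

  ## stage 3: epochs and N2 derivation
  if (config$erp) {
    if (!"n2" %in% names(latent))
      stop("ERP stage needs a latent `n2` column in the cohort")
    lk <- config$n2_link
    subjects$n2_true_uv <- lk[["mean"]] + lk[["sd"]] * scale(latent$n2)[, 1]
    ep_args <- config$epochs
    roi <- roi_spec(ep_args$roi_channels %||% paste0("ROI", 1:6))
    subjects$n2_hat <- vapply(seq_len(n), function(i) {
      args <- c(list(n2_amplitude = subjects$n2_true_uv[i],
                     seed = subject_seed(stage_seeds[["erp"]], i)), ep_args)
      derive_n2(do.call(generate_epoch_set, args), roi)
    }, numeric(1))
  }

  ## stage 4: analysis table and configured analyses
  analysis_tab <- latent
  if (config$erp) analysis_tab$n2 <- subjects$n2_hat
  if (config$sst) analysis_tab$ssrt <- subjects$ssrt_hat
  if (!is.null(config$missingness))
    analysis_tab <- inject_missingness(analysis_tab, config$missingness,
                                       seed = stage_seeds[["missingness"]])
  analyses <- list()
  use_mi <- config$mi >= 2 && anyNA(analysis_tab)
  if (!is.null(config$regression)) {
    reg <- config$regression
    analyses$regression <- if (use_mi) {
      impute_and_pool(analysis_tab, function(d) {
        h <- hierarchical_regression(d, reg$outcome, reg$blocks)
        st <- h$steps[[length(h$steps)]]
        data.frame(term = st$predictor, estimate = st$beta, se = st$se)
      }, m = config$mi, seed = stage_seeds[["missingness"]])
    } else {
      hierarchical_regression(analysis_tab, reg$outcome, reg$blocks)
    }
  }
  if (!is.null(config$path_formulas)) {
    analyses$path <- if (use_mi) {
      impute_and_pool(analysis_tab, function(d) {
        f <- fit_path_model(d, config$path_formulas)
        cf <- f$coefficients
        data.frame(term = paste(cf$from, "->", cf$to),
                   estimate = cf$estimate, se = cf$se)
      }, m = config$mi, seed = stage_seeds[["missingness"]])
    } else {
      fit_path_model(analysis_tab, config$path_formulas)
    }
  }

  config_hash <- md5_of(unclass(config))
  manifest <- list(
    config_hash = config_hash,
    master_seed = config$seed,
    stage_seeds = as.list(stage_seeds),
    n_subjects = n,
    n_excluded = nrow(exclusions),
    exclusions = exclusions,
    results_hash = md5_of(lapply(subjects, function(col)
      if (is.numeric(col)) signif(col, 12) else col))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_commented_csv <- function(d, path) {
      con <- file(path, "w")
      writeLines(paste("# config", config_hash), con)
      write.csv(d, con, row.names = FALSE)
      close(con)
    }
    behav_cols <- intersect(c("subject", "stop_latency_true", "ssrt_hat",
                              "sst_valid"), names(subjects))
    write_commented_csv(subjects[behav_cols],
                        file.path(out_dir, "behavioral.csv"))
    n2_cols <- intersect(c("subject", "n2_true_uv", "n2_hat"),
                         names(subjects))
    write_commented_csv(subjects[n2_cols], file.path(out_dir, "n2.csv"))
    jsonlite::write_json(
      lapply(analyses, serialize_analysis),
      file.path(out_dir, "analysis.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(subjects = subjects, analyses = analyses,
                 manifest = manifest), class = "study_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

serialize_analysis <- function(a) {
  if (inherits(a, "hier_reg"))
    list(kind = "hierarchical_regression", steps = a$steps,
         summary = a$summary)
  else if (inherits(a, "path_fit"))
    list(kind = "path_model", coefficients = a$coefficients,
         indirect = a$indirect, r_squared = as.list(a$r_squared),
         fit = a$fit)
  else if (inherits(a, "pooled"))
    list(kind = "pooled", m = attr(a, "m"), estimates = as.data.frame(a))
  else a
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Synthetic study: %d subjects, %d excluded by race-model screening\n",
              x$manifest$n_subjects, x$manifest$n_excluded))
  cat("  results hash:", x$manifest$results_hash, "\n")
  for (nm in names(x$analyses)) {
    cat("\n--", nm, "--\n")
    print(x$analyses[[nm]])
  }
  invisible(x)
}
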
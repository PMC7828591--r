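## Built-in calibration presets for the synthetic cohort generator.
## These encode the population structure the generators target by default:
## the 11-variable intercorrelation pattern of a longitudinal ADHD-risk
## cohort (N2 amplitude and SSRT at 17 years, concurrent and childhood
## symptom domains, parental symptoms, early effortful control), maternal
## education, and the standardized path/regression coefficients linking
## early precursors to the adolescent N2 and SSRT.

#' Variables of the default synthetic cohort
#'
#' @return Character vector of the 12 variable names used by the presets:
#'   adolescent N2 mean amplitude and SSRT, concurrent and childhood
#'   inattention and hyperactivity-impulsivity (H/I) symptoms, parental
#'   inattention and H/I symptoms, effortful control at 36 months, and
#'   mother's education.
#' @export
cohort_variables <- function() {
  c("n2", "ssrt", "ia_17", "hi_17", "ia_child", "hi_child",
    "father_ia", "father_hi", "mother_ia", "mother_hi",
    "effortful_control", "mother_edu")
}

#' Default cohort correlation matrix
#'
#' The 11-variable intercorrelation structure of the study variables
#' (adolescent N2 and SSRT, concurrent and childhood symptom domains,
#' parental symptoms, early effortful control), optionally extended by
#' mother's education.  Only the education-N2 correlation (-0.25) is an
#' empirically calibrated education entry; the remaining education
#' correlations default to zero — a modelling choice, overridable by
#' editing the returned matrix.
#'
#' @param include_education Append the `mother_edu` row/column (default
#'   `TRUE`).
#' @return A symmetric correlation matrix with unit diagonal and variable
#'   names from [cohort_variables()].
#' @export
cohort_preset_correlations <- function(include_education = TRUE) {
  v <- cohort_variables()[1:11]
  R <- diag(11)
  dimnames(R) <- list(v, v)
  set_r <- function(a, b, r) R[a, b] <<- R[b, a] <<- r
  set_r("ssrt", "n2", 0.31)
  set_r("ia_17", "n2", 0.14); set_r("ia_17", "ssrt", 0.17)
  set_r("hi_17", "n2", 0.17); set_r("hi_17", "ssrt", 0.14)
  set_r("hi_17", "ia_17", 0.68)
  set_r("ia_child", "n2", 0.28); set_r("ia_child", "ssrt", 0.23)
  set_r("ia_child", "ia_17", 0.50); set_r("ia_child", "hi_17", 0.44)
  set_r("hi_child", "n2", 0.20); set_r("hi_child", "ssrt", 0.26)
  set_r("hi_child", "ia_17", 0.24); set_r("hi_child", "hi_17", 0.40)
  set_r("hi_child", "ia_child", 0.53)
  set_r("father_ia", "n2", 0.25); set_r("father_ia", "ssrt", -0.25)
  set_r("father_ia", "ia_17", 0.12); set_r("father_ia", "hi_17", 0.00)
  set_r("father_ia", "ia_child", 0.14); set_r("father_ia", "hi_child", -0.03)
  set_r("father_hi", "n2", 0.17); set_r("father_hi", "ssrt", -0.03)
  set_r("father_hi", "ia_17", 0.01); set_r("father_hi", "hi_17", -0.20)
  set_r("father_hi", "ia_child", 0.12); set_r("father_hi", "hi_child", 0.01)
  set_r("father_hi", "father_ia", 0.36)
  set_r("mother_ia", "n2", 0.20); set_r("mother_ia", "ssrt", -0.18)
  set_r("mother_ia", "ia_17", 0.17); set_r("mother_ia", "hi_17", 0.10)
  set_r("mother_ia", "ia_child", 0.42); set_r("mother_ia", "hi_child", 0.10)
  set_r("mother_ia", "father_ia", 0.37); set_r("mother_ia", "father_hi", 0.32)
  set_r("mother_hi", "n2", 0.21); set_r("mother_hi", "ssrt", -0.19)
  set_r("mother_hi", "ia_17", -0.06); set_r("mother_hi", "hi_17", 0.02)
  set_r("mother_hi", "ia_child", 0.17); set_r("mother_hi", "hi_child", 0.07)
  set_r("mother_hi", "father_ia", 0.23); set_r("mother_hi", "father_hi", 0.10)
  set_r("mother_hi", "mother_ia", 0.38)
  set_r("effortful_control", "n2", -0.32)
  set_r("effortful_control", "ssrt", -0.12)
  set_r("effortful_control", "ia_17", -0.34)
  set_r("effortful_control", "hi_17", -0.38)
  set_r("effortful_control", "ia_child", -0.35)
  set_r("effortful_control", "hi_child", -0.33)
  set_r("effortful_control", "father_ia", 0.00)
  set_r("effortful_control", "father_hi", -0.09)
  set_r("effortful_control", "mother_ia", -0.26)
  set_r("effortful_control", "mother_hi", -0.20)
  if (!include_education) return(R)
  R12 <- rbind(cbind(R, mother_edu = 0), mother_edu = c(rep(0, 11), 1))
  rownames(R12) <- c(v, "mother_edu")
  R12["mother_edu", "n2"] <- R12["n2", "mother_edu"] <- -0.25
  R12
}

#' Default marginal means and SDs of the cohort variables
#'
#' Marginal scalings matching the descriptive statistics of the study
#' variables: the N2 mean amplitude in microvolts (mean -0.12, SD 2.06),
#' the SSRT in ms (159.90, 56.29), symptom T-scores, raw parental symptom
#' scores, the effortful-control composite, and mother's years of
#' education.  Childhood symptom composites are averaged standardized
#' scores and therefore stay at mean 0, SD 1.
#'
#' @return List with named numeric vectors `means` and `sds`.
#' @export
cohort_preset_margins <- function() {
  list(
    means = c(n2 = -0.12, ssrt = 159.90, ia_17 = 53.37, hi_17 = 58.56,
              ia_child = 0, hi_child = 0, father_ia = 11.31,
              father_hi = 15.55, mother_ia = 10.67, mother_hi = 12.72,
              effortful_control = 9.64, mother_edu = 12.80),
    sds = c(n2 = 2.06, ssrt = 56.29, ia_17 = 9.28, hi_17 = 12.73,
            ia_child = 1, hi_child = 1, father_ia = 5.96,
            father_hi = 7.59, mother_ia = 5.50, mother_hi = 6.02,
            effortful_control = 1.55, mother_edu = 1.72)
  )
}

#' Preset path models linking early precursors to the adolescent N2
#'
#' Standardized recursive path models in which the early precursors
#' (temperamental self-regulation at 36 months and paternal inattention)
#' predict the adolescent N2 amplitude directly and indirectly through
#' inattention symptoms, with mother's education as a covariate.
#'
#' `"concurrent"` uses the effortful-control factor with direct paths
#' -0.33 (effortful control -> N2) and 0.35 (paternal inattention -> N2);
#' `"attentional_focusing"` swaps in the attentional-focusing subscale
#' with direct path -0.29.  The precursor -> inattention paths (-0.34 and
#' 0.12) follow the preset correlation structure; the inattention -> N2
#' path is set to a small non-significant 0.10 and education -> N2 to
#' -0.25.  The two precursors are uncorrelated and education is orthogonal
#' to both, per the preset correlations.
#'
#' @param model `"concurrent"` or `"attentional_focusing"`.
#' @return List with elements `paths` (for
#'   [generate_from_path_model()]), `exo_cor`, and `formulas` (the same
#'   structure as model formulas for [fit_path_model()]).
#' @export
cohort_preset_path <- function(model = c("concurrent",
                                         "attentional_focusing")) {
  model <- match.arg(model)
  precursor <- if (model == "concurrent") "effortful_control"
               else "attentional_focusing"
  direct <- if (model == "concurrent") -0.33 else -0.29
  paths <- list(
    ia_17 = setNames(c(-0.34, 0.12), c(precursor, "father_ia")),
    n2 = setNames(c(direct, 0.35, 0.10, -0.25),
                  c(precursor, "father_ia", "ia_17", "mother_edu"))
  )
  exo <- c(precursor, "father_ia", "mother_edu")
  exo_cor <- diag(3)
  dimnames(exo_cor) <- list(exo, exo)
  formulas <- list(
    stats::reformulate(c(precursor, "father_ia"), "ia_17"),
    stats::reformulate(c(precursor, "father_ia", "ia_17", "mother_edu"), "n2")
  )
  list(paths = paths, exo_cor = exo_cor, formulas = formulas,
       precursor = precursor)
}

#' Preset generating models for the hierarchical regressions
#'
#' Single-equation linear models calibrated to the reported standardized
#' regression coefficients: the adolescent N2 regressed on childhood
#' inattention (0.31), childhood H/I (0), and mother's education (-0.25)
#' with the two childhood symptom domains correlated at 0.53; and the
#' SSRT regressed on the total childhood ADHD composite (0.28) and
#' mother's education (-0.28), orthogonal predictors.
#'
#' @param outcome `"n2"` or `"ssrt"`.
#' @return List with `paths`, `exo_cor`, `blocks` (ordered predictor
#'   blocks for [hierarchical_regression()]), and `outcome`.
#' @export
cohort_preset_regression <- function(outcome = c("n2", "ssrt")) {
  outcome <- match.arg(outcome)
  if (outcome == "n2") {
    paths <- list(n2 = c(ia_child = 0.31, hi_child = 0, mother_edu = -0.25))
    exo <- c("ia_child", "hi_child", "mother_edu")
    exo_cor <- diag(3)
    dimnames(exo_cor) <- list(exo, exo)
    exo_cor["ia_child", "hi_child"] <- exo_cor["hi_child", "ia_child"] <- 0.53
    blocks <- list("mother_edu", c("ia_child", "hi_child"))
  } else {
    paths <- list(ssrt = c(adhd_child = 0.28, mother_edu = -0.28))
    exo <- c("adhd_child", "mother_edu")
    exo_cor <- diag(2)
    dimnames(exo_cor) <- list(exo, exo)
    blocks <- list("mother_edu", "adhd_child")
  }
  list(paths = paths, exo_cor = exo_cor, blocks = blocks, outcome = outcome)
}

#' Default MCAR missingness rates
#'
#' Instrument-level missingness typical of a longitudinal cohort: 3% of
#' subjects lack paternal symptom data and 10% lack the early temperament
#' questionnaire.
#'
#' @return Named numeric vector of per-variable rates.
#' @export
cohort_preset_missingness <- function() {
  c(father_ia = 0.03, father_hi = 0.03, effortful_control = 0.10)
}
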
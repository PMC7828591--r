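---
title: "Simulating and analyzing inhibitory control: the horse race, the N2, and longitudinal path inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing inhibitory control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopnet)
```

# The problem this package addresses

Inhibitory control — the capacity to cancel an already-prepared response —
is one of the most robust neurocognitive correlates of ADHD and is
typically measured two ways in the same experiment: behaviorally, by the
stop-signal reaction time (SSRT) of the stop-signal task (SST), and
electrophysiologically, by the amplitude of the N2, a negative ERP
deflection around 180–250 ms after the stop signal over right-frontal
sites.  Longitudinal high-risk designs then ask whether early precursors —
parental inattention symptoms measured in the child's infancy,
temperamental effortful control at age three — predict these adolescent
markers directly, or only indirectly through the child's own symptom
development.

Real cohorts of this kind are small, private, and expensive.  `stopnet`
implements the full computational chain on synthetic data whose population
structure is calibrated to published descriptives, so every stage — trial
simulation, SSRT estimation, N2 derivation, and the inferential models —
is independently testable against known ground truth.

# The horse-race simulator

The SST is modeled as an independent race on every stop trial: a go
process with ex-Gaussian finishing time $G \sim \mathcal{N}(\mu,\sigma) +
\mathrm{Exp}(\tau)$ races a stop process launched $\mathrm{SSD}$ ms after
the go stimulus with latency $L$.  The trial is inhibited iff

$$\mathrm{SSD} + L < G,$$

strictly: **ties produce a response**.  The tie rule is deliberate — it is
conservative, and it makes the fully deterministic configuration (constant
$G = 600$, $L = 100$, initial SSD 500) resolve exactly: the first stop
trial ties and responds, the staircase steps down, and the SSD oscillates
between 500 and 450 forever with long-run response probability exactly
one half.  The one-up-one-down staircase moves the SSD by `ssd_step`
(default 50 ms) after every stop trial — up after success, down after
failure — which drives the response probability toward 0.5 for any
continuous go law.  The SSD is clamped to
$[0, \texttt{go\_max\_duration} + 1000]$; no published bound exists, and
the clamp only matters under degenerate parameters where the staircase
would otherwise drift without limit.

Two timing choices deserve comment:

* **Response registration.** RTs are capped at `go_max_duration`; later
  finishes become omissions.  The default cap is 2000 ms even though the
  go stimulus in the emulated protocol is displayed for at most 1000 ms:
  observed adolescent RT distributions extend well past 1000 ms with
  omission rates near half a percent, which is only possible if responses
  during the post-stimulus blank are registered.  With the default
  ex-Gaussian (480, 90, 200) the simulator then reproduces a mean go RT
  near 678 ms, omission probability near 0.005, and a choice-error rate
  near 0.05 — the calibration targets.  Users emulating a hard 1000-ms
  deadline can set `go_max_duration = 1000`; roughly 8% of go finishes
  are then censored into omissions, and the integration-method SSRT
  acquires a positive bias because the omission-replacement rule stacks
  probability mass at the cap.
* **Block structure.** The practice block is simulated (the staircase
  warms up on it) but flagged `block = 0` and excluded from every
  estimator.  Whether the tracker resets between blocks is not specified
  in the protocols this emulates; the default carries the SSD across
  blocks, and `carry_ssd_across_blocks = FALSE` resets it.

Choice errors are injected as label flips on responded go trials,
independent of the race, because the estimation guidelines treat them
purely as includable RTs.  Go omissions beyond deadline censoring occur
independently at `p_go_omission`.  Latent finishing times are retained in
the trial log solely so tests can re-derive every inhibition outcome by
direct comparison.

# SSRT estimation and validity screening

The integration method estimates the stop process's finishing time as the
$n$-th RT of the *augmented* go-RT distribution: all responded go RTs
(choice errors and premature responses included) plus one copy of the
subject's maximum RT per go omission, with

$$n = \mathrm{round}\!\left(N \cdot p(\mathrm{respond}\mid\mathrm{stop})\right),
\qquad \mathrm{SSRT} = \mathrm{RT}_{(n)} - \overline{\mathrm{SSD}}.$$

Rounding is to the nearest integer, half away from zero, clamped to
$[1, N]$ — the guidelines leave the discretization open, and this choice
makes the worked examples exact (ten RTs at $p = 0.5$ give $n = 5$).  The
mean SSD is taken over *all* stop test trials, not only post-convergence
ones.  No lower RT cutoff is applied by default.  The mean method
($\overline{\mathrm{RT}}_{go} - \overline{\mathrm{SSD}}$) is provided for
comparison; under tracking to 50% with a right-skewed go law it exceeds
the integration estimate, which is the bias that motivates preferring
integration.

Estimation refuses to run when the horse-race assumptions look violated:
$p(\mathrm{respond}\mid\mathrm{stop})$ outside $[0.25, 0.75]$, or mean
signal-respond RT not strictly below mean go RT.  Sessions with no
responded stop trial are indeterminate and invalid.  An explicit
`override_validity` flag exists for methodological work; it is off by
default, and the batch pipeline records excluded subjects with reasons so
downstream sample sizes reconcile.

# The N2 derivation

Epochs are trials × channels × samples arrays at 250 Hz over −200..800 ms
(251 samples; timestamps sit on exact multiples of 4 ms, and all windows
are endpoint-inclusive on that grid — the 180–250 ms N2 window therefore
contains the 18 samples 180, 184, …, 248 ms).  The derivation is:

1. **Baseline correction**: per trial and channel, subtract the mean over
   −200..0 ms.  The emulated protocols do not state their baseline rule;
   mean subtraction over the pre-stimulus window is the field standard
   and is testable (constants vanish, signals ride through).
2. **Median split of go trials** into slow and fast by the subject's
   median go RT.  Ties at the median go to *slow*, deterministically (an
   unstated detail in the source protocols; the slow half is the one
   comparable, under the race model, to successful stop trials).
3. **Condition averages and the difference wave**: successful-stop ERP
   minus slow-go ERP, removing the go-locked activity that overlaps the
   stop-locked response.  Unsuccessful-stop epochs are carried through
   the container but take no part in the derivation.
4. **ROI mean amplitude** over a configurable channel set (defaults to
   the six placeholder labels `ROI1..ROI6`; montage-specific electrode
   indices cannot be reproduced without a net layout, so real data users
   supply their own labels) and the 180–250 ms window.

The pipeline is linear in the data, so scaling epochs scales the measure;
with zero noise the synthetic generator's injected bump (Gaussian, center
215 ms, SD 20 ms) is recovered exactly at the grid mean of its generating
function.

**Split-half reliability** splits each subject's trials into odd/even
halves within each condition, runs the full derivation per half (including
a per-half median split), correlates halves across subjects, and applies
Spearman–Brown $2r/(1+r)$.  Odd/even with Spearman–Brown is a choice —
the scheme is rarely stated in ERP reports — and it anchors correctly:
duplicated halves give 1, pure noise gives ≈ 0, and reliability rises
monotonically with between-subject signal variance at fixed sensor noise.

# The synthetic cohort generator

Two modes, both multivariate normal:

* **Correlation mode** draws from a target correlation matrix (after
  nearest-positive-definite repair by eigenvalue clipping at $10^{-6}$ and
  rescaling — applied loudly via a message, refused when the most negative
  eigenvalue is below −0.05).  The built-in preset encodes the printed
  11-variable intercorrelation structure of a longitudinal ADHD-risk
  cohort plus mother's education; that matrix is already positive definite
  (smallest eigenvalue 0.22), so the preset is used verbatim.  Only the
  education–N2 correlation (−0.25) is empirically anchored among the
  education entries; the rest default to zero as a modelling choice.
* **Path mode** builds variables in topological order, each endogenous
  variable a stated linear combination of standardized parents plus a
  Gaussian disturbance scaled to unit total variance, so population
  standardized path coefficients equal the specification exactly and
  refitting the same structure on a large cohort recovers them.  Cyclic
  specifications and over-determined coefficient sets (implied disturbance
  variance ≤ 0) are rejected.

The preset path models place the two early precursors and mother's
education as uncorrelated exogenous variables, with direct paths to the
adolescent N2 of −0.33 (effortful control) and 0.35 (paternal
inattention) — or −0.29 for the attentional-focusing subscale variant —
and the education path at −0.25.  The precursor → inattention paths
(−0.34 and 0.12) follow from the preset correlation structure by
closed-form standardized regression, and the inattention → N2 path is
fixed at 0.10: the source analyses report that path as non-significant
without printing it, and 0.10 is a magnitude undetectable at the original
sample size while keeping the mediation chain alive for indirect-effect
testing.  Recovery of the calibrated direct paths does not depend on
these two filled-in values, because least-squares refitting is consistent
whatever the generating coefficients are.

Marginals are Gaussian, rescaled to the printed means/SDs (N2 mean −0.12,
SD 2.06 µV; SSRT 159.90, 56.29 ms; symptom T-scores; and so on) when
requested; downstream analyses standardize anyway.  Missingness is MCAR
only — each cell masked independently at its variable's rate (presets: 3%
paternal symptoms, 10% early temperament) — because that is the mechanism
the emulated studies report.  What the generator does *not* emulate:
non-Gaussian questionnaire marginals, item-level structure, MAR/MNAR
mechanisms, EEG artifacts or preprocessing (epochs are emitted clean and
baseline-ready), non-stationary or spatially correlated sensor noise.
Passing tests therefore demonstrate correctness of the estimators under
the stated statistical model, not robustness to real-data pathologies.

The per-subject epoch generator injects the N2 bump on ROI channels of
successful-stop trials only, on top of a go-locked template common to all
trials (so the difference wave cancels it), with trial counts defaulting
to 35 successful-stop and 144 go — typical post-artifact-rejection counts
for a three-block session.  In full pipeline runs each subject's injected
amplitude is the cohort's latent N2 rescaled to microvolts (mean −0.12,
SD 2.06), so ERP derivation and cohort statistics compose.

# The inferential chain

**Hierarchical regression** standardizes all variables and enters
predictor blocks cumulatively (education first, then both symptom domains
together, so the overlapping domains partial each other out).
Coefficients are standardized betas; each step reports $R^2$, adjusted
$R^2$, and the $\Delta R^2$ F-test.  Rank-deficient blocks raise an error
naming the collinear columns.

**Quartile ANCOVA** cuts the grouping variable at sample quartiles with
boundary ties going to the lower group (the emulated analyses report
unequal group sizes, confirming data-driven cuts, but not their tie
rule), fits `outcome ~ covariate + quartile`, and reports the omnibus
group test (covariate partialled first) plus the planned
lowest-quartile-versus-rest contrast on the same error term, both with
partial eta squared $SS_e/(SS_e + SS_{err})$.  Both are verified against
a brute-force projection decomposition in the tests.

**Path analysis** estimates each endogenous equation of the recursive
model by least squares on standardized variables.  The original analyses
used a full SEM engine; for a recursive observed-variable model with
uncorrelated disturbances the per-equation estimates coincide with ML in
population, and the tests confirm closed-form equivalence with
partial-regression solutions from the correlation matrix.  Indirect
effects are products along every directed chain, with first-order delta
(Sobel) standard errors; the Sobel SE agrees with a nonparametric
bootstrap within 10% at large n, and its 95% intervals cover the true
product at nominal rate in the coverage suite.  Global fit compares the
sample correlation matrix $S$ with the model-implied matrix $\Sigma$
(built by path tracing with the exogenous block free at its sample
values):

$$\chi^2 = (n-1)\left[\log|\Sigma| - \log|S| +
\mathrm{tr}(S\Sigma^{-1}) - p\right],$$

with $df = p(p+1)/2 - (\text{paths} + \text{disturbances} +
\text{exogenous moments})$; CFI against the independence baseline; RMSEA
$= \sqrt{\max(0, \chi^2 - df)/(df\,(n-1))}$ (zero when $df = 0$); SRMR as
the RMS residual correlation over the lower triangle.  A saturated model
yields exactly $\chi^2 = 0$, CFI 1, RMSEA 0, SRMR 0 because OLS
reproduces every moment.  GFI is not reported: it depends on estimator
internals that per-equation least squares does not share.

**Multiple imputation** assumes joint normality: per imputation, the mean
and covariance are re-estimated from a bootstrap resample of the complete
cases (propagating parameter uncertainty, the "proper" ingredient),
missing cells are drawn from their conditional normal, and Rubin's rules
pool the per-imputation estimates: $T = W + (1 + 1/m)B$ with
normal-reference degrees of freedom (no small-sample refinement).  The
default $m = 20$.  With no missing cells the machinery degenerates to the
complete-data analysis with $B = 0$.

**Conventions.** One-tailed p-values are reported alongside two-tailed
ones as half the two-tailed p in the direction of the estimate (a
directional-hypothesis convention); `one_tailed_p()` handles the
wrong-sign case.  No multiple-testing correction is applied, matching the
reporting style of the emulated analyses; significance marks use the
`+/*/**/***` ladder.

# The orchestrated study

`run_full_pipeline()` composes everything: latent cohort → per-subject
SST session whose constant stop latency is an affine map of the latent
inhibition trait (default 160 ± 30 ms per latent SD) → race-model
screening and integration-method SSRT → per-subject epochs whose injected
N2 is the mapped latent trait → N2 derivation → the configured regression
and path analyses, pooled over imputations when missingness is present.
Stage seeds are drawn deterministically from the master seed (so stages
can be re-run in isolation), subject seeds follow a fixed affine scheme,
and the manifest records seeds, exclusions with reasons, and an md5 hash
over the per-subject results; identical configurations reproduce
identical hashes.

# Numerical choices and problem sizes

Ex-Gaussian draws are truncated below at zero (the mass there is
negligible for all realistic parameters).  Nearest-PD repair clips at
$10^{-6}$ and refuses shifts beyond 0.05.  The package's verification
suites use problem sizes chosen to put Monte-Carlo error well inside each
tolerance: correlation-structure recovery at $n = 100{,}000$ (sampling SD
of r ≈ 0.003 against a ±0.02 band), path and regression recovery at
$n = 50{,}000$ (SE ≈ 0.004 against ±0.03), SSRT latency recovery over
≥ 5,000 tracked stop trials (±10 ms band), and split-half null behavior
at 200 subjects.  The latency-recovery check runs under a light-tailed go
law (500, 50, 100 ms) with omissions disabled so that deadline censoring
— a genuine bias of max-RT replacement, discussed above — does not
contaminate a check whose purpose is the estimator's arithmetic.

# Known limitations

Everything is Gaussian and MCAR; the race is fully independent (no
dependent or interactive race variants, no trigger-failure *estimation* —
trigger failures can be simulated but not recovered); the imputation
engine is joint-normal rather than chained equations; fit indices are
computed from correlation rather than covariance structure (appropriate
here because every analysis standardizes); and the ERP stage neither
ingests real EEG formats nor models preprocessing.  These boundaries are
deliberate: the package's claim is correctness of the estimation chain
under its stated model, demonstrated by oracle tests, not general-purpose
EEG or SEM tooling.
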
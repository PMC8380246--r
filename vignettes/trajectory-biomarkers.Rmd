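---
title: "Trajectory-based discovery of treatment-emergent expression markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-based discovery of treatment-emergent expression markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnatraj)
```

## Scope and model overview

`rnatraj` identifies RNAs whose *change* in peripheral expression during an
8-week antidepressant trial tracks clinical response, rather than predicting
it at baseline. The pipeline chains five pieces: response-trajectory
classification from the MADRS panel, a three-criterion RNA screening funnel,
per-RNA linear latent growth models, a three-step logistic/multinomial
association analysis, and the supporting group-comparison and qPCR
statistics. Everything operates on plain tables (tibbles in, tibbles out),
and a synthetic-cohort generator supplies data with the statistical
structure the analysis assumes, so every stage is testable end to end
without access to the original trial.

## Response classification

Response is a ratio rule: ΔMADRS = MADRS(T8)/MADRS(T0), response iff
ΔMADRS ≤ 0.5. We treat the boundary as inclusive — "a 50% reduction"
includes the exact-50% case. Early responders additionally satisfy the rule
at week 2. Nonresponders are descriptively subtyped *flat* versus *relapse*;
the published description of the relapsing shape is qualitative, so we
operationalise it as: the MADRS minimum occurs before week 8 and the score
then rises by more than 20% of baseline. The subtype never enters the
association models — the two nonresponse groups are merged there, as in the
original analysis.

Rule-based labels, not cluster assignments, define the analysis groups;
longitudinal k-means with Calinski–Harabasz model selection is provided to
*describe* the trajectory structure and check concordance. Restart
initialisation is seeded and deterministic; an empty-cluster restart is
discarded rather than re-seeded, and a candidate k for which no restart
yields k nonempty clusters is skipped with a warning (this only occurs for
degenerate inputs such as exactly duplicated trajectories).

## Screening funnel

The funnel applies, in order: (1) baseline patient-vs-control differential
expression at BH FDR ≤ 0.20; (2) exclusion of genes with missing counts at
T0 or T8; (3) Pearson correlation of week-8 expression with ΔMADRS at
p < 0.05; (4) exclusion of genes whose *baseline* expression correlates with
ΔMADRS at p < 0.2. Stage (4) deliberately discards predictors: the target
is mediation, and under the null a truly uncorrelated gene survives it with
probability 0.8, so funnel recall for true markers is bounded near 80% by
construction.

The wording "must show a correlation with the change in MADRS at T8" leaves
the expression variable ambiguous (T8 level, T0→T8 change, or pooled); we
default to the T8 level and expose `criterion2_variable = "delta"` as the
alternative in `pipeline_config()`.

The differential-expression engine is a per-gene negative-binomial Wald GLM
(log link, size-factor offset, dispersion α with variance μ + αμ² estimated
by alternating profile maximum likelihood) on median-of-ratios-normalized
counts. It is intentionally a plain NB Wald test: no empirical-Bayes
dispersion shrinkage, no fold-change shrinkage, no independent filtering —
the funnel, not the DE engine, is the contribution here, and bit-level
agreement with any particular DE package is a non-goal. Genes whose
dispersion estimate diverges to zero are refit as Poisson (the NB limit);
all-zero genes are flagged with p = 1 rather than dropped. The test itself
takes only group labels and size factors; age, sex and RIN are
instead removed from the log2 expression by per-timepoint OLS
residualization (`residualize()`), refit per timepoint because pooling
across visits would let the covariate fit absorb time trends.

The log2 transform uses a configurable pseudocount (default 1), applied
after depth division: `log2(count/s_j + 1)`.

## Latent growth model

Each selected RNA's three-timepoint adjusted expression is fit by maximum
likelihood to the two-factor linear growth model with loadings fixed at the
measurement weeks (0, 2, 8): implied mean Λ(μ_i, μ_s)′ and covariance
ΛΨΛ′ + Θ, Θ diagonal and free per timepoint. With 9 observed moments and 8
free parameters the model has one degree of freedom, so the χ² test the fit
indices need is defined. The discrepancy

F_ML = ln|Σ| − ln|S| + tr(SΣ⁻¹) − 3 + (ȳ−μ)′Σ⁻¹(ȳ−μ)

is minimised by `nlminb` with an analytic gradient from a method-of-moments
start (per-subject OLS intercepts/slopes); Ψ is parameterised through its
Cholesky factor so it stays positive semidefinite, and Θ through log
variances. Convergence is declared at relative tolerance 1e-10 (500
iterations cap) or a gradient max-norm below 1e-5. The test statistic uses
the Wishart convention T = (n−1)·F_ML with the unbiased S;
`chisq_scale = "n"` switches to the normal-theory n·F_ML convention, since
the convention of the original software is not documented.

CFI, TLI, GFI, RMSEA and SRMR follow their standard definitions (SRMR over
the six unique covariance residuals only; a variant including mean
residuals would add two saturated terms and is omitted). The published
good-fit thresholds ">0.90" and "<0.8" (the latter almost certainly a typo
for <0.08) are not enforced — indices are reported and thresholds left to
the user. Factor scores use the regression method; the association results
are invariant to rescaling the slope loading column because the slope is
standardized before modelling. Exactly noise-free data have a singular
3×3 sample covariance and are rejected with an informative error; the Θ→0
behaviour is exercised in the tests with vanishingly small noise instead.

A genuinely open design point: the original description ("intercept and
slope parameters as predictors") is compatible with either a two-step
factor-score export or a one-step structural model. We implement the
two-step reading; it keeps each RNA's measurement model independent of the
outcome model and matches the per-SD-slope risk-ratio reporting.

## Three-step association

Step 1 fits, per RNA, responder ~ intercept score + standardized slope and
advances RNAs with slope Wald p < 0.05 (the intercept p is reported but not
gating). Step 2 fits one binary logistic model with all advancing RNAs'
standardized slopes plus age, sex (female = 1), anxiety history and
suicidality. Step 3 fits the analogous multinomial model
(early/later/nonresponder, base nonresponder) by full Newton–Raphson with
step-halving — the log-likelihood is concave, so iterations are monotone —
with standard errors from the inverse observed information. Joint models
include slopes only (intercepts are screened but not carried), matching the
published table that reports slope RRs alone. BH FDR is applied across
(advancing RNAs × 3 contrasts); re-deriving the published FDR column
requires family size 24 (8 RNAs × 3 contrasts), which is how we infer the
family definition. Quasi-separation is detected from degenerate fitted
probabilities and flagged; affected RNAs are excluded from advancement with
the flag visible in the step-1 table.

## Synthetic cohort: what it emulates and what it does not

Defaults are fixed once as the study conditions:

* **Cohort**: 153 patients / 104 controls; class proportions
  0.229/0.320/0.301/0.150 (early, later, flat-NR, relapse-NR), the published
  trajectory-group shares.
* **MADRS class means** (weeks 0–8): early (30,13,10,8,6), later
  (30,22,16,12,9), flat (30,29,28,29,28), relapse (30,15,13,18,26). No
  numeric curves are published; these reproduce the published qualitative
  shapes (early halving by week 2; later halving only by week 8; flat within
  15% of baseline; relapse dipping like early responders then rebounding)
  and are parameters, not ground truth. Noise sd 3 MADRS points reflects
  visit-to-visit variability while keeping rule-based labels mostly faithful
  to the latent class; draws are rounded, clamped to [0, 60], and week 0 is
  clamped at the inclusion threshold 21.
* **Counts**: NB with variance μ + αμ², α ~ U(0.05, 0.2) (typical bulk
  RNA-seq), baselines U(3, 9) on log2, log-normal size factors (sd 0.25),
  small per-gene age/sex/RIN coefficients, and subject-level random
  intercepts (sd 0.5 log2) and slopes (sd 0.1 log2/week). The random effects
  are the biological between-subject heterogeneity the growth model's Ψ
  estimates; they are sized so Ψ is comfortably identified at cohort n —
  with much smaller latent variance the ML solution sits on the PSD boundary
  for a nontrivial share of genes, making factor scores collinear, which is
  a property of the model, not a bug in the data.
* **Markers**: baseline case-control shift ±0.5 log2 at every patient
  timepoint (criterion 1 satisfiable), responder-class slope ±0.1 log2/week
  with zero class effect at week 0 (criterion 3 satisfiable), signs
  alternating. At these settings the fitted per-SD slope log-RR lands near
  0.7–0.9, the magnitude of the published risk ratios.

Not emulated: batch effects beyond size factors and RIN, count missingness,
dropout/incomplete visits (the analysis set is complete-case by design),
library-preparation artefacts, and gene-gene correlation beyond the shared
subject effects. Passing tests therefore demonstrate statistical
correctness of the machinery under the assumed structure, not robustness to
real-data pathologies.

## Numerical choices and degenerate inputs

* Median-of-ratios factors require at least one gene positive in all
  samples; otherwise the error suggests filtering. Factors are defined up to
  a common scale; only ratios matter downstream.
* `bh_adjust` validates [0, 1] and delegates to the standard step-up; note
  BH adjustment is *not* idempotent (re-adjusting adjusted values changes
  them), so adjusted values are computed exactly once per family.
* The multinomial Newton solver applies Levenberg-style damping if the
  observed information is numerically singular and flags separation when
  coefficients diverge.
* Calinski–Harabasz returns `Inf` for a partition with zero within-cluster
  variance.
* k-means ties and empty-cluster handling are delegated to the standard
  Lloyd implementation; determinism comes from the seeded restart stream.

## Study sizes used in the checks

The simulation studies bundled with the package (`study_lgm_recovery`,
`study_null_funnel`, `study_power`) use n = 5000 × 10 seeds for parameter
recovery, 150 patients × 2000 genes × 3 seeds for the null operating
characteristics, and 1000 patients × 5 seeds with 4 markers among 32
candidates (from a 500-gene normalization universe) for end-to-end power.
These sizes give Monte-Carlo error small enough for the bounds they are
checked against while completing in minutes on a single core. The power
study simulates a marker-poor universe because median-of-ratios
normalization over only 32 genes, 4 of them truly changing, leaks marker
signal into every null gene's normalized values — a small-panel artefact the
genome-wide original analysis does not have.

## Known limitations

* Three timepoints support only linear growth; quadratic or piecewise
  change is out of scope, as is FIML for missing data.
* The NB Wald test is slightly anticonservative (~6% at nominal 5%) under
  the generator's log-normal between-subject heterogeneity, which is
  NB-misspecified; this is inherent to the plain Wald test and within the
  tolerance the operating-characteristic checks assert.
* The step-1 advancement filter makes the final BH family
  selection-conditioned, so the false-discovery behaviour among advancing
  null RNAs is worse than the nominal 5% would suggest; the power study
  reports false positives per seed for exactly this reason.
* Expression enters the funnel's correlation stages as the covariate-
  adjusted T8 level by default; the pooled-timepoints alternative is not
  implemented.
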
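---
title: "Methods: vote-counting panel discovery, harmonized evaluation, and benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vote-counting panel discovery, harmonized evaluation, and benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PanelVote)
```

# The problem and the model

CSF proteomic signatures for Alzheimer's disease are typically discovered
by optimizing classification performance inside a single cohort. Such
panels inherit that cohort's platform, diagnostic definition and sampling
quirks, and frequently degrade elsewhere. PanelVote implements the
opposite prioritization: a protein enters a panel only if it is
differentially abundant **in at least two independent studies, in the same
direction**, and is measurable in every validation cohort. Reproducibility
across studies — not within-cohort fit — is the error control.

The statistical model underlying every stage is deliberately plain.
Abundances are analyzed on the log2 scale, where platform effects are
approximately affine and group differences approximately additive.
Diagnostic scoring is a linear model (ridge-penalized logistic regression)
on within-cohort z-scores; prognosis is a proportional-hazards model on a
median split of the panel score. Nothing in the pipeline estimates more
than first- and second-moment structure, which is what keeps it portable
across platforms.

# Preprocessing and harmonization

The pipeline order is fixed and logged in each object's provenance:
missingness filter → quantile normalization → log2 transform → optional
batch centering → z-score.

* **Missingness** (`filterMissingness`): proteins missing in strictly more
  than 80% of subjects are dropped. The boundary is kept: "more than 80%"
  is read literally, so a protein missing in exactly 8 of 10 subjects
  survives. One flag moves the threshold.
* **Quantile normalization** (`quantileNormalize`): the reference at each
  rank is the across-column mean of the available order statistics;
  missing entries never enter the reference and stay missing; tied input
  values receive the mean of the reference values they span. When columns
  have unequal observed counts the reference is evaluated at each column's
  quantiles by linear interpolation; with equal counts the procedure is
  exact and all columns share one sorted multiset. This rule is
  implemented in-package because installed implementations interpolate
  missing entries instead of excluding them; on complete data the two
  agree to machine precision (cross-checked against limma in the tests).
* **log2 transform**: requires strictly positive values; a pseudocount is
  available but defaults to 0 so silent shrinkage cannot occur.
* **z-scoring** (`zscoreStandardize`): per protein, within cohort, n−1
  standard deviation. Within-cohort scope is a design decision:
  harmonization should equalize cohorts, and pooling before standardizing
  would leak cohort composition into the scale. Zero-variance proteins are
  an error, not a silent drop — the caller decides. The stage is
  idempotent to 1e-9, so re-running a pipeline on its own output is safe.
* **Batch centering** (`batchCenter`): per-protein median subtraction per
  batch. This is intentionally the simplest adjustment that removes
  additive batch offsets; no empirical-Bayes pooling across proteins is
  attempted, because the evaluation stages operate on z-scores where
  location effects dominate.

A/T classification (`classifyATStatus`) applies CSF ratio rules with
**strict** inequalities: a subject exactly at p-Tau181/Aβ42 = 0.023 is
negative. Boundary handling is not dictated by the underlying assay
literature, so strictness was chosen once and applied everywhere;
classification is total on complete inputs (pos or neg, never unknown).

# The discovery funnel

Per study, `differentialAbundance` computes log2 FC = mean(case) −
mean(control) and a **two-sided Welch t-test** on observed values. Welch
(unequal variances) was chosen because case and control arms in CSF
studies rarely share dispersion; the equal-variance variant is a trivial
substitution but is not exposed, to keep the funnel's definition single.
Groups with fewer than three observed values are skipped with a warning —
three per arm is also the generator's floor, mirroring the inclusion
criterion of the compiled studies. No multiple-testing correction is
applied at this stage: the per-study filter (|log2 FC| ≥ 0.6 **inclusive**,
*p* < 0.05 **strict**) is deliberately liberal, and cross-study
reproducibility is the error control that follows.

`voteCount` matches studies by gene symbol (the only identifier shared
across LC-MS/MS, aptamer and PEA platforms). A study with several analytes
for one symbol contributes a single sign, taken from its largest-|FC|
record — deterministic and consistent with the highest-variance analyte
collapse used at the matrix level. `concordantDirection` then requires all
per-study signs to agree, and `coverageFilter` keeps candidates measured
in every validation matrix ("measured" = retained after the missingness
filter; a detection-completeness threshold would be an alternative reading
but is not implemented).

The final down-selection (`downSelectPanel`) is **greedy forward selection
by univariate CV-AUC ranking** with alphabetical tie-breaks: candidates are
added in rank order and the smallest prefix within ε = 0.002 of the best
prefix AUC wins. The search strategy in the source analyses is not
recoverable (forward, backward and exhaustive searches are all consistent
with "inclusion of additional candidates did not improve accuracy"), so
the greedy variant was chosen for determinism and a fully loggable trace;
the trace (ranking plus every prefix AUC) is stored in the returned
signature's notes. All prefixes are scored on identical fold assignments.

# Diagnostic evaluation

`rocAuc` computes AUC by the Mann–Whitney identity (mid-ranks, ties ½);
the test suite holds it equal to a brute-force pairwise concordance count.
Operating points use Youden's J with ties broken toward higher
specificity — when two cut-offs discriminate equally, the conservative
(fewer false positives) one is reported.

Confidence intervals default to **DeLong's method** (the standard of the
ROC tooling used across this literature); a percentile bootstrap (2000
stratified resamples, seeded) is available by flag. Degenerate cases
(AUC = 1 with no ties) collapse to a point interval with a warning rather
than fabricating width.

Two regimes mirror how multi-platform validation is actually done:

* `repeatedCvAuc` — stratified 5-fold CV, 10 repetitions, folds
  re-randomized per repeat from a single integer seed. The reported AUC is
  the **mean of per-repeat pooled AUCs**; the aggregation rule is not
  dictated by the problem, so both that mean and the DeLong interval on
  per-subject mean out-of-fold scores are emitted (plus the across-repeat
  dispersion interval), making either convention recoverable.
* `externalValidation` — a frozen `fitPanelModel` fit scores an
  independently z-scored test cohort; labels enter only at the metric
  stage, so test-set refitting is structurally impossible.

Logistic fits carry a small ridge (1e-3 on standardized inputs, intercept
unpenalized). This is a documented deviation from plain maximum
likelihood: it guarantees existence and determinism under complete
separation, which planted synthetic panels and some real panels do
produce. The penalty is implemented as an internal IRLS routine because no
installed package offers exactly this fixed-penalty form (glmnet's
objective is n-scaled with internal standardization); at ridge → 0 it
matches `glm` to 1e-4 in the tests. Proteins absent from an evaluation
cohort contribute 0 — the z-scale mean — and the covered fraction is
always reported, mirroring per-cohort coverage bookkeeping.

`pcaManova` runs PCA on complete proteins and a one-way MANOVA (Pillai's
trace, standard F approximation) on the leading components. With one
component it reduces to the between/total sum-of-squares ratio, which the
tests verify directly; under the null its p-values are uniform across
seeds.

# Prognostic evaluation

Panel scores for survival stratification default to the **mean
direction-aligned z-score** (`meanZScore`) when no trained model exists,
and to the model's linear predictor when one does; "median protein level"
stratification is ambiguous between the two, so both are implemented and
the mode is explicit in the call. `medianStratify` sends ties at the
median to the low group, keeping "high" strictly above the median; the
split is computed within the analysis subset (not the full cohort).

`coxFit` wraps the survival package: Breslow ties by default (simplest and
deterministic; Efron by flag), age and sex always available as covariates,
Wald two-sided p-values, CI = exp(coef ± 1.96 SE). Monotone likelihoods
(all events in one group) warn and fall back to a ridge-penalized fit.
`buildTransitionDataset` derives records from visit histories: origin
state at baseline, ≥ 2 visits, follow-up within 0.5–12.5 years, event at
the first qualifying destination visit, censoring at the last visit
(study-end censoring is the unimplemented alternative; last-visit was
chosen because visit schedules are irregular). Non-monotone clinical
sequences — reversions after a qualifying event — are kept with the first
event and a warning, since excluding them would bias toward smooth
decliners.

# Clinical association

`clinicalAssociation` fits, per protein × variable, OLS of log2 abundance
on the variable plus age and sex, on complete cases, with BH correction
**per variable across proteins**. The family definition follows the
per-column significance marking of association heatmaps; a per-protein
family would answer a different question (which variables does this
protein track) and is not what the cross-protein comparison needs.
Moderated statistics (limma's empirical-Bayes variance pooling) sit behind
`moderate = TRUE` with default settings, because the exact moderation
configuration of the source workflow is unspecified; betas are identical
either way, only standard errors shrink. `scaleEffects` multiplies by
sd(variable)/sd(protein), giving unitless effects that reduce to the
Pearson correlation in the bivariate no-covariate case.

# Benchmarking

`runBenchmark` holds everything constant across signatures: within a
cohort, the fold seed derives from the master seed and the **cohort name
only**, so every signature sees identical folds; ridge, k, repeats and
thresholds are shared; published panels are refit per cohort as unweighted
gene lists (original coefficients are platform-bound and mostly
unpublished). Zero-coverage cells are explicit non-evaluable rows with a
reason, never silent skips. The packaged registry transcribes fourteen
signatures verbatim (one obvious typo in a missing-protein cell, DDHA1,
is recorded as DDAH1 in the registry notes; the Liu panel's AT1B1 is kept
verbatim although it is presumably ATP1B1).

# The synthetic-data generator

`simulateCohort` draws log2 abundances as Normal(baseline + group·effect,
noise_sd), applies platform gain/offset, and masks per-protein
completely-at-random missingness with Beta-distributed rates. Defaults —
30 subjects per arm, planted effects of 1 log2 unit (floor 0.6, the DAP
filter boundary), noise 0.4, ~5% missingness — represent a moderately
powered discovery study. `simulateMultiStudy` plants one shared marker set
across studies, flips each marker's sign in one random study with
probability 1 − concordance (exercising the concordance filter), and keeps
study-specific hits disjoint. `simulateProgressionCohort` uses exponential
event times (closed-form hazard control) with uniform administrative
censoring on 0.5–12.5 years.

What the generator does **not** model: informative missingness (no
mechanism is documented for the real cohorts), protein–protein correlation
beyond the shared group effect, heavy-tailed abundance noise, and
platform-specific mean–variance relationships. Passing tests therefore
demonstrate correctness of the algorithms and calibration under the
Gaussian-additive model — not that any particular real cohort satisfies
that model. Conversely, because the planted truth is known exactly, the
suite can assert quantitative guarantees real data never afford: ≥ 90%
recovery of planted shared markers with ≤ 10% false candidates over 20
seeds on 8 studies, Cox CI coverage of 95% ± 3% over 500 replicates, and
null AUCs at chance.

# Numerical choices and degenerate inputs

* Seeds: every stochastic stage takes `deriveSeed(master, stage_name)`, a
  31-bit polynomial string hash — stable across platforms, documented so
  an independent implementation can reproduce the *scheme* (stream values
  are RNG-specific). Generators save and restore the caller's RNG state.
* Matrix round trips serialize at 15 significant digits (element-wise
  reproduction well within 1e-9).
* Missing-value tokens on input are exactly `""`, `"NA"`, `"NaN"`, `"na"`;
  anything else non-numeric is an error with the protein/subject location.
* Errors, not guesses, for: duplicate identifiers (unless collapse is
  requested), zero-variance proteins at z-scoring, zero A/T denominators,
  single-class training labels, all-identical scores at median split,
  zero events in survival data, requested variables absent from the
  clinical table.
* Problem sizes in tests and the acceptance script (e.g. 150–200 protein
  universes, 30–100 subjects per arm, 500 coverage replicates) were chosen
  as the smallest sizes at which the asserted rates are stable over
  seeds.

# Known limitations

* The funnel's published stage counts on the original compiled database
  cannot be reproduced here: the compiled per-study DAP tables and the
  real cohort matrices are controlled-access or supplementary deposits.
  The funnel's set semantics are instead verified exactly against
  brute-force oracles on constructed databases.
* Batch correction is additive-median only; latent-factor or
  empirical-Bayes correction is out of scope.
* Survival modeling excludes time-varying covariates, competing risks and
  interval censoring; visit-based event times are interval-censored in
  reality and treated as exact.
* Gene-symbol matching is the only cross-platform key; isoform- or
  analyte-level disagreements are resolved by the highest-variance rule,
  which keeps information but can pick different analytes in different
  cohorts.
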
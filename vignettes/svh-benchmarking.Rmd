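---
title: "Benchmarking automated SvH scoring: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking automated SvH scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svhbench)
```

## The problem

Rheumatoid arthritis erodes bone and narrows joint spaces; the
Sharp–van der Heijde (SvH) method quantifies that damage from plain
radiographs of the hands, wrists and feet. Expert scoring is slow and
requires training, so a natural benchmarking task is: given a cohort of
radiographic sets with expert ("ground truth") SvH scores, how close do
automated methods come, and which differences between methods are real?
`svhbench` implements the evaluation side of that task. It deliberately
contains no image handling: its unit of data is the score sheet.

## The score model

`svhRegistry()` enumerates the scored locations: per side, 15 hand/wrist
and 6 foot areas for joint space narrowing (JSN, 0–4 each), 16 hand/wrist
erosion areas (0–5 each) and 6 foot erosion joints (0–10 each; the two
sides of a foot joint are scored together and pre-summed, which is what
makes a 188-patient cohort carry 188 × 44 = 8272 erosion scores). The caps
sum to 448. Two modelling notes:

* The scheme's cardinalities and caps are the only load-bearing facts for
  every metric in the package; the anatomical names (`mcp2`, `lunate`,
  `mtp1`, ...) are registry configuration. We ship the standard
  enumeration, and the CSV column dialect
  `{LH|RH|LF|RF}_{name}__{J|E}` is our own documented convention — scoring
  templates in the wild differ and none is canonical.
* Ground truth is integer-valued and range-checked (`validateScores()`
  reports every violation rather than failing fast); submissions are
  continuous, finite and non-negative, because regression-style models
  emit fractional scores. Patient-level sub-totals in a submission are
  treated as the team's own overall-damage predictions (stored, not
  recomputed), which is why the CSV reader cross-checks them only to a
  configurable tolerance for submissions while requiring exact agreement
  for truth sheets.

## The metric

All three subchallenges score a submission with a patient-weighted RMSE of
log-transformed scores,

$$\mathrm{RMSE}_w \;=\; \sqrt{\frac{\sum_i w_i\, d_i^2}{\sum_i w_i}},
\qquad d_i = \ln(1+y_i) - \ln(1+s_i),$$

with one term per patient on overall totals (sc1), or one term per JSN /
erosion location (sc2 / sc3), each term carrying its patient's weight. The
+1 inside the logs keeps healthy joints (score 0) finite. The normalizer
$\sum w$ makes the statistic a weighted mean of squared residuals, so it is
invariant under rescaling all weights — the property the tests check by
duplicating a cohort.

Weights come from an 8-bin scheme on the ground-truth overall total
(`weightBins()`):

```{r}
weightBins()
```

Thresholds are natural logs of the bin upper limits — forced, since the
printed thresholds 1.1, 1.95, 3, 4, 5 equal ln 3, ln 7, ln 20, ln 55,
ln 148 — with exceptions for the two degenerate bins (0 and 1) and the
open-ended bin (6). The weight is $2^{\text{threshold}}$, rising from 1 for
an undamaged patient to 64 for totals above 148: heavy damage counts more,
but far less than the raw 0–448 scale would imply. Choices made where the
scheme's prose was ambiguous:

* Bins are assigned from the **ground truth**, never from predictions, so
  all teams are weighted identically — anything else would let a team
  influence its own weights.
* "Equal-weighted data sets" is implemented as weighting only, not as
  balanced subsampling of patients; the weighted mean already equalizes
  bin influence in expectation and keeps the metric deterministic.
* Real-valued totals (ensembles, validation means) are bucketed by the
  integer range containing their floor — the half-open convention
  $[\text{lower}, \text{upper}+1)$ — so bin assignment is total on the
  non-negative reals.
* Per-joint terms are pooled directly (not averaged within patient first):
  the comparison unit is the joint score itself.

## Ranking and statistical ties

`bootstrapMetrics()` resamples radiographic sets (patient rows) with
replacement at full cohort size — B = 1000 by default — and scores every
team on the same resample. Because the metric decomposes into per-patient
sums and a patient's weight depends only on its own truth total, each
iteration is computed exactly from per-patient sufficient statistics; the
tests verify rows against a literal re-scoring of the resampled cohort.
Resample indices are stored for audit, and a supplied index matrix bypasses
the RNG (the hook the determinism tests use).

`bayesFactor()` compares each team with a reference: K = (iterations the
reference is strictly better) / (iterations the team is strictly better).
Iterations where the metrics tie exactly are excluded from both counts,
which keeps K symmetric under swapping the roles (K ↔ 1/K). K > 3 is a
real difference ("greater than 3" is the win rule, so K = 3 exactly is a
tie); when both counts are zero — identical metric vectors, e.g. the
reference against itself — we report K = 1 and classify it tied, since the
resamples contain no evidence either way. `pairwiseTFdr()` supplies the
secondary comparison: paired t tests on the bootstrap vectors with
Benjamini–Hochberg correction across teams; a zero-variance difference
vector is reported as degenerate with p = 1 rather than an error, so a
cloned submission cannot crash a leaderboard run. Full-cohort ranking
breaks exact metric ties lexicographically by team id — arbitrary but
deterministic and documented.

## Ensembles

`meanEnsemble()` averages raw predicted scores cell-wise (the log transform
belongs to the metric, not the data); patient-level sub-totals are averaged
from the members' stored sub-totals. `ensembleSeries()` evaluates the top
performer alone, the top 2, the top 3, ..., sharing one set of bootstrap
resamples across all ensembles and the top individual so Bayes-factor
comparisons are variance-paired. With k comparably good members whose
log-scale errors are independent with SD σ, the ensemble's log-residual SD
contracts like σ/√k (Jensen-type distortions from averaging on the raw
scale are O(σ²) and negligible at the σ ≈ 0.3 the tests use); a
decorrelated, individually worse team can still improve the ensemble, and
the test suite constructs exactly that configuration (three teams with
error correlation 0.8 plus one independent team with 1.5× their error SD).

## The synthetic-data generator

The generator targets the qualitative shape of real SvH cohorts, not any
particular study's printed medians:

* **Cohorts** (`generateCohort()`): with probability `zero_inflation`
  (default 0.10) a patient has no damage at all; otherwise a log-normal
  latent severity L (defaults meanlog = ln 15, sdlog = 1.3) drives
  beta-binomial scores per joint area with mean
  `max_score * min(1, L/448)`, so E[total | L] ≈ L. The defaults give a
  median total near 15 with quartiles roughly 6–36 and rare totals of
  several hundred — zero-inflated, strongly right-skewed, spanning the
  scale, which is what damage distributions in RA cohorts look like.
  Per-joint dispersion (default 0.05) adds joint-to-joint heterogeneity.
* **Submissions** (`generateSubmission()`): per term,
  y = max(0, expm1(ln(1+s) + ε)) with
  ε = bias + σ(√(1−w)·z_team + √w·z_shared); w is the correlation weight
  with a cohort-level shared error field, so teams sharing `shared_seed`
  have log-scale error correlation w. σ is exactly the metric's residual
  SD — which is what makes planted noise orderings recoverable by
  construction. The clip at zero truncates large negative errors on
  zero-score joints; the error-statistics tests therefore measure on
  cohorts with scores ≥ 2, where the clipping probability is negligible,
  and the bias this introduces on zero-heavy cohorts is documented rather
  than corrected.
* **Readers** (`generateReaderPair()`): truth plus per-joint Gaussian noise
  on the raw score scale, rounded and clipped to the caps — two legal
  integer sheets whose mean plays the role of a validation ground truth.
  `readerCV()` summarizes their agreement as the per-patient pair CV
  (sample SD over mean), averaged over patients, excluding and counting
  all-zero pairs; that construction is our choice of a standard CV, made
  explicit because reader-agreement CVs are reported without formulas more
  often than not.

Everything is deterministic given its config: same seeds, byte-identical
CSVs. What the generator does **not** emulate: anatomical correlation
structure (wrist areas eroding together), longitudinal progression,
reader-specific systematic bias, or the image-quality differences that make
independent validation sets harder — so green simulation tests demonstrate
correctness of the machinery, not clinical performance of any algorithm.

## Numerical and degenerate-input choices

* Outlier screening (`flagOutliers()`) defaults to |y − s| ≥ 3 raw score
  units, fully parameterized; rates (`outlierRate()`) are rounded to one
  decimal, the precision such reviews report.
* Spearman metrics return NA with a warning on constant vectors instead of
  erroring; concordance requires ≥ 2 teams and counts ties as half.
* `runEvaluation()` skips a malformed submission file with a diagnostic
  and continues — a rolling leaderboard must not fall over on one bad
  upload. Its JSON manifest (config, seeds, version) is sufficient to
  reproduce every output file bit-exactly.
* Problem sizes in the test suite were chosen as the smallest that make
  the statistical assertions stable: oracle equivalence on 100 cohorts of
  2–5 patients at 1e-9; rank recovery with noise SDs 0.1/0.3/0.6 on 200
  patients, B = 1000, 20 replicates; ensemble contraction on 500 patients
  for k ∈ {2, 4, 9}.

## Limitations

The harness evaluates score sheets only; nothing here detects joints or
reads radiographs. The weighting scheme, tie rules and outlier default are
faithful to their published descriptions where those exist and are explicit
package choices where they do not (bin assignment on reals, bootstrap tie
exclusion, the CV construction, the CSV dialect). Headline numbers from any
particular challenge depend on private images and trained models and are
not reproducible from synthetic data; what is reproducible — and tested —
is the arithmetic of the scheme, the metric's definition, and the
statistical behaviour of the ranking and ensembling machinery under known
conditions.
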
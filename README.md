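# svhbench

Benchmarking machinery for algorithms that quantify radiographic joint
damage in rheumatoid arthritis (RA) against expert **Sharp–van der Heijde
(SvH)** scores.

Crowdsourced evaluations of automated SvH scoring need more than a single
error number: submissions must be scored on a common, validated score grid,
ranked with a metric that is robust to the extreme skew of damage scores,
separated from statistical ties by resampling, and probed for
wisdom-of-the-crowds gains from ensembling. `svhbench` packages that whole
evaluation flow, together with a synthetic-data module, so the machinery is
fully testable without access to any radiographs or private score sheets.

## The data model and the metric

The SvH method scores, per patient (one radiographic set = both hands/wrists
and both feet):

* **joint space narrowing (JSN)**: 15 hand/wrist + 6 foot areas per side,
  each 0–4 → 42 locations, 168 points;
* **erosion**: 16 hand/wrist areas per side (0–5) and 6 foot joints per side
  (0–10, both sides of the joint scored together) → 44 locations, 280
  points;

for a maximum overall total of **448**. `svhRegistry()` encodes this scheme
as a validated registry; `ScoreCohort` (integer ground truth) and
`SubmissionSet` (continuous predictions) live on its patient × joint-area
grid, with CSV serialization in a documented template.

Submissions are evaluated with a **patient-weighted log-RMSE**. Each
comparison term contributes

d&nbsp;=&nbsp;ln(1 + y) − ln(1 + s),

where s is the expert score and y the prediction (the +1 guards healthy,
zero-score joints), and the metric is

RMSE_w = √( Σ w·d² / Σ w ).

The weight w = 2^threshold comes from an 8-bin scheme over the patient's
ground-truth overall total (ranges 0, 1, 2–3, 4–7, 8–20, 21–55, 56–148,
>148; thresholds are natural logs of the bin upper limits, with exceptions
for the first two bins and the open-ended bin: 0, 1, 1.1, 1.95, 3, 4, 5, 6).
Three subchallenges share the formula and differ only in their comparison
units: overall damage per patient (sc1), every JSN location (sc2), every
erosion location (sc3).

On top of the metric sit:

* `bootstrapMetrics()` / `bayesFactor()` — patient-level bootstrap (1000
  iterations by default) and Bayes factors K against a reference team
  (K > 3 = genuinely different; K ≤ 3 = statistical tie), plus
  `pairwiseTFdr()` (FDR-corrected paired t tests) as the secondary
  comparison;
* `meanEnsemble()` / `ensembleSeries()` — cumulative top-k mean ensembles
  with Bayes-factor and Spearman evaluation;
* `concordanceIndex()`, `spearmanMetric()`, `flagOutliers()`,
  `outlierRate()`, `readerCV()` — cross-dataset and reader-agreement
  summaries;
* `generateCohort()`, `generateSubmission()`, `generateReaderPair()` —
  synthetic zero-inflated, right-skewed cohorts, noisy team submissions
  with controllable error SD / bias / between-team correlation, and paired
  expert readers;
* `runEvaluation()` / `makeDemo()` — end-to-end orchestration writing CSV
  artifacts plus a JSON manifest (also available as a thin CLI in
  `inst/scripts/svhbench.R`).

## Worked example

```r
library(svhbench)

truth <- generateCohort(cohortConfig(n_patients = 60, seed = 1))
truth
#> ScoreCohort: 60 patients x 86 joint areas
#> overall totals: median 15  range [ 0 , 333 ]

teams <- c(alpha = 0.1, beta = 0.3, gamma = 0.6)   # log-scale noise SDs
subs <- Map(function(id, sd)
  generateSubmission(truth, teamNoiseConfig(id, sd = sd, seed = 100 + round(100 * sd))),
  names(teams), teams)

metrics <- vapply(subs, function(s) weightedRMSE(truth, s, "sc2")$value, numeric(1))
rankSubmissions(metrics)
#>   rank team_id     value
#> 1    1   alpha 0.0835678
#> 2    2    beta 0.2529426
#> 3    3   gamma 0.4953988

bm <- bootstrapMetrics(truth, subs, "sc2", B = 1000, seed = 2)
bayesFactor(bm, "alpha")
#> BayesFactorReport (reference: alpha )
#>  team_id bayes_factor n_reference_better n_team_better n_ties classification
#>    alpha            1                  0             0   1000           tied
#>     beta          Inf               1000             0      0          worse
#>    gamma          Inf               1000             0      0          worse
```

The leaderboard recovers the planted noise ordering (lower weighted RMSE is
better), and the bootstrap Bayes factors declare both noisier teams
non-tied with the best one: the reference beat them in all 1000 resamples
(K = ∞). With teams this unequal, `ensembleSeries()` shows what the
challenge also observed for its top-heavy subchallenge: averaging in a much
worse model degrades the leader (classification "worse" at k = 2, 3);
ensembles shine when members are comparably good and their errors are
decorrelated — the property-based tests construct exactly that case.

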
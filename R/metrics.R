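.match_sc <- function(subchallenge) match.arg(subchallenge, .SUBCHALLENGES)

# Comparison units for a subchallenge. Returns, for aligned truth and
# submission, the truth values s, predictions y and the per-term patient
# weights w. sc1 compares patient-level overall totals (one term per
# patient); sc2/sc3 compare every JSN / erosion location (per-joint terms,
# each weighted by its patient's weight).
.metric_terms <- function(truth, submission, subchallenge) {
  sc <- .match_sc(subchallenge)
  submission <- .align_submission(truth, submission)
  w_pat <- patientWeight(truth)
  if (sc == "sc1") {
    list(s = overallTotals(truth), y = overallTotals(submission), w = w_pat,
         n_terms_per_patient = 1L)
  } else {
    type <- if (sc == "sc2") "jsn" else "erosion"
    ids <- truth@registry@areas$area_id[truth@registry@areas$damage_type == type]
    s <- truth@scores[, ids, drop = FALSE]
    y <- submission@predictions[, ids, drop = FALSE]
    list(s = s, y = y, w = matrix(w_pat, nrow(s), ncol(s)),
         n_terms_per_patient = length(ids))
  }
}

#' Patient-weighted log-RMSE of a submission
#'
#' The challenge's evaluation metric. Each comparison term contributes a
#' residual d = ln(1 + y) - ln(1 + s) (1 is added before the log so a
#' healthy joint, score 0, does not produce log 0); terms are weighted by
#' their patient's weight w = 2^bin_threshold (see [patientWeight()]), and
#' the metric is sqrt( sum(w d^2) / sum(w) ). Comparison units per
#' subchallenge: sc1 = one term per patient on the overall totals
#' (overall-damage task), sc2 = every joint-space-narrowing location,
#' sc3 = every erosion location. Lower is better; 0 iff every term matches
#' exactly.
#'
#' @param truth a [ScoreCohort-class] of ground-truth scores.
#' @param submission a [SubmissionSet-class] on the same patient/joint grid.
#' @param subchallenge "sc1", "sc2" or "sc3".
#' @return one-row data.frame: `subchallenge`, `team_id`, `value`,
#'   `n_patients`, `n_terms`.
#' @seealso [weightBins()], [spearmanMetric()]
#' @export
weightedRMSE <- function(truth, submission, subchallenge = c("sc1", "sc2", "sc3")) {
  sc <- .match_sc(subchallenge)
  tm <- .metric_terms(truth, submission, sc)
  d <- log1p(tm$y) - log1p(tm$s)
  value <- sqrt(sum(tm$w * d^2) / sum(tm$w))
  data.frame(subchallenge = sc, team_id = submission@team_id, value = value,
             n_patients = length(patientIds(truth)), n_terms = length(d))
}

#' Spearman correlation of a submission with the truth
#'
#' Rank correlation (midranks for ties) between predicted and true values
#' over the same comparison units as [weightedRMSE()]. Used as the
#' alternative outcome metric for ensemble evaluation.
#'
#' @inheritParams weightedRMSE
#' @return correlation in \[-1, 1\], or NA (with a warning) when either
#'   vector is constant.
#' @export
spearmanMetric <- function(truth, submission, subchallenge = c("sc1", "sc2", "sc3")) {
  tm <- .metric_terms(truth, submission, .match_sc(subchallenge))
  s <- as.vector(tm$s); y <- as.vector(tm$y)
  if (length(s) < 3L) stop("need at least 3 comparison units")
  if (stats::sd(s) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(y, s, method = "spearman")
}

#' Concordance index between two per-team performance lists
#'
#' Fraction of team pairs ordered identically by the two lists: 1 = same
#' ordering, 0.5 = random, 0 = inverse ordering. Pairs tied in either list
#' count one half. Used to compare final-evaluation and independent
#' validation performance.
#'
#' @param metric_values_a,metric_values_b numeric vectors of per-team
#'   metric values; when both are named they are matched by team id.
#' @return value in \[0, 1\].
#' @examples
#' concordanceIndex(c(a = 1, b = 2, c = 3), c(a = 10, b = 20, c = 30))  # 1
#' @export
concordanceIndex <- function(metric_values_a, metric_values_b) {
  a <- metric_values_a; b <- metric_values_b
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("team sets differ")
    b <- b[names(a)]
  }
  n <- length(a)
  if (n < 2L || length(b) != n) stop("need the same >= 2 teams in both lists")
  pairs <- utils::combn(n, 2)
  da <- a[pairs[1, ]] - a[pairs[2, ]]
  db <- b[pairs[1, ]] - b[pairs[2, ]]
  score <- ifelse(da == 0 | db == 0, 0.5, (sign(da) == sign(db)) * 1)
  mean(score)
}

#' Flag joint scores that are grossly discordant with the ground truth
#'
#' Deterministic screen for predictions far from the expert score,
#' emulating the post-hoc review of discordant scores. The default rule
#' flags a comparison unit when the absolute raw-score discrepancy
#' |y - s| meets the cutoff (default 3 score units); the cutoff is fully
#' parameterized.
#'
#' @inheritParams weightedRMSE
#' @param cutoff positive discrepancy threshold on the raw score scale.
#' @return data.frame with columns `patient_id`, `area_id`, `truth`,
#'   `predicted`, `discrepancy`; zero rows when nothing is flagged. For
#'   sc1 the `area_id` is `"<overall>"`.
#' @export
flagOutliers <- function(truth, submission, subchallenge = c("sc2", "sc3", "sc1"),
                         cutoff = 3) {
  sc <- .match_sc(subchallenge)
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0) {
    stop("cutoff must be a single positive number")
  }
  tm <- .metric_terms(truth, submission, sc)
  dev <- abs(tm$y - tm$s)
  if (sc == "sc1") {
    hit <- which(dev >= cutoff)
    out <- data.frame(patient_id = patientIds(truth)[hit],
                      area_id = rep("<overall>", length(hit)),
                      truth = as.vector(tm$s)[hit],
                      predicted = as.vector(tm$y)[hit])
  } else {
    hit <- which(dev >= cutoff, arr.ind = TRUE)
    out <- data.frame(patient_id = patientIds(truth)[hit[, 1]],
                      area_id = colnames(tm$s)[hit[, 2]],
                      truth = tm$s[hit], predicted = tm$y[hit])
  }
  out$discrepancy <- out$predicted - out$truth
  out[order(out$patient_id, out$area_id), , drop = FALSE]
}

#' Outlier rate as a printed percentage
#'
#' @param n_flagged,n_total flagged and total joint-score counts,
#'   `0 <= n_flagged <= n_total`, `n_total > 0`.
#' @return 100 * n_flagged / n_total rounded to one decimal (the precision
#'   outlier rates are reported at).
#' @examples
#' outlierRate(201, 7896)  # 2.5
#' @export
outlierRate <- function(n_flagged, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_flagged < 0) || any(n_flagged > n_total)) {
    stop("n_flagged must be in [0, n_total]")
  }
  round(100 * n_flagged / n_total, 1)
}

#' Between-reader coefficient of variation
#'
#' Agreement summary for two expert readers scoring the same radiographs:
#' for each patient the CV of the pair of totals (sample SD of the two
#' values divided by their mean), averaged over patients. Patients whose
#' pair mean is zero (both readers scored 0) are excluded from the average
#' and counted in the report.
#'
#' @param reader1,reader2 [ScoreCohort-class]s on the same patients, or
#'   numeric vectors of paired per-patient totals.
#' @param damage_type which totals to compare when cohorts are supplied:
#'   "overall", "jsn" or "erosion".
#' @return list with `cv` (mean per-patient CV), `n_used`, `n_excluded`.
#' @export
readerCV <- function(reader1, reader2, damage_type = c("overall", "jsn", "erosion")) {
  damage_type <- match.arg(damage_type)
  tot <- function(x) {
    if (is(x, "ScoreCohort")) {
      switch(damage_type, overall = overallTotals(x), jsn = jsnTotals(x),
             erosion = erosionTotals(x))
    } else as.numeric(x)
  }
  a <- tot(reader1); b <- tot(reader2)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("reader cohorts cover different patients")
    b <- b[names(a)]
  }
  if (length(a) == 0L || length(a) != length(b)) stop("need paired, non-empty totals")
  m <- (a + b) / 2
  s <- abs(a - b) / sqrt(2)            # sample SD (n - 1 = 1) of a pair
  use <- m > 0
  list(cv = if (any(use)) mean(s[use] / m[use]) else NA_real_,
       n_used = sum(use), n_excluded = sum(!use))
}
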
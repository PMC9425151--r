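# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is left untouched.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Per-patient sufficient statistics of the weighted RMSE: num_p = sum over
# the patient's terms of w d^2, den_p = sum of w. The metric on any
# patient multiset P is sqrt(sum(num[P]) / sum(den[P])) — a resampled
# patient's weight depends only on its own truth total, so recomputing
# weights on a resample is exactly this.
.patient_stats <- function(truth, submission, subchallenge) {
  tm <- .metric_terms(truth, submission, subchallenge)
  d2 <- (log1p(tm$y) - log1p(tm$s))^2
  if (is.matrix(d2)) {
    list(num = rowSums(tm$w * d2), den = rowSums(tm$w))
  } else {
    list(num = tm$w * d2, den = tm$w)
  }
}

#' Bootstrap the weighted RMSE over patient resamples
#'
#' Draws B resamples of the cohort's radiographic sets (rows) with
#' replacement at full cohort size and scores every submission on each
#' resample; all teams share the same resample within an iteration, and
#' patient weights are recomputed on each resample (a patient drawn twice
#' counts twice). This is the robustness analysis behind the Bayes-factor
#' ranking.
#'
#' @param truth a [ScoreCohort-class].
#' @param submissions named list of [SubmissionSet-class] (names default to
#'   the team ids).
#' @param subchallenge "sc1", "sc2" or "sc3".
#' @param B number of bootstrap iterations (the challenge used 1000).
#' @param seed integer seed for the resampling RNG.
#' @param indices optional B x n_patients integer matrix of row positions,
#'   overriding the RNG (audit/testing hook; e.g. a row of `1:n` scores the
#'   full cohort).
#' @return a [BootstrapMatrix-class].
#' @export
bootstrapMetrics <- function(truth, submissions, subchallenge = c("sc1", "sc2", "sc3"),
                             B = 1000L, seed = 1L, indices = NULL) {
  sc <- .match_sc(subchallenge)
  if (is(submissions, "SubmissionSet")) submissions <- list(submissions)
  if (is.null(names(submissions)) || !all(nzchar(names(submissions)))) {
    names(submissions) <- vapply(submissions, teamId, character(1))
  }
  n <- length(patientIds(truth))
  if (n < 2L) stop("need at least 2 patients to bootstrap")
  if (length(B) != 1L || B < 1L || B != floor(B)) stop("B must be a positive integer")
  B <- as.integer(B)
  if (is.null(indices)) {
    indices <- .with_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), nrow = B))
    seed <- as.integer(seed)
  } else {
    indices <- as.matrix(indices)
    if (ncol(indices) != n || nrow(indices) != B || any(indices < 1) || any(indices > n)) {
      stop("indices must be a B x n_patients matrix of row positions")
    }
    storage.mode(indices) <- "integer"
    seed <- NA_integer_
  }
  stats_list <- lapply(submissions, .patient_stats, truth = truth, subchallenge = sc)
  values <- matrix(NA_real_, B, length(submissions),
                   dimnames = list(NULL, names(submissions)))
  for (t in seq_along(stats_list)) {
    num <- stats_list[[t]]$num
    den <- stats_list[[t]]$den
    resampled_num <- matrix(num[indices], nrow = B)
    resampled_den <- matrix(den[indices], nrow = B)
    values[, t] <- sqrt(rowSums(resampled_num) / rowSums(resampled_den))
  }
  new("BootstrapMatrix", subchallenge = sc, B = B, values = values,
      seed = seed, indices = indices)
}

#' Bayes factors of every submission against a reference
#'
#' For each team, K = (#iterations the reference's metric is strictly
#' lower) / (#iterations the team's is strictly lower); iterations where
#' the two metrics tie exactly are excluded from both counts, which keeps
#' K symmetric (swapping reference and challenger maps K to 1/K). A team
#' with K > 3 performed worse than the reference ("greater than 3" is the
#' win rule, so K = 3 exactly is a tie), K < 1/3 better, anything else
#' tied. A zero denominator with a positive numerator gives K = Inf; two
#' identical metric vectors (e.g. the reference against itself) give K = 1
#' and a tie by construction.
#'
#' @param matrix a [BootstrapMatrix-class].
#' @param reference_team team id of the reference submission (typically the
#'   top performer).
#' @return a [BayesFactorReport-class].
#' @export
bayesFactor <- function(matrix, reference_team) {
  stopifnot(is(matrix, "BootstrapMatrix"))
  v <- matrix@values
  if (!reference_team %in% colnames(v)) stop("reference team not in the bootstrap matrix")
  ref <- v[, reference_team]
  rows <- lapply(colnames(v), function(team) {
    ref_better <- sum(ref < v[, team])
    team_better <- sum(v[, team] < ref)
    k <- if (ref_better == 0L && team_better == 0L) 1
         else if (team_better == 0L) Inf
         else ref_better / team_better
    cls <- if (k > 3) "worse" else if (k < 1 / 3) "better" else "tied"
    data.frame(team_id = team, bayes_factor = k,
               n_reference_better = ref_better, n_team_better = team_better,
               n_ties = nrow(v) - ref_better - team_better,
               classification = cls)
  })
  new("BayesFactorReport", reference = reference_team, table = do.call(rbind, rows))
}

#' Rank submissions by full-cohort metric
#'
#' Ascending weighted RMSE (lower is better); exact ties are broken
#' lexicographically by team id so the ranking is deterministic.
#'
#' @param metrics named numeric vector of per-team metric values, or a
#'   data.frame with columns `team_id` and `value` (e.g. rbind-ed
#'   [weightedRMSE()] rows).
#' @return data.frame with columns `rank`, `team_id`, `value`.
#' @export
rankSubmissions <- function(metrics) {
  if (is.data.frame(metrics)) {
    v <- stats::setNames(metrics$value, metrics$team_id)
  } else v <- metrics
  if (length(v) < 1L || is.null(names(v))) stop("need >= 1 named metric value")
  ord <- order(v, names(v))
  data.frame(rank = seq_along(v), team_id = names(v)[ord],
             value = unname(v[ord]))
}

#' FDR-corrected pairwise t tests against a reference submission
#'
#' Secondary comparison: a paired two-sided t test of each team's bootstrap
#' metric vector against the reference's, with Benjamini-Hochberg
#' correction across teams. A zero-variance difference vector (e.g. a team
#' identical to the reference) cannot be tested; it is reported with p = 1
#' and `degenerate = TRUE`.
#'
#' @inheritParams bayesFactor
#' @return data.frame with columns `team_id`, `p_value`, `q_value`,
#'   `degenerate`, one row per non-reference team.
#' @export
pairwiseTFdr <- function(matrix, reference_team) {
  stopifnot(is(matrix, "BootstrapMatrix"))
  v <- matrix@values
  if (!reference_team %in% colnames(v)) stop("reference team not in the bootstrap matrix")
  if (nrow(v) < 2L) stop("need B >= 2 bootstrap iterations for a paired t test")
  teams <- setdiff(colnames(v), reference_team)
  res <- lapply(teams, function(team) {
    diff <- v[, team] - v[, reference_team]
    if (stats::sd(diff) == 0) {
      data.frame(team_id = team, p_value = 1, degenerate = TRUE)
    } else {
      data.frame(team_id = team,
                 p_value = stats::t.test(v[, team], v[, reference_team],
                                         paired = TRUE)$p.value,
                 degenerate = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[c("team_id", "p_value", "q_value", "degenerate")]
}
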
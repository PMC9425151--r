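#' Arithmetic-mean ensemble of submissions
#'
#' The "wisdom of the crowds" aggregate: the mean estimation for each
#' (patient, joint area) cell across the member submissions, on the raw
#' predicted-score scale. Patient-level sub-totals are the means of the
#' members' stored sub-totals (not recomputed from the ensembled joints).
#'
#' @param members list of [SubmissionSet-class] on identical grids.
#' @param team_id id for the resulting ensemble submission (default
#'   `"ensemble_k<k>"`).
#' @return a [SubmissionSet-class].
#' @export
meanEnsemble <- function(members, team_id = NULL) {
  if (is(members, "SubmissionSet")) members <- list(members)
  k <- length(members)
  if (k < 1L) stop("need at least one member submission")
  ref <- members[[1]]
  pred <- ref@predictions
  tot <- ref@totals
  for (m in members[-1]) {
    if (!identical(dimnames(m@predictions), dimnames(pred))) {
      stop("member grids differ (patients or joint areas)")
    }
    pred <- pred + m@predictions
    tot <- tot + m@totals
  }
  if (is.null(team_id)) team_id <- paste0("ensemble_k", k)
  submissionSet(team_id, pred / k, totals = tot / k, registry = ref@registry)
}

#' Cumulative top-k ensemble series
#'
#' Ranks the submissions by full-cohort weighted RMSE, then evaluates the
#' top performer alone, the mean of the top 2, the top 3, and so on. Each
#' ensemble is scored with the weighted RMSE and with the Spearman
#' correlation (the alternative outcome metric), and compared with the top
#' individual model by the bootstrap Bayes-factor robustness analysis; the
#' same bootstrap resamples are shared by all ensembles within a run so
#' comparisons are variance-paired.
#'
#' @param truth a [ScoreCohort-class].
#' @param submissions named list of [SubmissionSet-class].
#' @param subchallenge "sc1", "sc2" or "sc3".
#' @param B bootstrap iterations for the Bayes-factor comparison.
#' @param seed resampling seed.
#' @return an [EnsembleSeries-class]; its table's `classification` reads as
#'   the ensemble's call versus the top individual ("better" = the ensemble
#'   outperformed it with Bayes factor > 3).
#' @export
ensembleSeries <- function(truth, submissions, subchallenge = c("sc1", "sc2", "sc3"),
                           B = 1000L, seed = 1L) {
  sc <- .match_sc(subchallenge)
  if (is.null(names(submissions))) {
    names(submissions) <- vapply(submissions, teamId, character(1))
  }
  full <- vapply(submissions, function(s) weightedRMSE(truth, s, sc)$value, numeric(1))
  ranking <- rankSubmissions(full)
  ordered <- submissions[ranking$team_id]
  ks <- seq_along(ordered)
  ensembles <- lapply(ks, function(k) {
    meanEnsemble(unname(ordered[seq_len(k)]), team_id = paste0("ensemble_k", k))
  })
  names(ensembles) <- vapply(ensembles, teamId, character(1))

  top <- ordered[[1]]
  pool <- c(list(top_individual = top), ensembles)
  bm <- bootstrapMetrics(truth, pool, sc, B = B, seed = seed)
  bf <- bayesFactor(bm, "top_individual")
  # bayesFactor classifies each team (here: each ensemble) relative to the
  # reference (the top individual), so rows already describe the ensemble.
  bft <- bf@table[match(names(ensembles), bf@table$team_id), ]

  tab <- data.frame(
    k = ks,
    members = vapply(ks, function(k) paste(ranking$team_id[seq_len(k)], collapse = "+"),
                     character(1)),
    weighted_rmse = vapply(ensembles, function(e) weightedRMSE(truth, e, sc)$value,
                           numeric(1)),
    spearman = vapply(ensembles, function(e) spearmanMetric(truth, e, sc), numeric(1)),
    bayes_factor = bft$bayes_factor,
    classification = bft$classification
  )
  rownames(tab) <- NULL
  new("EnsembleSeries", subchallenge = sc, members = ranking$team_id,
      table = tab, ensembles = ensembles)
}

#' Pairwise Spearman correlation between submissions
#'
#' Correlation of the teams' predictions with each other (not with the
#' truth) over the subchallenge's comparison units; low off-diagonal
#' correlation identifies teams contributing information orthogonal to the
#' rest — the teams that help an ensemble most.
#'
#' @param submissions named list of >= 2 [SubmissionSet-class] on identical
#'   grids.
#' @param subchallenge "sc1", "sc2" or "sc3".
#' @return symmetric team x team correlation matrix with unit diagonal;
#'   a team with a constant prediction vector yields NA entries and a
#'   warning.
#' @export
pairwiseSubmissionCorrelation <- function(submissions,
                                          subchallenge = c("sc1", "sc2", "sc3")) {
  sc <- .match_sc(subchallenge)
  if (length(submissions) < 2L) stop("need at least 2 submissions")
  if (is.null(names(submissions))) {
    names(submissions) <- vapply(submissions, teamId, character(1))
  }
  vec <- function(s) {
    if (sc == "sc1") return(overallTotals(s))
    type <- if (sc == "sc2") "jsn" else "erosion"
    ids <- s@registry@areas$area_id[s@registry@areas$damage_type == type]
    as.vector(s@predictions[, ids, drop = FALSE])
  }
  m <- vapply(submissions, vec, numeric(length(vec(submissions[[1]]))))
  const <- apply(m, 2, stats::sd) == 0
  if (any(const)) {
    warning("constant prediction vector(s): ",
            paste(names(submissions)[const], collapse = ", "))
  }
  out <- suppressWarnings(stats::cor(m, method = "spearman"))
  diag(out) <- 1
  out
}
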
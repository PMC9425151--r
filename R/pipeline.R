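.read_submission_dir <- function(dir, registry) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  subs <- list()
  for (f in files) {
    sub <- tryCatch(readScoresCsv(f, role = "submission", registry = registry),
                    error = function(e) {
                      message("skipping malformed submission '", basename(f),
                              "': ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(sub)) subs[[teamId(sub)]] <- sub
  }
  subs
}

.as_truth <- function(x, registry) {
  if (is(x, "ScoreCohort")) x else readScoresCsv(x, "truth", registry = registry)
}

.as_submissions <- function(x, registry) {
  if (is.character(x)) return(.read_submission_dir(x, registry))
  if (is(x, "SubmissionSet")) x <- list(x)
  if (is.null(names(x))) names(x) <- vapply(x, teamId, character(1))
  x
}

#' Run the full challenge evaluation flow
#'
#' Score, rank, bootstrap, ensemble, and (optionally) validate against a
#' second cohort — the end-to-end evaluation of a set of submissions
#' against a ground-truth cohort. Per subchallenge this produces a ranked
#' leaderboard, the bootstrap metric matrix, the Bayes-factor report and
#' FDR-corrected pairwise t tests versus the top team, and the cumulative
#' top-k ensemble series. When a validation cohort (and the teams'
#' submissions on it) is supplied, the per-team metrics on both cohorts and
#' their concordance index are reported as well. A malformed submission
#' file is skipped with a diagnostic, never aborting the run. All outputs
#' are CSV plus a JSON manifest (config, seeds, package version) that
#' suffices to reproduce every file bit-exactly.
#'
#' @param truth ground-truth [ScoreCohort-class] or path to a truth CSV.
#' @param submissions named list of [SubmissionSet-class] or a directory of
#'   submission CSVs (team id = file name).
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @param subchallenges subset of c("sc1","sc2","sc3") to evaluate.
#' @param B bootstrap iterations.
#' @param seed integer seed; per-subchallenge resampling seeds are derived
#'   from it deterministically.
#' @param outlier_cutoff raw-score cutoff passed to [flagOutliers()].
#' @param validation_truth,validation_submissions optional second cohort
#'   and the same teams' submissions on it (objects or paths).
#' @return (invisibly) a list with one element per subchallenge —
#'   `leaderboard`, `bootstrap`, `bayes_factors`, `pairwise_t`, `ensemble`,
#'   `outliers`, and optionally `validation` (per-team metric pairs +
#'   `concordance`) — plus `manifest`.
#' @export
runEvaluation <- function(truth, submissions, out_dir = NULL,
                          subchallenges = c("sc1", "sc2", "sc3"),
                          B = 1000L, seed = 1L, outlier_cutoff = 3,
                          validation_truth = NULL, validation_submissions = NULL) {
  subchallenges <- match.arg(subchallenges, .SUBCHALLENGES, several.ok = TRUE)
  reg <- svhRegistry()
  truth <- .as_truth(truth, reg)
  submissions <- .as_submissions(submissions, reg)
  if (!length(submissions)) stop("no valid submissions")
  has_validation <- !is.null(validation_truth) && !is.null(validation_submissions)
  if (has_validation) {
    validation_truth <- .as_truth(validation_truth, reg)
    validation_submissions <- .as_submissions(validation_submissions, reg)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
    }
  }

  results <- list()
  combined <- data.frame(team_id = names(submissions))
  for (sc in subchallenges) {
    sc_seed <- as.integer(seed) + match(sc, .SUBCHALLENGES)
    metrics <- vapply(submissions,
                      function(s) weightedRMSE(truth, s, sc)$value, numeric(1))
    ranking <- rankSubmissions(metrics)
    combined[[sc]] <- unname(metrics[combined$team_id])

    bm <- bootstrapMetrics(truth, submissions, sc, B = B, seed = sc_seed)
    top <- ranking$team_id[1]
    bf <- bayesFactor(bm, top)
    tt <- if (B >= 2) pairwiseTFdr(bm, top) else NULL
    ens <- ensembleSeries(truth, submissions, sc, B = B, seed = sc_seed)
    out_flagged <- do.call(rbind, lapply(names(submissions), function(tm) {
      fl <- flagOutliers(truth, submissions[[tm]], sc, cutoff = outlier_cutoff)
      if (nrow(fl)) cbind(team_id = tm, fl) else NULL
    }))
    n_total <- if (sc == "sc1") length(patientIds(truth)) else {
      countJointScores(length(patientIds(truth)),
                       if (sc == "sc2") "jsn" else "erosion", reg)
    }
    outlier_summary <- data.frame(
      team_id = names(submissions),
      n_flagged = vapply(names(submissions), function(tm) {
        if (is.null(out_flagged)) 0L else sum(out_flagged$team_id == tm)
      }, integer(1)),
      n_total = n_total)
    outlier_summary$rate_pct <- outlierRate(outlier_summary$n_flagged, n_total)

    emit(ranking, paste0("leaderboard_", sc, ".csv"))
    emit(data.frame(iteration = rep(seq_len(bm@B), ncol(bm@values)),
                    team_id = rep(colnames(bm@values), each = bm@B),
                    value = as.vector(bm@values)),
         paste0("bootstrap_", sc, ".csv"))
    emit(bf@table, paste0("bayes_factors_", sc, ".csv"))
    if (!is.null(tt)) emit(tt, paste0("pairwise_t_", sc, ".csv"))
    emit(ens@table, paste0("ensemble_", sc, ".csv"))
    emit(outlier_summary, paste0("outlier_summary_", sc, ".csv"))

    sc_res <- list(leaderboard = ranking, bootstrap = bm, bayes_factors = bf,
                   pairwise_t = tt, ensemble = ens, outliers = outlier_summary)

    if (has_validation) {
      common <- intersect(names(submissions), names(validation_submissions))
      vmetrics <- vapply(validation_submissions[common], function(s)
        weightedRMSE(validation_truth, s, sc)$value, numeric(1))
      scatter <- data.frame(team_id = common,
                            final_evaluation = unname(metrics[common]),
                            validation = unname(vmetrics))
      ci <- if (length(common) >= 2) {
        concordanceIndex(metrics[common], vmetrics)
      } else NA_real_
      emit(scatter, paste0("validation_scatter_", sc, ".csv"))
      emit(data.frame(subchallenge = sc, concordance_index = ci,
                      n_teams = length(common)),
           paste0("validation_concordance_", sc, ".csv"))
      sc_res$validation <- list(scatter = scatter, concordance = ci)
    }
    results[[sc]] <- sc_res
  }

  combined$n_patients <- length(patientIds(truth))
  if (!is.null(out_dir)) {
    writeLeaderboardCsv(combined, file.path(out_dir, "leaderboard.csv"))
  }
  manifest <- list(
    package = "svhbench",
    version = as.character(utils::packageVersion("svhbench")),
    subchallenges = subchallenges, B = as.integer(B), seed = as.integer(seed),
    outlier_cutoff = outlier_cutoff,
    n_patients = length(patientIds(truth)),
    teams = names(submissions),
    validation = has_validation)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  results$manifest <- manifest
  invisible(results)
}

#' Build and evaluate a self-contained demo workspace
#'
#' Generates a synthetic cohort, simulated team submissions with a known
#' noise ordering, a paired expert-reader validation structure, writes all
#' of them as CSVs in the documented template, runs [runEvaluation()] on
#' them, and emits a plain-text summary. Everything is deterministic given
#' the seed.
#'
#' @param out_dir workspace directory (created if needed).
#' @param n_patients cohort size.
#' @param team_sds log-scale noise SDs, one simulated team per value (named
#'   `team_<sd>`); their order is the planted ground-truth ranking.
#' @param B bootstrap iterations.
#' @param seed master seed.
#' @return (invisibly) the [runEvaluation()] result list, with `paths`
#'   (workspace layout) attached.
#' @export
makeDemo <- function(out_dir, n_patients = 50L, team_sds = c(0.1, 0.3, 0.6),
                     B = 100L, seed = 42L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sub_dir <- file.path(out_dir, "submissions")
  dir.create(sub_dir, showWarnings = FALSE)
  reg <- svhRegistry()

  truth <- generateCohort(cohortConfig(n_patients, seed = seed), reg)
  writeScoresCsv(truth, file.path(out_dir, "truth.csv"))

  teams <- paste0("team_", sub("\\.", "p", formatC(team_sds, format = "g")))
  for (i in seq_along(team_sds)) {
    sub <- generateSubmission(truth, teamNoiseConfig(
      teams[i], sd = team_sds[i], seed = seed + 100L + i, shared_seed = seed))
    writeScoresCsv(sub, file.path(sub_dir, paste0(teams[i], ".csv")))
  }
  readers <- generateReaderPair(truth, reader_sds = c(0.5, 0.5), seed = seed + 500L)
  writeScoresCsv(readers$reader1, file.path(out_dir, "reader1.csv"))
  writeScoresCsv(readers$reader2, file.path(out_dir, "reader2.csv"))

  res <- runEvaluation(file.path(out_dir, "truth.csv"), sub_dir,
                       out_dir = file.path(out_dir, "results"),
                       B = B, seed = seed)

  cv <- readerCV(readers$reader1, readers$reader2)
  lines <- c("svhbench demo workspace",
             paste0("patients: ", n_patients, ", teams: ",
                    paste(teams, collapse = ", "), ", B = ", B, ", seed = ", seed),
             "",
             "Leaderboard (weighted RMSE, lower is better):")
  for (sc in .SUBCHALLENGES) {
    lb <- res[[sc]]$leaderboard
    lines <- c(lines, paste0("  ", sc, ": ",
                             paste(sprintf("%s=%.4f", lb$team_id, lb$value),
                                   collapse = "  ")))
  }
  lines <- c(lines, "",
             sprintf("between-reader CV (overall totals): %.3f (%d patients used, %d all-zero pairs excluded)",
                     cv$cv, cv$n_used, cv$n_excluded))
  writeLines(lines, file.path(out_dir, "summary.txt"))

  res$paths <- list(truth = file.path(out_dir, "truth.csv"),
                    submissions = sub_dir,
                    results = file.path(out_dir, "results"),
                    summary = file.path(out_dir, "summary.txt"))
  invisible(res)
}
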
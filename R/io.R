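.TOTAL_COLS <- c("Overall_narrowing", "Overall_erosion", "Overall_Tol")

#' Read and write score-sheet CSVs
#'
#' The on-disk template (UTF-8, header row, one row per radiographic set):
#' a `Patient_ID` column, one column per registry joint area named
#' `{LH|RH|LF|RF}_{name}__{J|E}`, and the three sub-total columns
#' `Overall_narrowing`, `Overall_erosion`, `Overall_Tol`. Truth files carry
#' integer scores and their sub-totals must equal the recomputed row sums
#' exactly; submission files carry continuous non-negative predictions and
#' their stored sub-totals are cross-checked against the recomputed sums to
#' `total_tolerance` (patient-level sub-totals are themselves predictions,
#' so the check is tolerance-parameterized). Writing then reading a truth
#' cohort is an identity.
#'
#' @param path CSV file path.
#' @param role "truth" or "submission".
#' @param team_id team id for submissions (default: file name without
#'   extension).
#' @param registry a [JointAreaRegistry-class].
#' @param total_tolerance maximum allowed |stored - recomputed| sub-total
#'   discrepancy for submissions (truth files must match exactly).
#' @return [readScoresCsv()]: a [ScoreCohort-class] (`role = "truth"`) or a
#'   [SubmissionSet-class] (`role = "submission"`); [writeScoresCsv()]: the
#'   path, invisibly.
#' @export
readScoresCsv <- function(path, role = c("truth", "submission"), team_id = NULL,
                          registry = svhRegistry(), total_tolerance = 1e-6) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  hdr <- names(df)
  dup <- unique(hdr[duplicated(hdr)])
  if (length(dup)) stop("duplicated column(s): ", paste(dup, collapse = ", "))
  expected <- c("Patient_ID", registry@areas$area_id, .TOTAL_COLS)
  missing_cols <- setdiff(expected, hdr)
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  unknown <- setdiff(hdr, expected)
  if (length(unknown)) {
    stop("unknown joint-area column(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (anyDuplicated(df$Patient_ID)) stop("duplicated Patient_ID values")

  num_cols <- setdiff(expected, "Patient_ID")
  m <- matrix(NA_real_, nrow(df), length(num_cols),
              dimnames = list(df$Patient_ID, num_cols))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !nzchar(trimws(df[[col]])))
    if (length(bad)) {
      stop("malformed number in column '", col, "', row ", bad[1],
           " (Patient_ID ", df$Patient_ID[bad[1]], "): '", df[[col]][bad[1]], "'")
    }
    if (any(v < 0)) {
      r <- which(v < 0)[1]
      stop("negative value in column '", col, "', row ", r,
           " (Patient_ID ", df$Patient_ID[r], ")")
    }
    m[, col] <- v
  }

  scores <- m[, registry@areas$area_id, drop = FALSE]
  stored <- m[, .TOTAL_COLS, drop = FALSE]
  recomputed <- cbind(.type_totals(scores, registry, "jsn"),
                      .type_totals(scores, registry, "erosion"),
                      rowSums(scores))
  tol <- if (role == "truth") 0 else total_tolerance
  dev <- abs(stored - recomputed)
  if (any(dev > tol)) {
    idx <- which(dev > tol, arr.ind = TRUE)[1, ]
    stop("sub-total mismatch in column '", .TOTAL_COLS[idx[2]], "', Patient_ID ",
         rownames(stored)[idx[1]], ": stored ", stored[idx[1], idx[2]],
         " vs recomputed ", signif(recomputed[idx[1], idx[2]], 12))
  }

  if (role == "truth") {
    scoreCohort(scores, registry)
  } else {
    if (is.null(team_id)) team_id <- tools::file_path_sans_ext(basename(path))
    submissionSet(team_id, scores,
                  totals = cbind(jsn = stored[, "Overall_narrowing"],
                                 erosion = stored[, "Overall_erosion"],
                                 overall = stored[, "Overall_Tol"]),
                  registry = registry)
  }
}

#' @param x a [ScoreCohort-class] or [SubmissionSet-class] to serialize.
#' @rdname readScoresCsv
#' @export
writeScoresCsv <- function(x, path) {
  m <- scoreMatrix(x)
  if (is(x, "ScoreCohort")) {
    jsn <- jsnTotals(x); ero <- erosionTotals(x); ov <- overallTotals(x)
    storage.mode(m) <- "integer"
    df <- data.frame(Patient_ID = rownames(m), m,
                     Overall_narrowing = as.integer(jsn),
                     Overall_erosion = as.integer(ero),
                     Overall_Tol = as.integer(ov),
                     check.names = FALSE)
  } else {
    df <- data.frame(Patient_ID = rownames(m), m,
                     Overall_narrowing = unname(jsnTotals(x)),
                     Overall_erosion = unname(erosionTotals(x)),
                     Overall_Tol = unname(overallTotals(x)),
                     check.names = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a leaderboard CSV
#'
#' One row per team with its weighted RMSE per subchallenge, ascending by
#' the first subchallenge evaluated; deterministic column order
#' `team_id, sc1, sc2, sc3, n_patients`.
#'
#' @param leaderboard data.frame with columns `team_id`, any of
#'   `sc1`/`sc2`/`sc3`, and `n_patients`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeLeaderboardCsv <- function(leaderboard, path) {
  cols <- c("team_id", intersect(c("sc1", "sc2", "sc3"), names(leaderboard)),
            "n_patients")
  utils::write.csv(leaderboard[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
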
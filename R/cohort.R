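.as_score_matrix <- function(scores) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  scores
}

#' Validate a matrix of ground-truth SvH scores against a registry
#'
#' Report-based validation: never throws, returns one row per violation so
#' a caller can list every problem in a sheet at once. Checked per patient
#' and area: presence of every registry area (and absence of unknown
#' columns), non-missing, integer-valued, within `[0, max_score]`.
#'
#' @param scores matrix or data.frame, rows = patients, columns named by
#'   registry `area_id`s; or a [ScoreCohort-class].
#' @param registry a [JointAreaRegistry-class].
#' @return data.frame with columns `patient_id`, `area_id`, `problem`;
#'   zero rows iff the scores are valid.
#' @examples
#' reg <- svhRegistry()
#' m <- matrix(0, 1, nrow(jointAreas(reg)),
#'             dimnames = list("p1", jointAreas(reg)$area_id))
#' nrow(validateScores(m, reg)) == 0
#' @export
validateScores <- function(scores, registry = svhRegistry()) {
  if (is(scores, "ScoreCohort")) scores <- scores@scores
  scores <- .as_score_matrix(scores)
  a <- registry@areas
  pid <- rownames(scores)
  if (is.null(pid)) pid <- as.character(seq_len(nrow(scores)))

  bad <- data.frame(patient_id = character(), area_id = character(),
                    problem = character())
  add <- function(p, ar, why) rbind(bad, data.frame(patient_id = p, area_id = ar, problem = why))

  missing_areas <- setdiff(a$area_id, colnames(scores))
  for (ar in missing_areas) bad <- add("<all>", ar, "missing joint area")
  unknown <- setdiff(colnames(scores), a$area_id)
  for (ar in unknown) bad <- add("<all>", ar, "unknown joint area")
  dup <- unique(colnames(scores)[duplicated(colnames(scores))])
  for (ar in dup) bad <- add("<all>", ar, "duplicated joint area")

  keep <- intersect(a$area_id, colnames(scores))
  if (length(keep) && nrow(scores)) {
    caps <- a$max_score[match(keep, a$area_id)]
    s <- scores[, keep, drop = FALSE]
    flag <- function(mask, why) {
      idx <- which(mask, arr.ind = TRUE)
      if (nrow(idx)) {
        bad <<- rbind(bad, data.frame(patient_id = pid[idx[, 1]],
                                      area_id = keep[idx[, 2]], problem = why))
      }
    }
    flag(is.na(s), "missing score")
    ok <- !is.na(s)
    flag(ok & s != floor(s), "non-integer score")
    flag(ok & s < 0, "negative score")
    flag(ok & s > matrix(caps, nrow(s), length(caps), byrow = TRUE),
         "score above joint-area cap")
  }
  rownames(bad) <- NULL
  bad
}

#' Construct a ScoreCohort
#'
#' @param scores integer matrix or data.frame (patients x joint areas);
#'   rownames (or a `Patient_ID` column) give patient ids; columns are
#'   registry `area_id`s in any order.
#' @param registry a [JointAreaRegistry-class].
#' @return a validated [ScoreCohort-class].
#' @export
scoreCohort <- function(scores, registry = svhRegistry()) {
  if (is.data.frame(scores) && "Patient_ID" %in% names(scores)) {
    rownames(scores) <- scores$Patient_ID
    scores$Patient_ID <- NULL
  }
  scores <- .as_score_matrix(scores)
  rep <- validateScores(scores, registry)
  if (nrow(rep)) {
    stop("invalid score sheet(s): ", nrow(rep), " violation(s); first: ",
         rep$problem[1], " [patient ", rep$patient_id[1], ", area ",
         rep$area_id[1], "]")
  }
  scores <- scores[, registry@areas$area_id, drop = FALSE]
  new("ScoreCohort", scores = scores, registry = registry)
}

#' @rdname cohort-accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @rdname cohort-accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))
#' @rdname cohort-accessors
#' @export
setGeneric("registry", function(x) standardGeneric("registry"))
#' @rdname cohort-accessors
#' @export
setGeneric("jsnTotals", function(x) standardGeneric("jsnTotals"))
#' @rdname cohort-accessors
#' @export
setGeneric("erosionTotals", function(x) standardGeneric("erosionTotals"))
#' @rdname cohort-accessors
#' @export
setGeneric("overallTotals", function(x) standardGeneric("overallTotals"))
#' @rdname cohort-accessors
#' @export
setGeneric("teamId", function(x) standardGeneric("teamId"))

.type_totals <- function(m, registry, type) {
  ids <- registry@areas$area_id[registry@areas$damage_type == type]
  rowSums(m[, ids, drop = FALSE])
}

#' Accessors for cohorts and submissions
#'
#' `patientIds`, `scoreMatrix` (the score/prediction matrix), `registry`,
#' and the derived `jsnTotals` / `erosionTotals` / `overallTotals`
#' (named per patient). For a [SubmissionSet-class] the totals are the
#' team's stored patient-level sub-total predictions, not recomputed sums.
#'
#' @param x a [ScoreCohort-class] or [SubmissionSet-class].
#' @return vector/matrix accessor results, named by patient id.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
setMethod("patientIds", "ScoreCohort", function(x) rownames(x@scores))
#' @rdname cohort-accessors
setMethod("scoreMatrix", "ScoreCohort", function(x) x@scores)
#' @rdname cohort-accessors
setMethod("registry", "ScoreCohort", function(x) x@registry)
#' @rdname cohort-accessors
setMethod("jsnTotals", "ScoreCohort", function(x) .type_totals(x@scores, x@registry, "jsn"))
#' @rdname cohort-accessors
setMethod("erosionTotals", "ScoreCohort", function(x) .type_totals(x@scores, x@registry, "erosion"))
#' @rdname cohort-accessors
setMethod("overallTotals", "ScoreCohort", function(x) rowSums(x@scores))

#' @rdname cohort-accessors
setMethod("patientIds", "SubmissionSet", function(x) rownames(x@predictions))
#' @rdname cohort-accessors
setMethod("scoreMatrix", "SubmissionSet", function(x) x@predictions)
#' @rdname cohort-accessors
setMethod("registry", "SubmissionSet", function(x) x@registry)
#' @rdname cohort-accessors
setMethod("teamId", "SubmissionSet", function(x) x@team_id)
#' @rdname cohort-accessors
setMethod("jsnTotals", "SubmissionSet", function(x) x@totals[, "jsn"])
#' @rdname cohort-accessors
setMethod("erosionTotals", "SubmissionSet", function(x) x@totals[, "erosion"])
#' @rdname cohort-accessors
setMethod("overallTotals", "SubmissionSet", function(x) x@totals[, "overall"])

#' Subset a cohort to (possibly repeated) patient rows
#'
#' Integer indices may repeat (bootstrap resamples); repeated patients get
#' suffixed ids so the result remains a valid cohort.
#'
#' @param x a [ScoreCohort-class] or [SubmissionSet-class].
#' @param i integer row positions or patient ids.
#' @param j,...,drop ignored (kept for generic compatibility).
#' @return object of the same class.
#' @rdname cohort-subset
#' @export
setMethod("[", "ScoreCohort", function(x, i, j, ..., drop = FALSE) {
  s <- x@scores[i, , drop = FALSE]
  rownames(s) <- make.unique(rownames(s))
  new("ScoreCohort", scores = s, registry = x@registry)
})

#' @rdname cohort-subset
#' @export
setMethod("[", "SubmissionSet", function(x, i, j, ..., drop = FALSE) {
  p <- x@predictions[i, , drop = FALSE]
  t <- x@totals[i, , drop = FALSE]
  rownames(p) <- make.unique(rownames(p))
  rownames(t) <- rownames(p)
  new("SubmissionSet", team_id = x@team_id, predictions = p, totals = t,
      registry = x@registry)
})

#' Construct a SubmissionSet
#'
#' @param team_id single string identifying the team.
#' @param predictions numeric matrix (patients x joint areas), rownames =
#'   patient ids, colnames = registry `area_id`s in any order; finite,
#'   >= 0, fractional values allowed.
#' @param totals optional patients x 3 matrix (columns `jsn`, `erosion`,
#'   `overall`) of patient-level sub-total predictions; when omitted they
#'   are computed as row sums of the per-joint predictions.
#' @param registry a [JointAreaRegistry-class].
#' @return a validated [SubmissionSet-class].
#' @export
submissionSet <- function(team_id, predictions, totals = NULL,
                          registry = svhRegistry()) {
  predictions <- .as_score_matrix(predictions)
  missing_areas <- setdiff(registry@areas$area_id, colnames(predictions))
  unknown <- setdiff(colnames(predictions), registry@areas$area_id)
  if (length(missing_areas) || length(unknown)) {
    stop("prediction grid mismatch; missing: ",
         paste(utils::head(missing_areas, 3), collapse = ", "),
         if (length(unknown)) paste0("; unknown: ", paste(utils::head(unknown, 3), collapse = ", ")))
  }
  predictions <- predictions[, registry@areas$area_id, drop = FALSE]
  if (is.null(totals)) {
    totals <- cbind(jsn = .type_totals(predictions, registry, "jsn"),
                    erosion = .type_totals(predictions, registry, "erosion"),
                    overall = rowSums(predictions))
  } else {
    totals <- as.matrix(totals)[, c("jsn", "erosion", "overall"), drop = FALSE]
    rownames(totals) <- rownames(predictions)
  }
  new("SubmissionSet", team_id = as.character(team_id),
      predictions = predictions, totals = totals, registry = registry)
}

# Reorder a submission's patients to the truth cohort's order; error on any
# grid mismatch (different patient sets or joint areas).
.align_submission <- function(truth, submission) {
  stopifnot(is(truth, "ScoreCohort"), is(submission, "SubmissionSet"))
  tp <- patientIds(truth)
  sp <- patientIds(submission)
  if (!setequal(tp, sp) || length(tp) != length(sp)) {
    stop("submission '", submission@team_id,
         "' is not aligned to the truth cohort (patient sets differ)")
  }
  if (!identical(colnames(truth@scores), colnames(submission@predictions))) {
    stop("submission '", submission@team_id,
         "' is not aligned to the truth cohort (joint-area grid differs)")
  }
  if (identical(tp, sp)) submission else submission[match(tp, sp)]
}
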
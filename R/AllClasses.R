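#' @import methods
NULL

.DAMAGE_TYPES <- c("jsn", "erosion")
.REGIONS <- c("hand_wrist", "foot")
.SIDES <- c("left", "right")
.SUBCHALLENGES <- c("sc1", "sc2", "sc3")

#' JointAreaRegistry: the Sharp-van der Heijde joint-area enumeration
#'
#' Holds one row per scored location: region (hand/wrist or foot), side,
#' anatomical name, damage type (joint space narrowing or erosion) and the
#' per-location score cap. Joint space narrowing is capped at 4 everywhere;
#' erosion is capped at 5 in the hand/wrist and 10 per foot joint (the two
#' sides of each foot joint are scored together). Use [svhRegistry()] to
#' construct the canonical registry.
#'
#' @slot areas data.frame with columns `area_id`, `region`, `side`, `name`,
#'   `damage_type`, `max_score`; one row per scored location.
#' @export
setClass("JointAreaRegistry", representation(areas = "data.frame"))

setValidity("JointAreaRegistry", function(object) {
  a <- object@areas
  msgs <- character()
  need <- c("area_id", "region", "side", "name", "damage_type", "max_score")
  if (!all(need %in% names(a))) {
    return(paste("missing columns:", paste(setdiff(need, names(a)), collapse = ", ")))
  }
  if (!all(a$region %in% .REGIONS)) msgs <- c(msgs, "unknown region")
  if (!all(a$side %in% .SIDES)) msgs <- c(msgs, "unknown side")
  if (!all(a$damage_type %in% .DAMAGE_TYPES)) msgs <- c(msgs, "unknown damage_type")
  if (anyDuplicated(a$area_id) || anyDuplicated(a[c("region", "side", "name", "damage_type")])) {
    msgs <- c(msgs, "duplicated joint areas")
  }
  jsn <- a$damage_type == "jsn"
  if (any(a$max_score[jsn] != 4L)) msgs <- c(msgs, "JSN areas must be capped at 4")
  ero_hand <- !jsn & a$region == "hand_wrist"
  ero_foot <- !jsn & a$region == "foot"
  if (any(a$max_score[ero_hand] != 5L)) msgs <- c(msgs, "hand/wrist erosion areas must be capped at 5")
  if (any(a$max_score[ero_foot] != 10L)) msgs <- c(msgs, "foot erosion joints must be capped at 10")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ScoreCohort: ground-truth SvH score sheets for a patient cohort
#'
#' One row per patient (radiographic set), one column per registry joint
#' area; entries are the expert-assigned integer scores. Sub-totals (JSN,
#' erosion, overall) are derived, never stored.
#'
#' @slot scores integer-valued matrix, rownames = patient ids, colnames =
#'   registry `area_id`s in registry order.
#' @slot registry the [JointAreaRegistry-class] the columns refer to.
#' @export
setClass("ScoreCohort",
         representation(scores = "matrix", registry = "JointAreaRegistry"))

setValidity("ScoreCohort", function(object) {
  rep <- validateScores(object@scores, object@registry)
  if (nrow(rep) > 0) {
    return(paste0(nrow(rep), " violation(s), e.g.: ", rep$problem[1],
                  " [", rep$patient_id[1], ", ", rep$area_id[1], "]"))
  }
  if (is.null(rownames(object@scores)) || anyDuplicated(rownames(object@scores))) {
    return("patient ids (rownames) must be present and unique")
  }
  TRUE
})

#' SubmissionSet: one team's predicted scores
#'
#' Continuous, non-negative predictions on the same patient x joint-area
#' grid as the ground-truth cohort, plus the team's patient-level sub-total
#' predictions (JSN, erosion, overall) used for the overall-damage
#' subchallenge.
#'
#' @slot team_id single string.
#' @slot predictions numeric matrix, same layout as a [ScoreCohort-class]
#'   score matrix; finite and >= 0 (fractional values allowed).
#' @slot totals numeric matrix (patients x 3) with columns
#'   `jsn`, `erosion`, `overall`.
#' @slot registry the [JointAreaRegistry-class] the columns refer to.
#' @export
setClass("SubmissionSet",
         representation(team_id = "character", predictions = "matrix",
                        totals = "matrix", registry = "JointAreaRegistry"))

setValidity("SubmissionSet", function(object) {
  msgs <- character()
  p <- object@predictions
  if (length(object@team_id) != 1L || is.na(object@team_id) || !nzchar(object@team_id)) {
    msgs <- c(msgs, "team_id must be a single non-empty string")
  }
  if (!identical(colnames(p), object@registry@areas$area_id)) {
    msgs <- c(msgs, "prediction columns must match the registry area ids")
  }
  if (!all(is.finite(p)) || any(p < 0)) {
    msgs <- c(msgs, "predictions must be finite and >= 0")
  }
  if (is.null(rownames(p)) || anyDuplicated(rownames(p))) {
    msgs <- c(msgs, "patient ids (rownames) must be present and unique")
  }
  t <- object@totals
  if (!identical(colnames(t), c("jsn", "erosion", "overall")) ||
      !identical(rownames(t), rownames(p))) {
    msgs <- c(msgs, "totals must be a patients x c(jsn, erosion, overall) matrix")
  } else if (!all(is.finite(t)) || any(t < 0)) {
    msgs <- c(msgs, "totals must be finite and >= 0")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' BootstrapMatrix: metric values over patient-level bootstrap resamples
#'
#' Row b holds every submission's weighted RMSE computed on the b-th
#' resample (with replacement, full cohort size). The same resample is
#' shared by all teams within an iteration, and the resample indices are
#' kept for audit.
#'
#' @slot subchallenge "sc1", "sc2" or "sc3".
#' @slot B number of bootstrap iterations.
#' @slot values B x n_teams numeric matrix, colnames = team ids.
#' @slot seed the seed the resamples were drawn from (NA if indices were
#'   supplied directly).
#' @slot indices B x n_patients integer matrix of resampled row positions.
#' @export
setClass("BootstrapMatrix",
         representation(subchallenge = "character", B = "integer",
                        values = "matrix", seed = "integer",
                        indices = "matrix"))

setValidity("BootstrapMatrix", function(object) {
  if (!object@subchallenge %in% .SUBCHALLENGES) return("unknown subchallenge")
  if (nrow(object@values) != object@B || nrow(object@indices) != object@B) {
    return("values and indices must have B rows")
  }
  if (is.null(colnames(object@values))) return("values must carry team ids as colnames")
  TRUE
})

#' @describeIn BootstrapMatrix-class `$` access to slots (`subchallenge`,
#'   `B`, `values`, `seed`, `indices`).
#' @param x,name slot access.
#' @export
setMethod("$", "BootstrapMatrix", function(x, name) slot(x, name))

#' BayesFactorReport: bootstrap Bayes factors versus a reference submission
#'
#' For each team, K = (#iterations the reference is strictly better) /
#' (#iterations the team is strictly better), exact ties excluded from both
#' counts. K > 3 classifies the team as worse than the reference, K < 1/3
#' as better, anything in between (including K = 3 exactly) as tied. When
#' both counts are zero (identical metric vectors, e.g. the reference
#' against itself) K is reported as 1 and the team is tied by construction.
#'
#' @slot reference reference team id.
#' @slot table data.frame with columns `team_id`, `bayes_factor`,
#'   `n_reference_better`, `n_team_better`, `n_ties`, `classification`.
#' @export
setClass("BayesFactorReport",
         representation(reference = "character", table = "data.frame"))

setValidity("BayesFactorReport", function(object) {
  tb <- object@table
  need <- c("team_id", "bayes_factor", "n_reference_better", "n_team_better",
            "n_ties", "classification")
  if (!all(need %in% names(tb))) return("malformed report table")
  if (!all(tb$classification %in% c("better", "tied", "worse"))) {
    return("classification must be better/tied/worse")
  }
  ref <- tb[tb$team_id == object@reference, ]
  if (nrow(ref) == 1L && ref$classification != "tied") {
    return("reference must be classified tied against itself")
  }
  TRUE
})

#' @describeIn BayesFactorReport-class `$` access to slots (`reference`,
#'   `table`).
#' @param x,name slot access.
#' @export
setMethod("$", "BayesFactorReport", function(x, name) slot(x, name))

#' EnsembleSeries: cumulative top-k mean-ensemble evaluation
#'
#' @slot subchallenge "sc1", "sc2" or "sc3".
#' @slot members team ids in rank order (ensemble k averages members 1..k).
#' @slot table data.frame with one row per k: `k`, `members`,
#'   `weighted_rmse`, `spearman`, `bayes_factor`, `classification`
#'   (Bayes-factor call of the ensemble relative to the top individual
#'   model; "better" means the ensemble outperformed it).
#' @slot ensembles list of the k [SubmissionSet-class] ensembles.
#' @export
setClass("EnsembleSeries",
         representation(subchallenge = "character", members = "character",
                        table = "data.frame", ensembles = "list"))

#' @describeIn EnsembleSeries-class `$` access to slots (`subchallenge`,
#'   `members`, `table`, `ensembles`).
#' @param x,name slot access.
#' @export
setMethod("$", "EnsembleSeries", function(x, name) slot(x, name))

setMethod("show", "JointAreaRegistry", function(object) {
  a <- object@areas
  cat("JointAreaRegistry with", nrow(a), "scored locations\n")
  tab <- table(a$damage_type, a$region)
  print(tab)
  cat("maximum total score:", sum(a$max_score), "\n")
})

setMethod("show", "ScoreCohort", function(object) {
  tot <- overallTotals(object)
  cat("ScoreCohort:", nrow(object@scores), "patients x",
      ncol(object@scores), "joint areas\n")
  cat("overall totals: median", stats::median(tot),
      " range [", min(tot), ",", max(tot), "]\n")
})

setMethod("show", "SubmissionSet", function(object) {
  cat("SubmissionSet '", object@team_id, "': ", nrow(object@predictions),
      " patients x ", ncol(object@predictions), " joint areas\n", sep = "")
})

setMethod("show", "BootstrapMatrix", function(object) {
  cat("BootstrapMatrix (", object@subchallenge, "): B = ", object@B,
      ", teams = ", ncol(object@values), "\n", sep = "")
})

setMethod("show", "BayesFactorReport", function(object) {
  cat("BayesFactorReport (reference:", object@reference, ")\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "EnsembleSeries", function(object) {
  cat("EnsembleSeries (", object@subchallenge, "), k = 1..",
      length(object@members), "\n", sep = "")
  print(object@table[c("k", "weighted_rmse", "spearman", "classification")],
        row.names = FALSE)
})
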
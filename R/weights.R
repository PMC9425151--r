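#' The 8-bin patient-weighting scheme
#'
#' Patients are binned by their ground-truth overall SvH total into the
#' ranges 0, 1, 2-3, 4-7, 8-20, 21-55, 56-148 and >148. Each bin carries a
#' threshold — the natural log of its upper limit, except the first two
#' bins (thresholds 0 and 1) and the open-ended bin (threshold 6) — and a
#' patient weight of 2^threshold. Rounded to printed precision the
#' thresholds are 0, 1, 1.1, 1.95, 3, 4, 5, 6. The weighting damps the
#' influence of the extremes of the 0-448 score range on the evaluation
#' metric.
#'
#' @return data.frame with one row per bin: `index` (0-7), `label`,
#'   `lower`, `upper` (Inf for the open-ended bin), `threshold`, `weight`.
#' @examples
#' weightBins()
#' @export
weightBins <- function() {
  lower <- c(0, 1, 2, 4, 8, 21, 56, 149)
  upper <- c(0, 1, 3, 7, 20, 55, 148, Inf)
  threshold <- c(0, 1, log(3), log(7), log(20), log(55), log(148), 6)
  data.frame(index = 0:7,
             label = c("0", "1", "2-3", "4-7", "8-20", "21-55", "56-148", ">148"),
             lower = lower, upper = upper,
             threshold = threshold, weight = 2^threshold)
}

# 0-based bin index for non-negative (possibly real-valued) overall totals.
# Real values are bucketed by the integer range containing their floor,
# i.e. the half-open convention [lower, upper + 1).
.bin_index <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("overall totals must be finite and >= 0")
  }
  findInterval(floor(x), weightBins()$lower) - 1L
}

#' Assign overall totals to weight bins
#'
#' @param overall_total numeric vector of non-negative overall SvH totals;
#'   real values fall in the bin whose integer range contains their floor.
#' @return data.frame of the matching [weightBins()] rows (one per input).
#' @examples
#' assignBin(c(0, 7, 448))$label   # "0", "4-7", ">148"
#' @export
assignBin <- function(overall_total) {
  bins <- weightBins()
  out <- bins[.bin_index(overall_total) + 1L, ]
  rownames(out) <- NULL
  out
}

#' Threshold of a weight bin
#'
#' @param bin_index integer bin index (0-7).
#' @return the bin threshold: 0 and 1 for the first two bins, the natural
#'   log of the bin's upper limit for bins 2-6, and 6 for the open-ended
#'   bin.
#' @export
binThreshold <- function(bin_index) {
  if (any(bin_index != floor(bin_index)) || any(bin_index < 0) || any(bin_index > 7)) {
    stop("bin_index must be an integer in 0..7")
  }
  weightBins()$threshold[bin_index + 1L]
}

#' Patient weight from the ground-truth overall total
#'
#' w = 2^threshold of the bin containing the patient's ground-truth overall
#' SvH total. Weights are a property of the truth cohort, so every
#' submission is scored under identical weights.
#'
#' @param x a [ScoreCohort-class] (weights for every patient) or a numeric
#'   vector of overall totals.
#' @return numeric weights.
#' @examples
#' patientWeight(c(0, 5, 300))   # 1, 2^ln(7), 64
#' @rdname patientWeight
#' @export
setGeneric("patientWeight", function(x) standardGeneric("patientWeight"))

#' @rdname patientWeight
setMethod("patientWeight", "numeric", function(x) 2^binThreshold(.bin_index(x)))

#' @rdname patientWeight
setMethod("patientWeight", "ScoreCohort", function(x) patientWeight(overallTotals(x)))
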
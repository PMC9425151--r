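# Small cohorts built in code for the unit tests.

REG <- svhRegistry()
N_AREAS <- nrow(jointAreas(REG))

# A cohort of uniformly random legal integer scores (heavier damage than
# the generator's zero-inflated cohorts; handy for exercising all bins).
random_cohort <- function(n, seed = 1, min_score = 0) {
  caps <- jointAreas(REG)$max_score
  withr::with_seed(seed, {
    m <- vapply(caps, function(cap) sample(min_score:cap, n, replace = TRUE),
                numeric(n))
    if (n == 1) m <- matrix(m, nrow = 1)
  })
  dimnames(m) <- list(sprintf("pt%03d", seq_len(n)), jointAreas(REG)$area_id)
  scoreCohort(m, REG)
}

# An all-zero ("healthy") cohort.
zero_cohort <- function(n) {
  m <- matrix(0, n, N_AREAS,
              dimnames = list(sprintf("pt%03d", seq_len(n)),
                              jointAreas(REG)$area_id))
  scoreCohort(m, REG)
}

# Submission wrapping an explicit prediction matrix.
as_submission <- function(team, pred, truth) {
  dimnames(pred) <- dimnames(scoreMatrix(truth))
  submissionSet(team, pred, registry = registry(truth))
}

# The truth echoed back as a (perfect) submission.
perfect_submission <- function(truth, team = "perfect") {
  as_submission(team, scoreMatrix(truth), truth)
}

# Bootstrap matrix built directly from a values matrix (for Bayes-factor
# boundary cases).
raw_bootstrap <- function(values, subchallenge = "sc1") {
  new("BootstrapMatrix", subchallenge = subchallenge, B = nrow(values),
      values = values, seed = NA_integer_,
      indices = matrix(1L, nrow(values), 2))
}
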
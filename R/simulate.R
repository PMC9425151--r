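#' Configuration of a synthetic SvH cohort
#'
#' The generator emulates the qualitative shape of real SvH cohorts:
#' zero-inflated (a fraction of patients has no RA-related damage at all),
#' right-skewed patient totals spanning 0 to several hundred, and per-joint
#' overdispersion. Each damaged patient carries a log-normal latent
#' severity L; each joint area then draws a beta-binomial score with cap
#' `max_score` and mean `max_score * min(1, L/448)`, so the expected
#' overall total of a patient is about L. Defaults give a median total
#' near 15 with quartiles roughly 6-36.
#'
#' @param n_patients cohort size.
#' @param seed RNG seed.
#' @param zero_inflation probability a patient is entirely damage-free.
#' @param severity_meanlog,severity_sdlog meanlog/sdlog of the log-normal
#'   latent severity (score-point scale).
#' @param dispersion per-joint beta-binomial overdispersion (0 = pure
#'   binomial; larger = more joint-to-joint heterogeneity).
#' @return a validated `cohort_config` list.
#' @export
cohortConfig <- function(n_patients, seed = 1L, zero_inflation = 0.10,
                         severity_meanlog = log(15), severity_sdlog = 1.3,
                         dispersion = 0.05) {
  stopifnot(length(n_patients) == 1L, n_patients >= 1,
            n_patients == floor(n_patients),
            zero_inflation >= 0, zero_inflation <= 1,
            is.finite(severity_meanlog), severity_sdlog >= 0, dispersion >= 0)
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 zero_inflation = zero_inflation,
                 severity_meanlog = severity_meanlog,
                 severity_sdlog = severity_sdlog, dispersion = dispersion),
            class = "cohort_config")
}

#' Configuration of a simulated team's prediction noise
#'
#' A team's prediction for a joint with true score s is
#' `max(0, expm1(log1p(s) + eps))` with
#' `eps = bias + sd * (sqrt(1 - shared_weight) * z_team +
#' sqrt(shared_weight) * z_shared)`: z_team is the team's private standard
#' normal error field and z_shared a cohort-level common field determined
#' by `shared_seed` alone, so two teams with the same `shared_seed` and
#' `shared_weight = w` have log-scale error correlation w (and identical
#' error fields at w = 1). `sd = 0, bias = 0` reproduces the truth exactly.
#'
#' @param team_id team label.
#' @param sd log-scale error standard deviation (>= 0).
#' @param bias additive log-scale bias.
#' @param shared_weight correlation weight in \[0, 1\] mixing the shared
#'   error field into the team's errors.
#' @param rounding if TRUE, predictions are rounded to integers and clipped
#'   to the joint-area caps (a team submitting discrete scores).
#' @param seed team-private RNG seed.
#' @param shared_seed seed of the cohort-level common error field.
#' @return a validated `team_noise_config` list.
#' @export
teamNoiseConfig <- function(team_id, sd = 0.3, bias = 0, shared_weight = 0,
                            rounding = FALSE, seed = 1L, shared_seed = 1L) {
  stopifnot(sd >= 0, is.finite(bias), shared_weight >= 0, shared_weight <= 1,
            is.logical(rounding))
  structure(list(team_id = as.character(team_id), sd = sd, bias = bias,
                 shared_weight = shared_weight, rounding = rounding,
                 seed = as.integer(seed), shared_seed = as.integer(shared_seed)),
            class = "team_noise_config")
}

#' Generate a synthetic ground-truth cohort
#'
#' @param config a [cohortConfig()].
#' @param registry a [JointAreaRegistry-class].
#' @return a [ScoreCohort-class]; deterministic given the config (same
#'   config, same cohort, byte-identical CSV output).
#' @examples
#' truth <- generateCohort(cohortConfig(20, seed = 7))
#' summary(overallTotals(truth))
#' @export
generateCohort <- function(config, registry = svhRegistry()) {
  stopifnot(inherits(config, "cohort_config"))
  a <- registry@areas
  n <- config$n_patients
  max_total <- sum(a$max_score)
  scores <- .with_seed(config$seed, {
    healthy <- stats::rbinom(n, 1, config$zero_inflation) == 1
    L <- stats::rlnorm(n, config$severity_meanlog, config$severity_sdlog)
    L[healthy] <- 0
    p <- pmin(1, L / max_total)
    m <- matrix(0L, n, nrow(a))
    for (j in seq_len(nrow(a))) {
      pj <- p
      if (config$dispersion > 0) {
        prec <- 1 / config$dispersion
        inner <- p > 0 & p < 1
        if (any(inner)) {
          pj[inner] <- stats::rbeta(sum(inner), p[inner] * prec,
                                    (1 - p[inner]) * prec)
        }
      }
      m[, j] <- stats::rbinom(n, a$max_score[j], pj)
    }
    m
  })
  dimnames(scores) <- list(sprintf("P%04d", seq_len(n)), a$area_id)
  scoreCohort(scores, registry)
}

#' Simulate one team's submission from a truth cohort
#'
#' Applies the log-scale error model of [teamNoiseConfig()] to every joint
#' area; the team's patient-level sub-total predictions are the row sums of
#' its per-joint predictions. Predictions are clipped at 0 (which slightly
#' shrinks errors on zero-score joints).
#'
#' @param truth a [ScoreCohort-class].
#' @param noise a [teamNoiseConfig()].
#' @return a [SubmissionSet-class]; deterministic given truth and config.
#' @export
generateSubmission <- function(truth, noise) {
  stopifnot(is(truth, "ScoreCohort"), inherits(noise, "team_noise_config"))
  s <- truth@scores
  z_shared <- .with_seed(noise$shared_seed,
                         matrix(stats::rnorm(length(s)), nrow(s), ncol(s)))
  z_team <- .with_seed(noise$seed,
                       matrix(stats::rnorm(length(s)), nrow(s), ncol(s)))
  eps <- noise$bias + noise$sd * (sqrt(1 - noise$shared_weight) * z_team +
                                  sqrt(noise$shared_weight) * z_shared)
  pred <- pmax(expm1(log1p(s) + eps), 0)
  if (noise$rounding) {
    caps <- truth@registry@areas$max_score
    pred <- pmin(round(pred), matrix(caps, nrow(pred), ncol(pred), byrow = TRUE))
  }
  dimnames(pred) <- dimnames(s)
  submissionSet(noise$team_id, pred, registry = truth@registry)
}

#' Simulate two independent expert readers
#'
#' Perturbs the truth scores with independent per-joint Gaussian noise on
#' the raw score scale, rounds to integers and clips to `[0, max_score]`,
#' yielding two legal integer score cohorts — the structure of a validation
#' set scored by two readers, whose mean is the validation ground truth.
#'
#' @param truth a [ScoreCohort-class].
#' @param reader_sds length-2 numeric, raw-score noise SD per reader.
#' @param seed RNG seed (the two readers use seed and seed + 1).
#' @return list with elements `reader1` and `reader2`
#'   ([ScoreCohort-class]s).
#' @export
generateReaderPair <- function(truth, reader_sds = c(0.5, 0.5), seed = 1L) {
  stopifnot(is(truth, "ScoreCohort"), length(reader_sds) == 2L,
            all(reader_sds >= 0))
  s <- truth@scores
  caps <- matrix(truth@registry@areas$max_score, nrow(s), ncol(s), byrow = TRUE)
  perturb <- function(sd, sd_seed) {
    noisy <- .with_seed(sd_seed, s + stats::rnorm(length(s), sd = sd))
    m <- pmin(pmax(round(noisy), 0), caps)
    dimnames(m) <- dimnames(s)
    scoreCohort(m, truth@registry)
  }
  list(reader1 = perturb(reader_sds[1], seed),
       reader2 = perturb(reader_sds[2], seed + 1L))
}
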
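test_that("generateCohort honors zero inflation, seeds and degenerate limits", {
  all_zero <- generateCohort(cohortConfig(15, seed = 1, zero_inflation = 1))
  expect_true(all(overallTotals(all_zero) == 0))

  c1 <- generateCohort(cohortConfig(25, seed = 7))
  c2 <- generateCohort(cohortConfig(25, seed = 7))
  expect_identical(scoreMatrix(c1), scoreMatrix(c2))
  c3 <- generateCohort(cohortConfig(25, seed = 8))
  expect_false(identical(scoreMatrix(c1), scoreMatrix(c3)))

  # vanishing severity scale drives every score to zero
  tiny <- generateCohort(cohortConfig(15, seed = 2, zero_inflation = 0,
                                      severity_meanlog = -20, severity_sdlog = 0))
  expect_true(all(overallTotals(tiny) == 0))

  expect_error(cohortConfig(10, zero_inflation = 1.5))
  expect_error(cohortConfig(0))
})

test_that("every generated cohort is a valid score sheet collection", {
  withr::with_seed(201, {
    configs <- replicate(25, cohortConfig(
      n_patients = sample(1:40, 1), seed = sample(1e6, 1),
      zero_inflation = runif(1), severity_meanlog = runif(1, 0, 5),
      severity_sdlog = runif(1, 0, 2), dispersion = runif(1, 0, 0.5)),
      simplify = FALSE)
  })
  for (cfg in configs) {
    cohort <- generateCohort(cfg)
    expect_identical(nrow(validateScores(scoreMatrix(cohort), REG)), 0L)
    expect_true(all(overallTotals(cohort) <= 448))
  }
})

test_that("generated cohorts are right-skewed with totals spanning a wide range", {
  cohort <- generateCohort(cohortConfig(400, seed = 17))
  tot <- overallTotals(cohort)
  expect_gt(mean(tot), median(tot))        # right skew
  expect_gt(max(tot), 100)
  expect_true(any(tot == 0))               # zero-inflated
})

test_that("generateSubmission reproduces its configured error statistics", {
  truth <- random_cohort(20, seed = 211)
  exact <- generateSubmission(truth, teamNoiseConfig("e", sd = 0, bias = 0, seed = 1))
  expect_equal(weightedRMSE(truth, exact, "sc2")$value, 0, tolerance = 1e-12)
  expect_equal(scoreMatrix(exact), scoreMatrix(truth) * 1.0, tolerance = 1e-12)

  # empirical log-scale residual SD within 5% of sigma over ~10,000 terms;
  # scores >= 2 keep the clip-at-zero probability negligible
  big <- random_cohort(120, seed = 212, min_score = 2)
  sub <- generateSubmission(big, teamNoiseConfig("s", sd = 0.3, seed = 213))
  resid <- log1p(scoreMatrix(sub)) - log1p(scoreMatrix(big))
  expect_equal(sd(resid), 0.3, tolerance = 0.05)
  expect_equal(mean(resid), 0, tolerance = 0.01)

  # bias shifts the residual mean
  biased <- generateSubmission(big, teamNoiseConfig("b", sd = 0.1, bias = 0.25,
                                                    seed = 214))
  expect_equal(mean(log1p(scoreMatrix(biased)) - log1p(scoreMatrix(big))), 0.25,
               tolerance = 0.01)

  # full shared weight and a common shared seed give identical error fields
  t1 <- generateSubmission(truth, teamNoiseConfig("t1", sd = 0.3, shared_weight = 1,
                                                  seed = 5, shared_seed = 99))
  t2 <- generateSubmission(truth, teamNoiseConfig("t2", sd = 0.3, shared_weight = 1,
                                                  seed = 6, shared_seed = 99))
  expect_equal(scoreMatrix(t1), scoreMatrix(t2), tolerance = 1e-12)

  # partial shared weight induces the configured error correlation
  u1 <- generateSubmission(big, teamNoiseConfig("u1", sd = 0.3, shared_weight = 0.8,
                                                seed = 7, shared_seed = 42))
  u2 <- generateSubmission(big, teamNoiseConfig("u2", sd = 0.3, shared_weight = 0.8,
                                                seed = 8, shared_seed = 42))
  r1 <- log1p(scoreMatrix(u1)) - log1p(scoreMatrix(big))
  r2 <- log1p(scoreMatrix(u2)) - log1p(scoreMatrix(big))
  expect_equal(cor(as.vector(r1), as.vector(r2)), 0.8, tolerance = 0.05)
})

test_that("generateReaderPair yields legal, reproducible, noise-ordered readers", {
  truth <- generateCohort(cohortConfig(30, seed = 221))

  silent <- generateReaderPair(truth, reader_sds = c(0, 0), seed = 1)
  expect_identical(scoreMatrix(silent$reader1), scoreMatrix(truth))
  expect_equal(readerCV(silent$reader1, silent$reader2)$cv, 0)

  p1 <- generateReaderPair(truth, reader_sds = c(0.5, 0.7), seed = 31)
  p2 <- generateReaderPair(truth, reader_sds = c(0.5, 0.7), seed = 31)
  expect_identical(scoreMatrix(p1$reader1), scoreMatrix(p2$reader1))
  expect_identical(scoreMatrix(p1$reader2), scoreMatrix(p2$reader2))
  expect_identical(nrow(validateScores(p1$reader1, REG)), 0L)
  expect_identical(nrow(validateScores(p1$reader2, REG)), 0L)

  # increasing reader noise does not decrease the between-reader CV (trend
  # over 20 seeds). A damage-heavy cohort isolates the trend: on
  # zero-inflated cohorts the clip at 0 inflates both readers' totals and
  # confounds the relative-disagreement measure.
  damaged <- random_cohort(30, seed = 222)
  cv_at <- function(sd) {
    mean(vapply(1:20, function(s) {
      p <- generateReaderPair(damaged, reader_sds = c(sd, sd), seed = 1000 + s)
      readerCV(p$reader1, p$reader2)$cv
    }, numeric(1)))
  }
  expect_lt(cv_at(0.3), cv_at(1.2))
})

test_that("generation is deterministic end to end (byte-identical CSVs)", {
  dir <- withr::local_tempdir()
  write_once <- function(tag) {
    truth <- generateCohort(cohortConfig(12, seed = 55))
    sub <- generateSubmission(truth, teamNoiseConfig("t", sd = 0.4, seed = 56))
    tp <- file.path(dir, paste0("truth_", tag, ".csv"))
    sp <- file.path(dir, paste0("sub_", tag, ".csv"))
    writeScoresCsv(truth, tp); writeScoresCsv(sub, sp)
    c(tp, sp)
  }
  f1 <- write_once("a"); f2 <- write_once("b")
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))
})
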
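test_that("weightedRMSE is zero iff the submission matches the truth exactly", {
  truth <- random_cohort(5, seed = 11)
  perfect <- perfect_submission(truth)
  for (sc in c("sc1", "sc2", "sc3")) {
    expect_identical(weightedRMSE(truth, perfect, sc)$value, 0)
  }
  nudged <- scoreMatrix(truth)
  nudged[1, 1] <- nudged[1, 1] + 0.25
  expect_gt(weightedRMSE(truth, as_submission("t", nudged, truth), "sc2")$value, 0)
})

test_that("a unit log-residual on a weight-1 patient gives exactly 1", {
  # healthy patient (total 0, weight 1); overall prediction e - 1 makes the
  # single sc1 term |ln(e) - ln(1)| = 1
  truth <- zero_cohort(1)
  pred <- matrix(0, 1, N_AREAS)
  pred[1, 1] <- exp(1) - 1
  sub <- as_submission("t", pred, truth)
  res <- weightedRMSE(truth, sub, "sc1")
  expect_equal(res$value, 1, tolerance = 1e-12)
  expect_equal(res$n_terms, 1L)
})

test_that("weightedRMSE matches the loop oracle on mixed-bin toy cohorts", {
  for (seed in c(3, 14, 15)) {
    truth <- random_cohort(3, seed = seed)
    sub <- generateSubmission(truth, teamNoiseConfig("t", sd = 0.4, seed = seed + 1))
    for (sc in c("sc1", "sc2", "sc3")) {
      expect_equal(weightedRMSE(truth, sub, sc)$value, oracle_wrmse(truth, sub, sc),
                   tolerance = 1e-12)
    }
  }
})

test_that("weightedRMSE is invariant to patient order and weight rescaling", {
  truth <- random_cohort(6, seed = 21)
  sub <- generateSubmission(truth, teamNoiseConfig("t", sd = 0.3, seed = 22))
  v0 <- weightedRMSE(truth, sub, "sc2")$value

  perm <- c(4, 1, 6, 3, 2, 5)
  expect_equal(weightedRMSE(truth[perm], sub[perm], "sc2")$value, v0,
               tolerance = 1e-12)

  # duplicating the cohort doubles every weight; normalization cancels it
  dup <- c(1:6, 1:6)
  expect_equal(weightedRMSE(truth[dup], sub[dup], "sc2")$value, v0,
               tolerance = 1e-12)
})

test_that("increasing a single term's residual never decreases the metric", {
  truth <- random_cohort(4, seed = 31)
  base <- scoreMatrix(truth) * 1.0
  prev <- -Inf
  for (bump in c(0, 0.5, 1, 2, 4)) {
    pred <- base
    pred[2, 5] <- pred[2, 5] + bump
    v <- weightedRMSE(truth, as_submission("t", pred, truth), "sc2")$value
    expect_gte(v, prev)
    prev <- v
  }
})

test_that("spearmanMetric hits the exact anchors and the midrank oracle", {
  truth <- random_cohort(8, seed = 41)
  expect_equal(spearmanMetric(truth, perfect_submission(truth), "sc1"), 1)

  # order-reversing map of the overall totals
  tot <- overallTotals(truth)
  stopifnot(anyDuplicated(tot) == 0)
  rev_rank <- (max(tot) + min(tot)) - tot
  pred <- scoreMatrix(truth) * 0
  pred[, 1] <- rev_rank   # overall total = rev_rank, reversing the order
  expect_equal(spearmanMetric(truth, as_submission("t", pred, truth), "sc1"), -1)

  # tie-heavy integer predictions against the hand-rolled midrank formula
  sub <- generateSubmission(truth, teamNoiseConfig("t", sd = 0.5, seed = 42,
                                                   rounding = TRUE))
  tm_truth <- as.vector(scoreMatrix(truth)[, jointAreas(REG, "jsn")$area_id])
  tm_pred <- as.vector(scoreMatrix(sub)[, jointAreas(REG, "jsn")$area_id])
  expect_equal(spearmanMetric(truth, sub, "sc2"),
               oracle_spearman(tm_pred, tm_truth), tolerance = 1e-12)

  expect_warning(v <- spearmanMetric(truth, as_submission("t", pred * 0, truth), "sc2"),
                 "constant")
  expect_true(is.na(v))
})

test_that("concordanceIndex anchors at 1, 0 and enumerated pair fractions", {
  x <- c(a = 0.3, b = 0.5, c = 0.9, d = 1.4)
  expect_equal(concordanceIndex(x, x), 1)
  expect_equal(concordanceIndex(x, -x), 0)
  # 3 teams, exactly one discordant pair
  expect_equal(concordanceIndex(c(1, 2, 3), c(1, 3, 2)), 2 / 3)
  # ties in one list count half
  expect_equal(concordanceIndex(c(1, 2, 3), c(5, 5, 6)), (0.5 + 1 + 1) / 3)
  expect_error(concordanceIndex(1, 2), "2 teams")
  expect_error(concordanceIndex(c(a = 1, b = 2), c(a = 1, z = 2)))
})

test_that("concordanceIndex of independent random orderings averages 0.5", {
  vals <- withr::with_seed(99, replicate(1000, {
    concordanceIndex(runif(6), runif(6))
  }))
  expect_equal(mean(vals), 0.5, tolerance = 0.05)
})

test_that("concordanceIndex agrees with survival::concordance on tie-free data", {
  skip_if_not_installed("survival")
  withr::with_seed(7, {
    for (i in 1:10) {
      a <- rnorm(12); b <- rnorm(12)
      ref <- survival::concordance(b ~ a)$concordance
      expect_equal(concordanceIndex(a, b), ref, tolerance = 1e-12)
    }
  })
})

test_that("flagOutliers applies the discrepancy rule deterministically", {
  truth <- random_cohort(5, seed = 51)
  expect_identical(nrow(flagOutliers(truth, perfect_submission(truth), "sc2")), 0L)

  # a single JSN joint off by its full cap is flagged at any cutoff <= cap
  pred <- scoreMatrix(truth) * 1.0
  jsn1 <- jointAreas(REG, "jsn")$area_id[1]
  pred[3, jsn1] <- if (pred[3, jsn1] >= 4) pred[3, jsn1] - 4 else pred[3, jsn1] + 4
  sub <- as_submission("t", pred, truth)
  for (cutoff in c(1, 2, 4)) {
    fl <- flagOutliers(truth, sub, "sc2", cutoff = cutoff)
    expect_equal(nrow(fl), 1L)
    expect_equal(fl$area_id, jsn1)
  }
  expect_identical(nrow(flagOutliers(truth, sub, "sc3", cutoff = 1)), 0L)

  # flag count is non-increasing in the cutoff
  noisy <- generateSubmission(truth, teamNoiseConfig("n", sd = 0.8, seed = 52))
  counts <- vapply(c(0.5, 1, 2, 3, 5),
                   function(ct) nrow(flagOutliers(truth, noisy, "sc2", cutoff = ct)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(flagOutliers(truth, noisy, "sc2", cutoff = 0))
})

test_that("outlierRate reproduces printed percentage arithmetic", {
  expect_equal(outlierRate(201, 7896), 2.5)
  expect_equal(outlierRate(462, 8272), 5.6)
  expect_equal(outlierRate(97, 7896), 1.2)
  expect_equal(outlierRate(192, 8272), 2.3)
  expect_equal(outlierRate(0, 7896), 0.0)
  expect_error(outlierRate(1, 0))
  expect_error(outlierRate(5, 4))
})

test_that("readerCV matches closed forms and the per-pair oracle", {
  truth <- random_cohort(10, seed = 61)
  expect_equal(readerCV(truth, truth)$cv, 0)

  # pair (a, 3a): per-patient CV is sqrt(2)/2 regardless of a
  a <- c(2, 10, 50, 100)
  res <- readerCV(a, 3 * a)
  expect_equal(res$cv, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(res$n_used, 4L)

  # zero-mean pairs are excluded and counted
  res0 <- readerCV(c(0, 4), c(0, 6))
  expect_equal(res0$n_excluded, 1L)
  expect_equal(res0$cv, (abs(4 - 6) / sqrt(2)) / 5)

  # random readers against a brute-force per-pair mean
  withr::with_seed(62, {
    r1 <- rpois(30, 20); r2 <- rpois(30, 20)
  })
  brute <- mean(sapply(which((r1 + r2) > 0), function(i) {
    sd(c(r1[i], r2[i])) / mean(c(r1[i], r2[i]))
  }))
  expect_equal(readerCV(r1, r2)$cv, brute, tolerance = 1e-12)
})
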
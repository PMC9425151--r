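# Naive loop-based reference implementations, kept independent of the
# package code paths they check: bin thresholds are hard-coded if-chains,
# statistics are written out elementwise.

oracle_threshold <- function(total) {
  t <- floor(total)
  if (t <= 0) 0
  else if (t == 1) 1
  else if (t <= 3) log(3)
  else if (t <= 7) log(7)
  else if (t <= 20) log(20)
  else if (t <= 55) log(55)
  else if (t <= 148) log(148)
  else 6
}

oracle_weight <- function(total) 2^oracle_threshold(total)

# Weighted RMSE by explicit loops over patients and joint areas.
oracle_wrmse <- function(truth, submission, subchallenge) {
  s <- scoreMatrix(truth)
  y <- scoreMatrix(submission)[rownames(s), colnames(s), drop = FALSE]
  areas <- jointAreas(registry(truth))
  num <- 0; den <- 0
  for (p in seq_len(nrow(s))) {
    w <- oracle_weight(sum(s[p, ]))
    if (subchallenge == "sc1") {
      d <- log(1 + overallTotals(submission)[[rownames(s)[p]]]) - log(1 + sum(s[p, ]))
      num <- num + w * d^2
      den <- den + w
    } else {
      type <- if (subchallenge == "sc2") "jsn" else "erosion"
      for (j in seq_len(ncol(s))) {
        if (areas$damage_type[j] == type) {
          d <- log(1 + y[p, j]) - log(1 + s[p, j])
          num <- num + w * d^2
          den <- den + w
        }
      }
    }
  }
  sqrt(num / den)
}

oracle_midrank <- function(v) {
  r <- numeric(length(v))
  for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(rx)) {
    num <- num + (rx[i] - mx) * (ry[i] - my)
    dx <- dx + (rx[i] - mx)^2
    dy <- dy + (ry[i] - my)^2
  }
  num / sqrt(dx * dy)
}

oracle_concordance <- function(a, b) {
  n <- length(a)
  total <- 0; count <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    count <- count + 1
    if (a[i] == a[j] || b[i] == b[j]) total <- total + 0.5
    else if ((a[i] < a[j]) == (b[i] < b[j])) total <- total + 1
  }
  total / count
}

# K for one challenger column against a reference column of metric values.
oracle_bayes_factor <- function(ref, team) {
  ref_better <- 0; team_better <- 0
  for (b in seq_along(ref)) {
    if (ref[b] < team[b]) ref_better <- ref_better + 1
    else if (team[b] < ref[b]) team_better <- team_better + 1
  }
  if (ref_better == 0 && team_better == 0) 1
  else if (team_better == 0) Inf
  else ref_better / team_better
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[ord[i]] * n / i)
    q[ord[i]] <- running
  }
  q
}

# Two-sided paired t test p-value written out from the t statistic.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  2 * pt(-abs(tstat), df = n - 1)
}
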
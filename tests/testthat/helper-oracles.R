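# Independent brute-force oracles used to check the package's closed-form
# implementations. These deliberately re-derive everything from first
# principles (cell-by-cell sums of squares, covariance formulas) and never
# call the functions they check.

# Full sums-of-squares decomposition of an n x k repeated-measures matrix,
# written as explicit loops over cells.
oracle_rm_anova <- function(y) {
  n <- nrow(y); k <- ncol(y)
  gm <- sum(y) / (n * k)
  ss_time <- 0; ss_subj <- 0; ss_tot <- 0
  for (j in 1:k) ss_time <- ss_time + n * (mean(y[, j]) - gm)^2
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(y[i, ]) - gm)^2
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (y[i, j] - gm)^2
  ss_err <- ss_tot - ss_time - ss_subj
  Fstat <- (ss_time / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(F = Fstat,
       p = stats::pf(Fstat, k - 1, (n - 1) * (k - 1), lower.tail = FALSE),
       eta2p = ss_time / (ss_time + ss_err),
       ss_time = ss_time, ss_subj = ss_subj, ss_err = ss_err)
}

# Cronbach's alpha straight from the item covariance matrix:
# alpha = k/(k-1) * (1 - tr(S)/sum(S))
oracle_alpha <- function(y) {
  S <- stats::cov(y)
  k <- ncol(y)
  k / (k - 1) * (1 - sum(diag(S)) / sum(S))
}

# Average-measures consistency ICC from mean squares computed by explicit
# two-way decomposition.
oracle_icc_avg <- function(y) {
  d <- oracle_rm_anova(y)
  n <- nrow(y); k <- ncol(y)
  ms_subj <- d$ss_subj / (n - 1)
  ms_err <- d$ss_err / ((n - 1) * (k - 1))
  (ms_subj - ms_err) / ms_subj
}

# Paired t-test p-value computed from scratch.
oracle_paired_p <- function(x1, x2) {
  d <- x2 - x1
  tt <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  2 * stats::pt(abs(tt), df = length(d) - 1, lower.tail = FALSE)
}

# The 20 training-day intensity percentages of the default cycle grid, in
# session order (week by week, Mon-Wed, Fri, Sat).
table2_pcts <- function() {
  c(85, 75, 95, 85, 78,
    96, 76, 80, 96, 80,
    98, 75, 98, 75, 98,
    93, 80, 100, 75, 83)
}

# Spreadsheet-style recomputation of one athlete's full cycle from the raw
# estimator constants, bypassing every package function.
oracle_cycle_totals <- function(K, weight) {
  vo2rel <- function(k) 3.134304e-7 * k^2 + 0.02077344 * k - 9.03125
  v <- 0.0014 * K + 0.1786
  vo2max <- vo2rel(K) * weight / 1000
  p <- table2_pcts() / 100
  speed <- p * v
  dist <- speed * 1200
  frac <- vo2rel((speed - 0.1786) / 0.0014) / vo2rel(K)
  vo2 <- vo2max * 20 * frac
  list(total_distance = sum(dist),
       total_load_distance = sum(frac * v * 1200),
       total_vo2 = sum(vo2),
       total_kcal = sum(5 * vo2),
       mean_load = 100 * mean(frac))
}
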
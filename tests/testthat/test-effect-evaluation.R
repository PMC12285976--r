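test_that("within-subjects ANOVA matches the brute-force decomposition and aov()", {
  toy <- matrix(c(3, 5, 4,
                  6, 8, 9,
                  2, 4, 5), nrow = 3, byrow = TRUE)
  fit <- rm_anova(toy)
  oracle <- oracle_rm_anova(toy)
  expect_equal(fit$F, oracle$F, tolerance = 1e-9)
  expect_equal(fit$p, oracle$p, tolerance = 1e-9)
  expect_equal(fit$eta2p, oracle$eta2p, tolerance = 1e-9)
  expect_equal(unname(fit$ss["error"]), oracle$ss_err, tolerance = 1e-9)
  expect_equal(fit$df1, 2)
  expect_equal(fit$df2, 4)

  # independent cross-check against the stock aov() error decomposition
  long <- data.frame(
    y = as.vector(toy),
    subject = factor(rep(1:3, times = 3)),
    time = factor(rep(1:3, each = 3))
  )
  a <- summary(stats::aov(y ~ time + Error(subject/time), data = long))
  tab <- a[["Error: subject:time"]][[1]]
  expect_equal(fit$F, tab["time", "F value"], tolerance = 1e-9)
  expect_equal(fit$p, tab["time", "Pr(>F)"], tolerance = 1e-9)

  set.seed(11)
  y <- matrix(rnorm(20 * 4, mean = rep(c(0, 1, 2, 1.5), each = 20)), 20, 4)
  fit2 <- rm_anova(y)
  oracle2 <- oracle_rm_anova(y)
  expect_equal(fit2$F, oracle2$F, tolerance = 1e-9)
  expect_equal(fit2$eta2p, oracle2$eta2p, tolerance = 1e-9)
})

test_that("ANOVA diagnostics and degenerate inputs are reported", {
  set.seed(3)
  y <- matrix(rnorm(14 * 5), 14, 5)
  fit <- rm_anova(y)
  expect_equal(nrow(fit$normality), 5)
  expect_true(all(fit$normality$shapiro_p > 0 & fit$normality$shapiro_p <= 1))
  expect_true(is.finite(fit$sphericity$p))
  expect_true(fit$eta2g <= fit$eta2p)

  # purely additive matrix: zero error variance
  additive <- outer(c(1, 2, 5), c(0, 3, 7), "+")
  expect_warning(fit_d <- rm_anova(additive), "zero within-subject")
  expect_true(fit_d$degenerate)
  expect_equal(fit_d$F, Inf)

  expect_error(rm_anova(matrix(c(1, NA, 3, 4), 2, 2)), "complete")
  expect_error(rm_anova(matrix(1:4, 4, 1)), "at least")
})

test_that("Greenhouse-Geisser correction rescales both df and cannot lower p", {
  set.seed(8)
  y <- matrix(rnorm(12 * 4), 12, 4) + rep(c(0, 0.5, 1, 0.2), each = 12)
  plain <- rm_anova(y)
  gg <- rm_anova(y, correction = "greenhouse-geisser")
  expect_equal(gg$F, plain$F)  # correction changes the reference, not F
  expect_true(gg$epsilon_gg > 1 / 3 && gg$epsilon_gg <= 1)
  expect_gte(gg$p, plain$p)
})

test_that("partial eta squared reconstructs from F and df", {
  expect_equal(round(partial_eta_sq(145, 4, 52), 3), 0.918)
  expect_equal(round(partial_eta_sq(47.1, 4, 52), 3), 0.784)
  expect_equal(partial_eta_sq(0, 4, 52), 0)
  expect_error(partial_eta_sq(-1, 4, 52), "f >= 0")
  expect_error(partial_eta_sq(5, 0, 52), "positive")
})

test_that("Bonferroni pairwise tests equal the manual paired-t oracle times C(T,2)", {
  set.seed(21)
  toy <- matrix(rnorm(9, mean = rep(c(0, 1, 3), each = 3)), 3, 3)
  out <- bonferroni_pairwise(toy)
  expect_equal(nrow(out), 3)
  for (i in seq_len(3)) {
    raw <- oracle_paired_p(toy[, out$t1[i]], toy[, out$t2[i]])
    expect_equal(out$p_raw[i], raw, tolerance = 1e-9)
    expect_equal(out$p_adj[i], min(1, raw * 3), tolerance = 1e-9)
  }
  # cross-check against the stock pairwise.t.test adjustment
  long <- data.frame(y = as.vector(toy), time = factor(rep(1:3, each = 3)))
  ref <- stats::pairwise.t.test(long$y, long$time, paired = TRUE,
                                p.adjust.method = "bonferroni")$p.value
  expect_equal(out$p_adj[out$t1 == 1 & out$t2 == 2], ref["2", "1"],
               tolerance = 1e-9)
  expect_equal(out$p_adj[out$t1 == 2 & out$t2 == 3], ref["3", "2"],
               tolerance = 1e-9)
})

test_that("identical timepoints give an adjusted p of exactly 1", {
  y <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(2, 3, 5, 6))
  out <- bonferroni_pairwise(y)
  dup <- out[out$t1 == 1 & out$t2 == 2, ]
  expect_equal(dup$t, 0)
  expect_equal(dup$p_adj, 1)
})

test_that("percent change matches the headline improvements", {
  expect_equal(round(percent_change(2324, 2946), 1), 26.8)
  expect_equal(round(percent_change(3.43, 4.3), 1), 25.4)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(c(2, 4), c(3, 2)), c(50, -50))
  expect_error(percent_change(0, 5), "nonzero")
})

test_that("alpha and average-measures ICC match the covariance-formula oracles", {
  toy <- matrix(c(10, 11,
                  12, 14,
                  9,  10,
                  15, 15), nrow = 4, byrow = TRUE)
  expect_equal(cronbach_alpha(toy), oracle_alpha(toy), tolerance = 1e-9)
  expect_equal(icc_average(toy)$icc, oracle_icc_avg(toy), tolerance = 1e-9)
  # consistency-form average-measures ICC is Cronbach's alpha
  expect_equal(icc_average(toy)$icc, cronbach_alpha(toy), tolerance = 1e-12)

  set.seed(31)
  y <- matrix(rnorm(5 * 5, mean = rep(rnorm(5, sd = 2), 5)), 5, 5)
  expect_equal(cronbach_alpha(y), oracle_alpha(y), tolerance = 1e-9)
  expect_equal(icc_average(y)$icc, oracle_icc_avg(y), tolerance = 1e-9)
})

test_that("perfectly duplicated measurements give unit reliability", {
  y <- cbind(c(1, 5, 9, 3), c(1, 5, 9, 3), c(1, 5, 9, 3))
  expect_equal(cronbach_alpha(y), 1)
  expect_equal(icc_average(y)$icc, 1)
  expect_error(cronbach_alpha(matrix(1, 4, 3)), "zero total variance")
})

test_that("ICC confidence interval brackets the estimate and respects Spearman-Brown", {
  set.seed(5)
  ch <- generate_cohort(cohort_spec(n = 14, seed = 5))
  ic <- icc_average(ch$data)
  expect_true(ic$lower < ic$icc && ic$icc < ic$upper)
  # rho = 0.8 over 5 measures: average-measures reliability 5*0.8/(1+4*0.8)
  set.seed(6)
  iccs <- replicate(60, icc_average(generate_cohort(cohort_spec())$data)$icc)
  expect_equal(mean(iccs), 5 * 0.8 / (1 + 4 * 0.8), tolerance = 0.02)
  expect_gt(mean(iccs), 0.9)
})

test_that("zone census tallies every profile exactly once", {
  t1 <- table1_fixture()
  census <- zone_census(t1$vo2rel)
  expect_equal(unname(census["below_elite"]), 14L, ignore_attr = TRUE)
  expect_equal(sum(census), 14)
  boundary <- zone_census(57.9)
  expect_equal(unname(boundary["world_class"]), 1L, ignore_attr = TRUE)
  prof <- aerobic_profile(c(2324, 2750), 72)
  expect_equal(sum(zone_census(prof)), 2)
  expect_error(zone_census(numeric(0)), "no profiles|positive")
})

test_that("power is monotone in n and the minimal n search is consistent", {
  pw <- power_at_n(2:30)
  expect_true(all(diff(pw) >= 0))
  n_req <- required_sample_size(target_power = 0.90)
  expect_gte(power_at_n(n_req), 0.90)
  expect_lt(power_at_n(n_req - 1), 0.90)
  expect_error(power_at_n(12, rho = 1), "rho")
  expect_error(power_at_n(12, effect_f = 0), "positive")
  expect_error(required_sample_size(target_power = 1.2), "target_power")
})
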
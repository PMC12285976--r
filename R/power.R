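# Design-stage power for the one-group within-factors repeated-measures
# F test, using the G*Power "ANOVA: repeated measures, within factors"
# convention: the repeated-measures correlation inflates the effective
# noncentrality by 1/(1 - rho).

#' Power of the within-subjects F test at a given sample size
#'
#' Noncentral-F power for a one-group repeated-measures design with `m`
#' measurements, Cohen effect size `f`, common between-measurement
#' correlation `rho` and nonsphericity correction `epsilon`:
#' noncentrality `lambda = f^2 * n * m * epsilon / (1 - rho)` on
#' `(m-1) * epsilon` and `(n-1)(m-1) * epsilon` degrees of freedom.
#'
#' @param n Number of subjects (vectorized), >= 2.
#' @param effect_f Cohen's f effect size (> 0); default 0.25 ("medium").
#' @param alpha Type-I error rate.
#' @param m Number of repeated measurements (>= 2).
#' @param rho Expected correlation among measurements, in [0, 1).
#' @param epsilon Nonsphericity correction in (1/(m-1), 1]; 1 = sphericity.
#' @return Power (probability of rejection) for each `n`.
#' @examples
#' power_at_n(12, effect_f = 0.25, alpha = 0.05, m = 5, rho = 0.8) # 0.926
#' @export
power_at_n <- function(n, effect_f = 0.25, alpha = 0.05, m = 5,
                       rho = 0.8, epsilon = 1) {
  if (any(n < 2)) stop("`n` must be at least 2", call. = FALSE)
  if (effect_f <= 0) stop("`effect_f` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (m < 2) stop("`m` must be at least 2", call. = FALSE)
  if (rho < 0 || rho >= 1) {
    stop("`rho` must be in [0, 1): a unit correlation leaves no error variance",
         call. = FALSE)
  }
  if (epsilon <= 1 / (m - 1) || epsilon > 1) {
    stop("`epsilon` must lie in (1/(m-1), 1]", call. = FALSE)
  }
  lambda <- effect_f^2 * n * m * epsilon / (1 - rho)
  df1 <- (m - 1) * epsilon
  df2 <- (n - 1) * (m - 1) * epsilon
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Smallest sample size reaching a target power
#'
#' Walks `n` upward until [power_at_n()] reaches `target_power`. Power is
#' nondecreasing in `n` for this design, so the first hit is the minimum.
#'
#' @inheritParams power_at_n
#' @param target_power Desired power (1 - beta), in (0, 1).
#' @param n_max Search ceiling (error if exceeded).
#' @return Minimal number of subjects.
#' @examples
#' required_sample_size(target_power = 0.90) # 12
#' @export
required_sample_size <- function(target_power = 0.90, effect_f = 0.25,
                                 alpha = 0.05, m = 5, rho = 0.8,
                                 epsilon = 1, n_max = 10000L) {
  if (target_power <= 0 || target_power >= 1) {
    stop("`target_power` must be in (0, 1)", call. = FALSE)
  }
  for (n in 2:n_max) {
    if (power_at_n(n, effect_f, alpha, m, rho, epsilon) >= target_power) {
      return(n)
    }
  }
  stop("no n <= ", n_max, " reaches the target power", call. = FALSE)
}
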
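# Longitudinal effect evaluation: one-way within-subjects ANOVA with effect
# sizes and assumption checks, Bonferroni pairwise tests, percent change,
# and test-retest reliability (Cronbach's alpha, average-measures ICC).

.as_rm_matrix <- function(data, min_n = 2L, min_t = 2L) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric athletes x timepoints matrix",
         call. = FALSE)
  }
  if (anyNA(data)) {
    stop("`data` must be complete (no missing cells)", call. = FALSE)
  }
  if (nrow(data) < min_n || ncol(data) < min_t) {
    stop("need at least ", min_n, " subjects and ", min_t, " timepoints",
         call. = FALSE)
  }
  data
}

#' Assemble a longitudinal dataset
#'
#' Tags an athletes × timepoints matrix of one aerobic variable with its
#' label and units. Analysis functions accept either this or a bare matrix.
#'
#' @param x Numeric matrix, one row per athlete, one column per timepoint.
#' @param variable Name of the measured variable (e.g. `"K"`).
#' @param units Measurement units (e.g. `"m"`).
#' @return The matrix with class `longitudinal_dataset` and attributes
#'   `variable`, `units`.
#' @export
longitudinal_dataset <- function(x, variable = "K", units = "m") {
  x <- .as_rm_matrix(x)
  structure(x, variable = variable, units = units,
            class = c("longitudinal_dataset", "matrix", "array"))
}

# Core sums-of-squares decomposition of the subjects x time layout.
# Returns everything rm_anova needs; kept lean so simulation loops are cheap.
.rm_ss <- function(y) {
  n <- nrow(y); k <- ncol(y)
  gm <- mean(y)
  col_m <- colMeans(y)
  row_m <- rowMeans(y)
  ss_time <- n * sum((col_m - gm)^2)
  ss_subj <- k * sum((row_m - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_time - ss_subj
  list(n = n, k = k, ss_time = ss_time, ss_subj = ss_subj,
       ss_err = ss_err, ss_tot = ss_tot)
}

# Greenhouse-Geisser epsilon from the double-centered covariance matrix.
.gg_epsilon <- function(y) {
  S <- stats::cov(y)
  k <- ncol(S)
  Sc <- sweep(S, 1, rowMeans(S))
  Sc <- sweep(Sc, 2, colMeans(S))
  Sc <- Sc + mean(S)
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' One-way within-subjects (repeated-measures) ANOVA
#'
#' Decomposes an athletes × timepoints matrix into time, subject and error
#' sums of squares and tests the time effect with `F = MS_time / MS_error`
#' on `(T-1, (n-1)(T-1))` degrees of freedom. Reports partial eta squared
#' `SS_time / (SS_time + SS_error)`, generalized eta squared
#' `SS_time / SS_total`, Shapiro–Wilk normality per timepoint and the
#' Mauchly sphericity test. No sphericity correction is applied by default;
#' `correction = "greenhouse-geisser"` rescales both degrees of freedom by
#' the Greenhouse–Geisser epsilon.
#'
#' @param data Athletes × timepoints matrix (or [longitudinal_dataset()]);
#'   complete, n >= 2, T >= 2.
#' @param correction `"none"` (default) or `"greenhouse-geisser"`.
#' @param checks If `FALSE`, skip the normality/sphericity diagnostics
#'   (useful inside simulation loops).
#' @return List of class `rm_anova`: `F`, `df1`, `df2`, `p`, `eta2p`,
#'   `eta2g`, `ss` (named vector), `epsilon_gg`, `sphericity` (Mauchly `W`
#'   and `p`, or `NA` when not estimable), `normality` (per-timepoint
#'   Shapiro–Wilk), `n`, `timepoints`, `degenerate`.
#' @examples
#' y <- generate_cohort(cohort_spec(n = 10, seed = 7))$data
#' rm_anova(y)
#' @export
rm_anova <- function(data, correction = c("none", "greenhouse-geisser"),
                     checks = TRUE) {
  correction <- match.arg(correction)
  y <- .as_rm_matrix(data)
  d <- .rm_ss(y)
  df1 <- d$k - 1
  df2 <- (d$n - 1) * (d$k - 1)
  ms_time <- d$ss_time / df1
  ms_err <- d$ss_err / df2
  degenerate <- ms_err <= .Machine$double.eps * d$ss_tot
  if (degenerate) {
    warning("zero within-subject error variance; F is unbounded",
            call. = FALSE)
    Fstat <- Inf
  } else {
    Fstat <- ms_time / ms_err
  }
  eps <- if (correction == "greenhouse-geisser") .gg_epsilon(y) else 1
  p <- stats::pf(Fstat, eps * df1, eps * df2, lower.tail = FALSE)
  normality <- NULL
  sphericity <- list(W = NA_real_, p = NA_real_)
  if (checks) {
    normality <- data.frame(
      timepoint = seq_len(d$k),
      shapiro_W = NA_real_, shapiro_p = NA_real_
    )
    if (d$n >= 3 && d$n <= 5000) {
      for (j in seq_len(d$k)) {
        sw <- tryCatch(stats::shapiro.test(y[, j]), error = function(e) NULL)
        if (!is.null(sw)) {
          normality$shapiro_W[j] <- unname(sw$statistic)
          normality$shapiro_p[j] <- sw$p.value
        }
      }
    }
    mt <- tryCatch(
      stats::mauchly.test(stats::lm(y ~ 1), X = ~1),
      error = function(e) NULL
    )
    if (!is.null(mt)) {
      sphericity <- list(W = unname(mt$statistic), p = mt$p.value)
    }
  }
  structure(
    list(
      F = Fstat, df1 = df1, df2 = df2, p = p,
      eta2p = d$ss_time / (d$ss_time + d$ss_err),
      eta2g = d$ss_time / d$ss_tot,
      ss = c(time = d$ss_time, subject = d$ss_subj,
             error = d$ss_err, total = d$ss_tot),
      epsilon_gg = if (correction == "greenhouse-geisser") eps else NA_real_,
      correction = correction,
      sphericity = sphericity,
      normality = normality,
      n = d$n, timepoints = d$k,
      degenerate = degenerate
    ),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("One-way within-subjects ANOVA\n")
  cat(sprintf("  F(%g, %g) = %.3f, p = %.4g\n", x$df1, x$df2, x$F, x$p))
  cat(sprintf("  partial eta^2 = %.3f, generalized eta^2 = %.3f\n",
              x$eta2p, x$eta2g))
  if (!is.na(x$sphericity$p)) {
    cat(sprintf("  Mauchly W = %.3f, p = %.3g\n",
                x$sphericity$W, x$sphericity$p))
  }
  if (x$degenerate) cat("  [degenerate: zero error variance]\n")
  invisible(x)
}

#' Partial eta squared from an F statistic
#'
#' `eta2p = F * df1 / (F * df1 + df2)` — the algebraic identity linking the
#' within-subjects F statistic to its effect size.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (> 0).
#' @return Partial eta squared in [0, 1).
#' @examples
#' partial_eta_sq(145, 4, 52) # 0.918
#' @export
partial_eta_sq <- function(f, df1, df2) {
  if (any(f < 0) || any(df1 <= 0) || any(df2 <= 0)) {
    stop("need f >= 0 and positive degrees of freedom", call. = FALSE)
  }
  f * df1 / (f * df1 + df2)
}

#' Bonferroni-adjusted pairwise comparisons between timepoints
#'
#' Paired t-test for every timepoint pair; raw p-values are multiplied by
#' the number of pairs `C(T, 2)` and capped at 1. A pair with identical
#' columns has zero mean difference and zero variance and is reported with
#' `t = 0`, `p = 1`.
#'
#' @inheritParams rm_anova
#' @return data.frame with one row per pair: `t1`, `t2`, `mean_diff`,
#'   `t`, `df`, `p_raw`, `p_adj`.
#' @export
bonferroni_pairwise <- function(data) {
  y <- .as_rm_matrix(data)
  k <- ncol(y)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(
    t1 = pairs[1, ], t2 = pairs[2, ],
    mean_diff = NA_real_, t = NA_real_, df = nrow(y) - 1,
    p_raw = NA_real_, p_adj = NA_real_
  )
  for (i in seq_len(m)) {
    d <- y[, pairs[2, i]] - y[, pairs[1, i]]
    md <- mean(d)
    se <- stats::sd(d) / sqrt(length(d))
    if (se == 0) {
      tt <- if (md == 0) 0 else sign(md) * Inf
      p <- if (md == 0) 1 else 0
    } else {
      tt <- md / se
      p <- 2 * stats::pt(abs(tt), df = length(d) - 1, lower.tail = FALSE)
    }
    out$mean_diff[i] <- md
    out$t[i] <- tt
    out$p_raw[i] <- p
  }
  out$p_adj <- pmin(1, out$p_raw * m)
  out
}

#' Percent change
#'
#' `100 * (after - before) / before`. Vectorized; errors on a zero
#' baseline.
#'
#' @param before,after Numeric values; `before` must be nonzero.
#' @return Percent change.
#' @examples
#' percent_change(2324, 2946) # 26.8
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) stop("`before` must be nonzero", call. = FALSE)
  100 * (after - before) / before
}

#' Cronbach's alpha across timepoints
#'
#' Internal-consistency reliability of the T repeated measurements, from
#' the item-covariance formula
#' `alpha = T/(T-1) * (1 - sum(var_t) / var(total))`.
#'
#' @param data Athletes × timepoints matrix, n >= 3, T >= 2.
#' @return Alpha coefficient.
#' @export
cronbach_alpha <- function(data) {
  y <- .as_rm_matrix(data, min_n = 3L)
  k <- ncol(y)
  total_var <- stats::var(rowSums(y))
  if (total_var == 0) stop("zero total variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(y, 2, stats::var)) / total_var)
}

#' Average-measures intraclass correlation
#'
#' Two-way consistency ICC for the average of the T measurements
#' (Shrout–Fleiss ICC(C, k)): `(MS_subjects - MS_error) / MS_subjects`,
#' with an F-based confidence interval from `F = MS_subjects / MS_error` on
#' `(n-1, (n-1)(T-1))` degrees of freedom. Numerically identical to
#' Cronbach's alpha.
#'
#' @inheritParams cronbach_alpha
#' @param conf_level Confidence level for the interval.
#' @return List: `icc`, `conf_level`, `lower`, `upper`, `F`, `df1`, `df2`.
#' @export
icc_average <- function(data, conf_level = 0.95) {
  y <- .as_rm_matrix(data, min_n = 3L)
  d <- .rm_ss(y)
  df1 <- d$n - 1
  df2 <- (d$n - 1) * (d$k - 1)
  ms_subj <- d$ss_subj / df1
  ms_err <- d$ss_err / df2
  if (ms_subj == 0) stop("zero between-subject variance", call. = FALSE)
  Fobs <- ms_subj / ms_err
  alpha2 <- (1 - conf_level) / 2
  lower <- 1 - 1 / (Fobs / stats::qf(1 - alpha2, df1, df2))
  upper <- 1 - 1 / (Fobs * stats::qf(1 - alpha2, df2, df1))
  list(
    icc = 1 - ms_err / ms_subj,
    conf_level = conf_level,
    lower = lower, upper = upper,
    F = Fobs, df1 = df1, df2 = df2
  )
}

#' Tally aerobic profiles by performance zone
#'
#' @param profiles Either a data.frame with a `zone` column (as returned by
#'   [aerobic_profile()]/[cooper_profiles()]) or a vector of VO2rel values
#'   to classify first.
#' @return Named integer vector of counts over the four zones (counts sum
#'   to the number of profiles).
#' @examples
#' zone_census(c(50.4, 52.0, 58.3))
#' @export
zone_census <- function(profiles) {
  if (is.data.frame(profiles)) {
    if (is.null(profiles$zone)) {
      stop("`profiles` data.frame must have a `zone` column", call. = FALSE)
    }
    z <- factor(profiles$zone, levels = .zone_levels)
  } else {
    z <- classify_zone(profiles)
  }
  if (length(z) == 0) stop("no profiles to tally", call. = FALSE)
  table(z)
}
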
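# Seeded synthetic cohorts with the longitudinal structure the analyses
# assume: truncated-normal baselines, multiplicative per-cycle gains with
# diminishing increments, and an athlete-level random intercept inducing a
# fixed between-occasion correlation.

.default_gain_pattern <- function() {
  # cumulative gain multipliers: ratios of the occasion medians
  # 2360 -> 2657 -> 2808 -> 2946 -> 2943 relative to baseline
  c(2360, 2657, 2808, 2946, 2943) / 2360
}

#' Specification of a synthetic longitudinal cohort
#'
#' Collects the distributional parameters the generator honors. The default
#' gain pattern applies diminishing multiplicative improvements (≈ +12.6%,
#' +6.4%, +5.8%, −0.1% per interval); the defaults for baseline mean/SD,
#' correlation and anthropometrics describe an elite women's team-handball
#' squad measured on five occasions.
#'
#' @param n Number of athletes (>= 2).
#' @param timepoints Number of measurement occasions.
#' @param baseline_mean,baseline_sd Mean and total SD (m) of the Cooper
#'   distance at occasion 1.
#' @param gain_pattern Cumulative gain multipliers, length `timepoints`,
#'   first element 1.
#' @param rho Between-occasion correlation, in [0, 1).
#' @param noise_sd Occasion-level noise SD (m) at baseline; defaults to
#'   `baseline_sd * sqrt(1 - rho)` so the between-occasion correlation is
#'   exactly `rho` and the occasion-1 SD is exactly `baseline_sd`.
#' @param baseline_range Truncation bounds (m) for the athlete-level
#'   baseline.
#' @param weight_mean,weight_sd,weight_min Body-weight distribution (kg),
#'   truncated below.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 14, timepoints = 5,
                        baseline_mean = 2324, baseline_sd = 295,
                        gain_pattern = NULL, rho = 0.8,
                        noise_sd = NULL,
                        baseline_range = c(1200, 4000),
                        weight_mean = 72, weight_sd = 6.4, weight_min = 45,
                        seed = NULL) {
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  if (timepoints < 2) stop("`timepoints` must be at least 2", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("`rho` must be in [0, 1)", call. = FALSE)
  if (baseline_sd <= 0 || weight_sd <= 0) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  if (is.null(gain_pattern)) {
    g <- .default_gain_pattern()
    gain_pattern <- if (timepoints <= length(g)) g[seq_len(timepoints)] else
      c(g, rep(g[length(g)], timepoints - length(g)))
  }
  if (length(gain_pattern) != timepoints || gain_pattern[1] != 1 ||
      any(gain_pattern <= 0)) {
    stop("`gain_pattern` must have length `timepoints`, start at 1, ",
         "and stay positive", call. = FALSE)
  }
  if (is.null(noise_sd)) noise_sd <- baseline_sd * sqrt(1 - rho)
  if (noise_sd < 0 || noise_sd > baseline_sd) {
    stop("`noise_sd` must be in [0, baseline_sd]", call. = FALSE)
  }
  if (baseline_range[1] >= baseline_range[2]) {
    stop("invalid `baseline_range`", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), timepoints = as.integer(timepoints),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         gain_pattern = gain_pattern, rho = rho, noise_sd = noise_sd,
         baseline_range = baseline_range,
         weight_mean = weight_mean, weight_sd = weight_sd,
         weight_min = weight_min, seed = seed),
    class = "cohort_spec"
  )
}

# truncated-normal draw by rejection; bounds far enough out that this
# terminates quickly for every default
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    cand <- stats::rnorm(length(todo), mean, sd)
    ok <- cand >= lower & cand <= upper
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws athlete-level true baselines `b_i` from a truncated normal, then
#' builds Cooper distances `K[i, t] = G_t * (b_i + e[i, t])` with
#' occasion-independent noise `e` and cumulative gain multipliers `G_t`.
#' Scaling the noise by the gain keeps every between-occasion correlation
#' exactly at `rho`. Body weight, age and height are drawn per athlete from
#' truncated normals. Fixing `seed` makes the dataset bit-reproducible;
#' draw order is: baselines, occasion noise, weights, ages, heights.
#'
#' @param spec A [cohort_spec()].
#' @return List: `data` (a [longitudinal_dataset()] of Cooper distances,
#'   n × timepoints), `athletes` (data.frame `id`, `age`, `height_cm`,
#'   `weight_kg`), `cooper` (long data.frame `id`, `timepoint`,
#'   `distance_m`), and `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 14, seed = 1))
#' round(colMeans(cohort$data))
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) {
    stop("`spec` must be a cohort_spec()", call. = FALSE)
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  sd_b <- sqrt(spec$baseline_sd^2 - spec$noise_sd^2)
  b <- .rtruncnorm(spec$n, spec$baseline_mean, sd_b,
                   spec$baseline_range[1], spec$baseline_range[2])
  e <- matrix(stats::rnorm(spec$n * spec$timepoints, 0, spec$noise_sd),
              nrow = spec$n)
  K <- (b + e) %*% diag(spec$gain_pattern, nrow = spec$timepoints)
  K <- pmax(K, 433)  # keep inside the estimator domain
  ids <- sprintf("A%02d", seq_len(spec$n))
  dimnames(K) <- list(ids, paste0("t", seq_len(spec$timepoints)))
  weights <- .rtruncnorm(spec$n, spec$weight_mean, spec$weight_sd,
                         lower = spec$weight_min)
  ages <- round(.rtruncnorm(spec$n, 22.1, 3.4, lower = 16, upper = 40))
  heights <- round(.rtruncnorm(spec$n, 171.8, 3.3, lower = 150, upper = 195), 1)
  athletes <- data.frame(
    id = ids, age = ages, height_cm = heights,
    weight_kg = round(weights, 1)
  )
  cooper <- data.frame(
    id = rep(ids, times = spec$timepoints),
    timepoint = rep(seq_len(spec$timepoints), each = spec$n),
    distance_m = as.vector(K)
  )
  list(
    data = longitudinal_dataset(K, variable = "K", units = "m"),
    athletes = athletes,
    cooper = cooper[order(cooper$id, cooper$timepoint), ],
    spec = spec
  )
}

#' Reference squad fixture: initial aerobic status of 14 players
#'
#' The initial anthropometrics and aerobic parameters of a 14-player
#' professional women's team-handball squad (age, height, weight, absolute
#' and relative VO2max, maximal aerobic speed), as printed in the reference
#' description of the cohort. The Cooper distance consistent with each
#' player's maximal aerobic speed is added via [distance_from_velocity()].
#'
#' @return data.frame with columns `id`, `age`, `height_cm`, `weight_kg`,
#'   `vo2max`, `vo2rel`, `v_vo2max`, `distance_m` (14 rows).
#' @export
table1_fixture <- function() {
  df <- data.frame(
    id = as.character(1:14),
    age = c(29, 20, 24, 28, 21, 19, 17, 20, 20, 22, 25, 20, 24, 21),
    height_cm = c(173, 167.5, 175, 172, 172.5, 172, 172, 174, 177, 174,
                  168.5, 164, 172, 172),
    weight_kg = c(63, 60, 79, 74, 73, 72, 72, 75, 71, 75, 68, 67.5, 86, 72),
    vo2max = c(2.81, 2.7, 3.13, 3.29, 3.68, 3.4, 1.84, 2.57, 3, 3.13,
               2.77, 3.11, 2.94, 2.96),
    vo2rel = c(44.82, 45.05, 39.63, 44.4, 50.48, 47.22, 25.52, 34.2,
               42.23, 41.8, 40.71, 46.14, 34.2, 41.15),
    v_vo2max = c(3.65, 3.68, 3.33, 3.64, 4.03, 3.82, 2.42, 2.98, 3.5,
                 3.47, 3.4, 3.75, 2.98, 3.43)
  )
  df$distance_m <- distance_from_velocity(df$v_vo2max)
  df
}
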
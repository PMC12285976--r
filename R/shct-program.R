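# SHCT cycle programming: the 4-week x 7-day intensity template, per-session
# prescriptions, and cycle load accounting (distance, oxygen, kilocalories).

.SESSION_SECONDS <- 1200  # 20-min continuous run; warm-up/cool-down excluded
.WEEKDAYS <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
               "Saturday", "Sunday")

#' Default SHCT intensity template
#'
#' The standard four-week cycle grid: five sessions per week
#' (Monday–Wednesday, Friday, Saturday; Thursday and Sunday rest), each cell
#' the session intensity as a percentage of maximal aerobic speed (vVO2max).
#' The grid peaks (>= 95%) once in week I, twice in week II, three times in
#' week III and once in week IV.
#'
#' @return An `shct_template`: a 4×7 numeric matrix of intensity
#'   percentages, `NA` on rest days, rows `I`–`IV`, columns weekday names.
#' @examples
#' default_template()
#' @export
default_template <- function() {
  grid <- rbind(
    I   = c(85, 75,  95, NA, 85, 78, NA),
    II  = c(96, 76,  80, NA, 96, 80, NA),
    III = c(98, 75,  98, NA, 75, 98, NA),
    IV  = c(93, 80, 100, NA, 75, 83, NA)
  )
  colnames(grid) <- .WEEKDAYS
  as_shct_template(grid)
}

#' Coerce and validate an SHCT intensity template
#'
#' @param grid A 4×7 numeric matrix (weeks × weekdays) of intensity
#'   percentages in (0, 100], with `NA` marking rest days. Each week must
#'   hold exactly 5 training sessions.
#' @return The validated matrix with class `shct_template`.
#' @export
as_shct_template <- function(grid) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  if (!identical(dim(grid), c(4L, 7L))) {
    stop("template must be a 4-week x 7-day grid", call. = FALSE)
  }
  if (any(rowSums(!is.na(grid)) != 5L)) {
    stop("each template week must contain exactly 5 training sessions",
         call. = FALSE)
  }
  vals <- grid[!is.na(grid)]
  if (any(vals <= 0 | vals > 100)) {
    stop("template intensities must be percentages in (0, 100]",
         call. = FALSE)
  }
  if (is.null(rownames(grid))) rownames(grid) <- c("I", "II", "III", "IV")
  if (is.null(colnames(grid))) colnames(grid) <- .WEEKDAYS
  structure(grid, class = c("shct_template", "matrix", "array"))
}

#' @export
print.shct_template <- function(x, ...) {
  cat("SHCT intensity template (% of vVO2max; NA = rest day)\n")
  print(unclass(x), na.print = "--")
  invisible(x)
}

#' Count VO2-peak sessions per week
#'
#' A "peak" session is one programmed at or above `threshold` percent of
#' vVO2max (95% by default convention).
#'
#' @param template An [as_shct_template()] grid.
#' @param threshold Peak threshold in percent, in (0, 100].
#' @return Integer vector of length 4, one count per week.
#' @examples
#' count_vo2_peaks(default_template(), 95) # 1 2 3 1
#' @export
count_vo2_peaks <- function(template, threshold = 95) {
  template <- as_shct_template(template)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 100) {
    stop("`threshold` must be a single percentage in (0, 100]", call. = FALSE)
  }
  as.integer(rowSums(template >= threshold, na.rm = TRUE))
}

#' Prescribe one SHCT session
#'
#' A session is 20 minutes of continuous running at `p` × vVO2max. The
#' record carries the prescribed speed and run distance (speed × 1200 s),
#' the fraction of VO2max the speed elicits (via
#' [vo2_fraction_at_speed()]), the load-accounted distance credited at the
#' oxygen-equivalent speed (vo2_fraction × vVO2max × 1200 s — the
#' convention under which cycle distance totals are tabulated alongside the
#' oxygen totals), the session oxygen volume (VO2max × 20 min ×
#' vo2_fraction) and its caloric equivalent at 5 kcal per liter.
#'
#' @param profile One-row aerobic profile (from [aerobic_profile()] or
#'   [profile_from_cooper()]); needs `v_vo2max` and `vo2max`.
#' @param K Cooper distance (m) the profile was derived from.
#' @param p Session intensity as a fraction of vVO2max, in (0, 1].
#' @return One-row data.frame: `intensity_pct`, `speed_ms`, `duration_s`,
#'   `distance_m`, `vo2_fraction`, `load_distance_m`, `session_vo2_l`,
#'   `session_kcal`.
#' @export
build_session <- function(profile, K, p) {
  profile <- as.list(profile)
  if (is.null(profile$v_vo2max) || is.null(profile$vo2max)) {
    stop("`profile` must carry `v_vo2max` and `vo2max`", call. = FALSE)
  }
  f <- vo2_fraction_at_speed(K, p)  # validates K and p
  speed <- p * profile$v_vo2max
  vo2 <- profile$vo2max * (.SESSION_SECONDS / 60) * f
  data.frame(
    intensity_pct = 100 * p,
    speed_ms = speed,
    duration_s = .SESSION_SECONDS,
    distance_m = speed * .SESSION_SECONDS,
    vo2_fraction = f,
    load_distance_m = f * profile$v_vo2max * .SESSION_SECONDS,
    session_vo2_l = vo2,
    session_kcal = .KCAL_PER_L_O2 * vo2
  )
}

#' Build a full four-week SHCT cycle
#'
#' Expands an intensity template into the 20 individual session
#' prescriptions for one athlete and totals the cycle loads: run distance,
#' load-accounted distance, oxygen volume, kilocalories, mean oxygen load
#' (% of VO2max) and weekly peak-session counts.
#'
#' @inheritParams build_session
#' @param template An [as_shct_template()] grid; defaults to
#'   [default_template()].
#' @param peak_threshold Percent of vVO2max defining a peak session.
#' @return List of class `shct_cycle` with elements `sessions` (20-row
#'   data.frame with `week`, `day` plus the [build_session()] columns) and
#'   `summary` (list: `total_distance_m`, `total_load_distance_m`,
#'   `total_vo2_l`, `total_kcal`, `mean_vo2_load_pct`,
#'   `weekly_peak_counts`).
#' @examples
#' prof <- aerobic_profile(2324, 72)
#' cyc <- build_cycle(prof, K = 2324)
#' cyc$summary$mean_vo2_load_pct
#' @export
build_cycle <- function(profile, K, template = default_template(),
                        peak_threshold = 95) {
  template <- as_shct_template(template)
  idx <- which(!is.na(t(template)))  # row-major walk: week by week
  weeks <- rep(rownames(template), each = 7)[idx]
  days <- rep(colnames(template), times = 4)[idx]
  p <- as.vector(t(template))[idx] / 100
  sessions <- build_session(profile, K, p)
  sessions <- cbind(data.frame(week = weeks, day = days), sessions)
  total_vo2 <- sum(sessions$session_vo2_l)
  summary <- list(
    total_distance_m = sum(sessions$distance_m),
    total_load_distance_m = sum(sessions$load_distance_m),
    total_vo2_l = total_vo2,
    total_kcal = .KCAL_PER_L_O2 * total_vo2,
    mean_vo2_load_pct = 100 * mean(sessions$vo2_fraction),
    weekly_peak_counts = count_vo2_peaks(template, peak_threshold)
  )
  structure(list(sessions = sessions, summary = summary),
            class = "shct_cycle")
}

#' @export
print.shct_cycle <- function(x, ...) {
  s <- x$summary
  cat("SHCT cycle:", nrow(x$sessions), "sessions over 4 weeks\n")
  cat(sprintf("  run distance     %10.0f m\n", s$total_distance_m))
  cat(sprintf("  load distance    %10.0f m  (oxygen-equivalent accounting)\n",
              s$total_load_distance_m))
  cat(sprintf("  oxygen           %10.1f L\n", s$total_vo2_l))
  cat(sprintf("  energy           %10.0f kcal\n", s$total_kcal))
  cat(sprintf("  mean O2 load     %10.2f %% of VO2max\n",
              s$mean_vo2_load_pct))
  cat("  weekly peaks    ", paste(s$weekly_peak_counts, collapse = " "), "\n")
  invisible(x)
}

#' Re-program the next cycle after a new Cooper measurement
#'
#' The measure–program–train–re-measure loop: the next cycle is built from
#' the new Cooper result only; the previous result is used to report the
#' change in profile parameters. A decline in Cooper distance is legal but
#' raised as a warning.
#'
#' @param athlete List or one-row data.frame with `weight_kg` (and
#'   optionally `id`).
#' @param previous,new Cooper result records with `distance_m` and
#'   `timepoint`; `new$timepoint` must be `previous$timepoint + 1`.
#' @inheritParams build_cycle
#' @return List of class `shct_reprogram`: `cycle` (the new `shct_cycle`),
#'   `profile` (new profile row) and `delta` (data.frame of old value, new
#'   value and percent change for each profile parameter).
#' @export
reprogram <- function(athlete, previous, new, template = default_template()) {
  previous <- as.list(previous)
  new <- as.list(new)
  if (is.null(new$distance_m) || is.null(previous$distance_m)) {
    stop("both Cooper results must carry `distance_m`", call. = FALSE)
  }
  if (!is.null(previous$timepoint) && !is.null(new$timepoint) &&
      as.integer(new$timepoint) != as.integer(previous$timepoint) + 1L) {
    stop("`new` must be the measurement immediately after `previous`",
         call. = FALSE)
  }
  if (new$distance_m < previous$distance_m) {
    warning("Cooper distance decreased (", previous$distance_m, " -> ",
            new$distance_m, " m); cycle re-programmed at the lower load",
            call. = FALSE)
  }
  athlete <- as.list(athlete)
  old_prof <- aerobic_profile(previous$distance_m, athlete$weight_kg)
  new_prof <- aerobic_profile(new$distance_m, athlete$weight_kg)
  pars <- c("distance_m", "vo2rel", "vo2max", "v_vo2max", "efficiency")
  delta <- data.frame(
    parameter = pars,
    old = as.numeric(old_prof[1, pars]),
    new = as.numeric(new_prof[1, pars])
  )
  delta$pct_change <- percent_change(delta$old, delta$new)
  structure(
    list(cycle = build_cycle(new_prof, new$distance_m, template),
         profile = new_prof,
         delta = delta),
    class = "shct_reprogram"
  )
}

#' @export
print.shct_reprogram <- function(x, ...) {
  cat("Re-programmed SHCT cycle; profile change:\n")
  d <- x$delta
  d$old <- signif(d$old, 6)
  d$new <- signif(d$new, 6)
  d$pct_change <- round(d$pct_change, 2)
  print(d, row.names = FALSE)
  print(x$cycle)
  invisible(x)
}
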
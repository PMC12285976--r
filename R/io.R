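# CSV / config surface: readers with schema validation, writers, and the
# four pipeline commands (profile, program, evaluate, simulate) driven by a
# YAML run configuration. All CSVs are header-row, dot-decimal, UTF-8;
# timepoints are 1-based; output distances are rounded to integer meters,
# everything else written at full precision.

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Validate an athlete table
#'
#' Requires columns `id`, `age`, `height_cm`, `weight_kg`; all
#' anthropometrics strictly positive, ids unique.
#'
#' @param athletes data.frame to check.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_athletes <- function(athletes) {
  if (!is.data.frame(athletes) || nrow(athletes) == 0) {
    stop("athlete table must be a non-empty data.frame", call. = FALSE)
  }
  .require_columns(athletes, c("id", "weight_kg"), "athlete table")
  for (col in intersect(c("age", "height_cm", "weight_kg"), names(athletes))) {
    v <- athletes[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("athlete column `", col, "` must be positive numeric",
           call. = FALSE)
    }
  }
  if (anyDuplicated(athletes$id)) {
    stop("athlete ids must be unique", call. = FALSE)
  }
  invisible(athletes)
}

#' Validate a long Cooper-result table
#'
#' Requires columns `id`, `timepoint`, `distance_m`; distances inside the
#' estimator domain (432 m, 6000 m), timepoints positive integers, one row
#' per (id, timepoint).
#'
#' @param cooper data.frame to check.
#' @return The input, invisibly, if valid.
#' @export
validate_cooper <- function(cooper) {
  if (!is.data.frame(cooper) || nrow(cooper) == 0) {
    stop("Cooper table must be a non-empty data.frame", call. = FALSE)
  }
  .require_columns(cooper, c("id", "timepoint", "distance_m"), "Cooper table")
  tp <- cooper$timepoint
  if (!is.numeric(tp) || any(!is.finite(tp)) || any(tp < 1) ||
      any(tp != round(tp))) {
    stop("`timepoint` must be 1-based integers", call. = FALSE)
  }
  .check_K(cooper$distance_m)
  if (anyDuplicated(cooper[c("id", "timepoint")])) {
    stop("duplicate (id, timepoint) rows in Cooper table", call. = FALSE)
  }
  invisible(cooper)
}

#' Read athlete / Cooper CSV files
#'
#' @param path CSV file path. `athletes.csv` schema:
#'   `id,age,height_cm,weight_kg`; `cooper.csv` schema:
#'   `id,timepoint,distance_m`.
#' @return Validated data.frame.
#' @export
read_athletes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = c(id = "character"))
  validate_athletes(df)
  df
}

#' @rdname read_athletes
#' @export
read_cooper <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = c(id = "character"))
  validate_cooper(df)
  df
}

#' Reshape a long Cooper table to the wide matrix the analyses use
#'
#' @param cooper Validated long table (`id`, `timepoint`, `distance_m`).
#' @return [longitudinal_dataset()] matrix, athletes × timepoints; errors
#'   if any athlete misses a timepoint.
#' @export
cooper_to_matrix <- function(cooper) {
  validate_cooper(cooper)
  ids <- sort(unique(cooper$id))
  tps <- sort(unique(cooper$timepoint))
  y <- matrix(NA_real_, length(ids), length(tps),
              dimnames = list(ids, paste0("t", tps)))
  y[cbind(match(cooper$id, ids), match(cooper$timepoint, tps))] <-
    cooper$distance_m
  if (anyNA(y)) {
    stop("incomplete design: every athlete needs every timepoint",
         call. = FALSE)
  }
  longitudinal_dataset(y, variable = "K", units = "m")
}

#' Read a run configuration
#'
#' YAML file with keys `athletes_csv`, `cooper_csv`, optional `template`
#' (4 lists of 7 entries, `~`/null for rest days), `alpha`, `correction`,
#' `out_dir`, `seed`.
#'
#' @param path YAML file.
#' @return Named list with defaults filled in and the template coerced via
#'   [as_shct_template()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha out of range", call. = FALSE)
  cfg$correction <- if (is.null(cfg$correction)) "none" else cfg$correction
  cfg$out_dir <- if (is.null(cfg$out_dir)) "." else cfg$out_dir
  if (!is.null(cfg$template)) {
    grid <- do.call(rbind, lapply(cfg$template, function(row) {
      vapply(row, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
             numeric(1))
    }))
    cfg$template <- as_shct_template(grid)
  }
  cfg
}

.out_path <- function(cfg, name) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(cfg$out_dir, name)
}

#' Pipeline commands
#'
#' The four stages of the measure → program → train → re-measure loop, each
#' a pure function of its inputs plus the configured seed:
#' * `cmd_profile()` reads the athlete and Cooper CSVs and writes
#'   `profiles.csv` (one row per id × timepoint).
#' * `cmd_program()` builds one SHCT cycle per athlete from the chosen
#'   timepoint and writes `program_<id>_<timepoint>.csv` plus a JSON file
#'   of cycle summaries.
#' * `cmd_evaluate()` runs the within-subjects ANOVA, Bonferroni pairwise
#'   tests and reliability block on the Cooper matrix and writes
#'   `evaluation.json` and a plain-text report.
#' * `cmd_simulate()` generates a synthetic cohort and writes
#'   `athletes.csv` / `cooper.csv` in the schema the other commands read.
#'
#' @param config List from [read_run_config()] (or built in code).
#' @param timepoint Which measurement the programs are built from.
#' @param n,seed Cohort size and seed for `cmd_simulate` (fall back to
#'   `config$n`, `config$seed`).
#' @return The written objects, invisibly: profiles data.frame, named list
#'   of `shct_cycle`s, evaluation list, or generated cohort.
#' @name pipeline_commands
NULL

#' @rdname pipeline_commands
#' @export
cmd_profile <- function(config) {
  athletes <- read_athletes(config$athletes_csv)
  cooper <- read_cooper(config$cooper_csv)
  profiles <- cooper_profiles(athletes, cooper)
  out <- profiles
  out$distance_m <- round(out$distance_m)
  utils::write.csv(out, .out_path(config, "profiles.csv"), row.names = FALSE)
  invisible(profiles)
}

#' @rdname pipeline_commands
#' @export
cmd_program <- function(config, timepoint = 1) {
  athletes <- read_athletes(config$athletes_csv)
  cooper <- read_cooper(config$cooper_csv)
  cooper <- cooper[cooper$timepoint == timepoint, , drop = FALSE]
  if (nrow(cooper) == 0) {
    stop("no Cooper results at timepoint ", timepoint, call. = FALSE)
  }
  template <- if (is.null(config$template)) default_template() else
    as_shct_template(config$template)
  cycles <- list()
  summaries <- list()
  for (i in seq_len(nrow(cooper))) {
    id <- cooper$id[i]
    w <- athletes$weight_kg[match(id, athletes$id)]
    if (is.na(w)) stop("no athlete record for id ", id, call. = FALSE)
    prof <- aerobic_profile(cooper$distance_m[i], w)
    cyc <- build_cycle(prof, cooper$distance_m[i], template)
    out <- cyc$sessions
    out$distance_m <- round(out$distance_m)
    out$load_distance_m <- round(out$load_distance_m)
    utils::write.csv(
      out,
      .out_path(config, sprintf("program_%s_%d.csv", id, timepoint)),
      row.names = FALSE
    )
    cycles[[id]] <- cyc
    summaries[[id]] <- cyc$summary
  }
  jsonlite::write_json(summaries,
                       .out_path(config, sprintf("summary_%d.json", timepoint)),
                       auto_unbox = TRUE, digits = NA)
  invisible(cycles)
}

#' @rdname pipeline_commands
#' @export
cmd_evaluate <- function(config) {
  cooper <- read_cooper(config$cooper_csv)
  y <- cooper_to_matrix(cooper)
  correction <- if (identical(config$correction, "greenhouse-geisser"))
    "greenhouse-geisser" else "none"
  fit <- rm_anova(y, correction = correction)
  pairwise <- bonferroni_pairwise(y)
  reliability <- list(
    cronbach_alpha = cronbach_alpha(y),
    icc_average = icc_average(y)
  )
  change <- percent_change(mean(y[, 1]), mean(y[, ncol(y)]))
  result <- list(
    anova = fit[c("F", "df1", "df2", "p", "eta2p", "eta2g")],
    sphericity = fit$sphericity,
    normality = fit$normality,
    pairwise = pairwise,
    reliability = reliability,
    percent_change_first_to_last = change,
    alpha = config$alpha
  )
  jsonlite::write_json(result, .out_path(config, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  rpt <- c(
    "Longitudinal evaluation of Cooper 12-min distance",
    sprintf("n = %d athletes, %d timepoints", fit$n, fit$timepoints),
    sprintf("F(%g, %g) = %.2f, p = %.3g%s", fit$df1, fit$df2, fit$F, fit$p,
            if (fit$p <= config$alpha) "  (significant)" else ""),
    sprintf("partial eta^2 = %.3f, generalized eta^2 = %.3f",
            fit$eta2p, fit$eta2g),
    sprintf("Cronbach alpha = %.3f; ICC(average) = %.3f [%.3f, %.3f]",
            reliability$cronbach_alpha, reliability$icc_average$icc,
            reliability$icc_average$lower, reliability$icc_average$upper),
    sprintf("first-to-last change = %.1f%%", change)
  )
  writeLines(rpt, .out_path(config, "report.txt"))
  invisible(result)
}

#' @rdname pipeline_commands
#' @export
cmd_simulate <- function(config, n = NULL, seed = NULL) {
  n <- if (!is.null(n)) n else if (!is.null(config$n)) config$n else 14
  seed <- if (!is.null(seed)) seed else config$seed
  cohort <- generate_cohort(cohort_spec(n = n, seed = seed))
  utils::write.csv(cohort$athletes, .out_path(config, "athletes.csv"),
                   row.names = FALSE)
  cooper <- cohort$cooper
  cooper$distance_m <- round(cooper$distance_m)
  utils::write.csv(cooper, .out_path(config, "cooper.csv"), row.names = FALSE)
  invisible(cohort)
}
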
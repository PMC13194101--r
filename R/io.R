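# Tabular I/O: trajectory logs, cohort metadata, configuration files.

TRAJ_COLS <- c("participant_id", "stage", "trial", "t_s", "x_m", "y_m")
COHORT_COLS <- c("participant_id", "group", "age", "sex", "education_years",
                 "moca", "moca_mis", "ad8", "cdr", "cdr_sob")

#' Validate a trajectory table
#'
#' Checks the trajectory invariants trial by trial: strictly increasing times
#' starting at 0, a constant 1/sampling_rate time step, duration within the
#' trial cap, every point inside the arena, and no duplicated
#' (participant, stage, trial, t) rows. Violations are reported with the row
#' numbers of the offending samples.
#'
#' @param df data.frame with columns participant_id, stage, trial, t_s, x_m, y_m
#' @param config an `arena_config`
#' @param tol numeric tolerance for time-step and containment checks
#' @return `df`, invisibly; errors on violation
#' @export
validate_trajectories <- function(df, config, tol = 1e-6) {
  miss <- setdiff(TRAJ_COLS, names(df))
  if (length(miss)) stop("missing trajectory columns: ", paste(miss, collapse = ", "))
  key <- interaction(df$participant_id, df$stage, df$trial, df$t_s, drop = TRUE)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key))
    stop("duplicated (participant, stage, trial, t) at rows: ",
         paste(utils::head(rows, 5L), collapse = ", "))
  }
  r <- sqrt(df$x_m^2 + df$y_m^2)
  out <- which(r > config$arena_radius * (1 + tol))
  if (length(out))
    stop("points outside the arena at rows: ",
         paste(utils::head(out, 5L), collapse = ", "))
  dt <- 1 / config$sampling_rate
  idx <- split(seq_len(nrow(df)),
               interaction(df$participant_id, df$stage, df$trial, drop = TRUE))
  for (rows in idx) {
    tt <- df$t_s[rows]
    o <- order(tt)
    tt <- tt[o]
    if (abs(tt[1]) > tol)
      stop("trial does not start at t = 0 (row ", rows[o][1], ")")
    if (length(tt) > 1L) {
      steps <- diff(tt)
      bad <- which(abs(steps - dt) > tol * max(1, dt))
      if (any(steps <= 0))
        stop("non-monotone time at rows: ",
             paste(utils::head(rows[o][which(steps <= 0) + 1L], 5L), collapse = ", "))
      if (length(bad))
        stop("irregular sampling interval at rows: ",
             paste(utils::head(rows[o][bad + 1L], 5L), collapse = ", "))
    }
    if (max(tt) > config$max_trial_duration + tol)
      stop("trial exceeds the duration cap (rows ",
           rows[o][length(rows)], ")")
  }
  invisible(df)
}

#' Read trajectory logs from CSV
#'
#' Expects the long format written by [write_trajectories()]: one row per
#' sample with columns participant_id, stage, trial, t_s, x_m, y_m. All
#' trajectory invariants are validated on load.
#'
#' @param path CSV file path
#' @param config an `arena_config` used for validation
#' @return validated data.frame of trajectory samples
#' @export
read_trajectories <- function(path, config = arena_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TRAJ_COLS, names(df))
  if (length(miss)) stop("missing trajectory columns: ", paste(miss, collapse = ", "))
  df$stage <- as.integer(df$stage)
  df$trial <- as.integer(df$trial)
  validate_trajectories(df, config)
  df
}

#' Write trajectory logs to CSV
#' @param df trajectory data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectories <- function(df, path) {
  utils::write.csv(df[, TRAJ_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Validate cohort metadata
#'
#' Checks instrument bounds (MoCA 0-30, MoCA-MIS 0-15, AD8 0-8, CDR in
#' \{0, 0.5, 1, 2, 3\}, CDR-SOB 0-18), group labels and uniqueness of
#' participant ids.
#'
#' @param df cohort data.frame
#' @return `df`, invisibly; errors on violation
#' @export
validate_cohort <- function(df) {
  miss <- setdiff(COHORT_COLS, names(df))
  if (length(miss)) stop("missing cohort columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty cohort file")
    return(invisible(df))
  }
  if (anyDuplicated(df$participant_id)) stop("duplicated participant_id")
  if (!all(df$group %in% c("HC", "aMCI")))
    stop("unknown group labels: ",
         paste(unique(setdiff(df$group, c("HC", "aMCI"))), collapse = ", "))
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be F or M")
  chk <- function(v, lo, hi, name) {
    bad <- which(!is.na(df[[v]]) & (df[[v]] < lo | df[[v]] > hi))
    if (length(bad))
      stop(sprintf("%s out of bounds [%g, %g] at rows: %s", name, lo, hi,
                   paste(utils::head(bad, 5L), collapse = ", ")))
  }
  chk("moca", 0, 30, "MoCA")
  chk("moca_mis", 0, 15, "MoCA-MIS")
  chk("ad8", 0, 8, "AD8")
  chk("cdr_sob", 0, 18, "CDR-SOB")
  chk("age", 0, 120, "age")
  chk("education_years", 0, 30, "education")
  if (!all(df$cdr %in% c(0, 0.5, 1, 2, 3)))
    stop("CDR must be one of 0, 0.5, 1, 2, 3")
  invisible(df)
}

#' Read cohort metadata from CSV
#'
#' @param path CSV file path
#' @return validated cohort data.frame; group counts are reported via message
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
  if (nrow(df) > 0L) {
    tab <- table(df$group)
    message("cohort: ", paste(names(tab), tab, sep = " = ", collapse = ", "))
  }
  df
}

#' Write cohort metadata to CSV
#' @param df cohort data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cohort <- function(df, path) {
  utils::write.csv(df[, COHORT_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Write an arena configuration to YAML
#' @param config an `arena_config`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_arena_config <- function(config, path) {
  lst <- unclass(config)
  lst$start_positions <- as.list(config$start_positions)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read an arena configuration from YAML
#' @param path YAML file path
#' @return validated `arena_config`
#' @export
read_arena_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sp <- as.data.frame(lst$start_positions)
  arena_config(
    arena_radius = lst$arena_radius,
    room_side = lst$room_side,
    platform_radius = lst$platform_radius,
    max_trial_duration = lst$max_trial_duration,
    sampling_rate = lst$sampling_rate,
    n_stages = lst$n_stages,
    n_trials_per_stage = lst$n_trials_per_stage,
    platform_centers = lapply(lst$platform_centers, as.numeric),
    start_positions = sp,
    quadrant_rotation = lst$quadrant_rotation %||% 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
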
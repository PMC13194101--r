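# The six per-trial navigation metrics and participant-level aggregation.
#
# Metric conventions: successful trials use samples up to and including the
# arrival sample only (the trial ends at arrival); censored trials use all
# samples. The shortest-distance reference of the path distance ratio is the
# platform EDGE (centre distance minus platform radius), so an optimal path
# has ratio exactly 1 and successful trials always have ratio >= 1.

#' Detect platform arrival
#'
#' Index of the first sample whose Euclidean distance to the stage's platform
#' centre is at most the platform radius, or `NA` if the platform is never
#' reached.
#'
#' @param traj data.frame with columns t_s, x_m, y_m (one trial)
#' @param config an `arena_config`
#' @param stage stage number
#' @return integer sample index (1-based) or `NA_integer_`
#' @export
detect_platform_arrival <- function(traj, config, stage) {
  if (!stage %in% seq_len(config$n_stages)) stop("unknown stage: ", stage)
  ctr <- cfg_platform(config, stage)
  d2 <- (traj$x_m - ctr[1])^2 + (traj$y_m - ctr[2])^2
  hit <- which(d2 <= config$platform_radius^2)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Path length up to arrival
#'
#' Sum of Euclidean segment lengths over the samples up to and including the
#' arrival sample, or over the whole trajectory if censored.
#'
#' @param traj trial data.frame
#' @param arrival arrival index from [detect_platform_arrival()]
#' @return metres travelled
#' @export
compute_path_length <- function(traj, arrival = NA_integer_) {
  n <- if (is.na(arrival)) nrow(traj) else arrival
  if (n < 2L) {
    if (nrow(traj) < 2L) warning("single-sample trajectory; path length 0")
    return(0)
  }
  x <- traj$x_m[seq_len(n)]
  y <- traj$y_m[seq_len(n)]
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Latency and censoring flag
#'
#' Time elapsed until platform arrival, or exactly the trial cap (60 s) with
#' `censored = TRUE` for unsuccessful trials.
#'
#' @param traj trial data.frame
#' @param arrival arrival index or `NA`
#' @param config an `arena_config`
#' @return list with `latency` (s) and `censored` (logical)
#' @export
compute_latency <- function(traj, arrival, config) {
  if (is.na(arrival)) {
    list(latency = config$max_trial_duration, censored = TRUE)
  } else {
    list(latency = traj$t_s[arrival], censored = FALSE)
  }
}

#' Path distance ratio
#'
#' Observed path length divided by the shortest possible distance from the
#' start to the platform edge (`d(start, centre) - platform_radius`, guarded
#' by `eps` for degenerate starts).
#'
#' @param traj trial data.frame
#' @param arrival arrival index or `NA`
#' @param config an `arena_config`
#' @param stage stage number
#' @param eps guard for near-platform starts
#' @return unitless ratio (>= 1 for successful trials)
#' @export
compute_path_distance_ratio <- function(traj, arrival, config, stage,
                                        eps = 1e-6) {
  ctr <- cfg_platform(config, stage)
  d0 <- sqrt((traj$x_m[1] - ctr[1])^2 + (traj$y_m[1] - ctr[2])^2)
  if (d0 <= config$platform_radius)
    stop("start position inside the platform disc")
  shortest <- max(d0 - config$platform_radius, eps)
  compute_path_length(traj, arrival) / shortest
}

#' Count quadrant crossings
#'
#' Number of adjacent sample pairs (up to arrival) whose quadrant labels
#' differ. No hysteresis or dead zone is applied.
#'
#' @param traj trial data.frame
#' @param arrival arrival index or `NA`
#' @param config an `arena_config`
#' @return non-negative integer count
#' @export
count_quadrant_crossings <- function(traj, arrival = NA_integer_, config) {
  n <- if (is.na(arrival)) nrow(traj) else arrival
  if (n < 2L) return(0L)
  q <- assign_quadrant(traj$x_m[seq_len(n)], traj$y_m[seq_len(n)], config)
  sum(q[-1L] != q[-n])
}

#' Percentage of trial time in the target quadrant
#'
#' 100 times the fraction of samples (up to arrival) lying in the quadrant
#' that contains the stage's platform centre.
#'
#' @param traj trial data.frame
#' @param arrival arrival index or `NA`
#' @param config an `arena_config`
#' @param stage stage number
#' @return percentage in [0, 100]
#' @export
compute_time_in_target_quadrant <- function(traj, arrival, config, stage) {
  n <- if (is.na(arrival)) nrow(traj) else arrival
  q <- assign_quadrant(traj$x_m[seq_len(n)], traj$y_m[seq_len(n)], config)
  100 * mean(q == target_quadrant(config, stage))
}

#' All six metrics for one trial
#'
#' @param traj trial data.frame (t_s, x_m, y_m)
#' @param config an `arena_config`
#' @param stage stage number
#' @return one-row data.frame: path_length, latency, latency_censored,
#'   path_distance_ratio, quadrant_crossings, time_in_target_quadrant,
#'   target_reached
#' @export
compute_trial_metrics <- function(traj, config, stage) {
  arrival <- detect_platform_arrival(traj, config, stage)
  lat <- compute_latency(traj, arrival, config)
  data.frame(
    path_length = compute_path_length(traj, arrival),
    latency = lat$latency,
    latency_censored = lat$censored,
    path_distance_ratio = compute_path_distance_ratio(traj, arrival, config, stage),
    quadrant_crossings = count_quadrant_crossings(traj, arrival, config),
    time_in_target_quadrant = compute_time_in_target_quadrant(traj, arrival,
                                                              config, stage),
    target_reached = !lat$censored
  )
}

#' Per-trial metrics for a whole trajectory table
#'
#' @param trajectories long trajectory data.frame (participant_id, stage,
#'   trial, t_s, x_m, y_m)
#' @param config an `arena_config`
#' @return data.frame with one row per (participant, stage, trial)
#' @export
compute_metrics <- function(trajectories, config = arena_config()) {
  idx <- split(seq_len(nrow(trajectories)),
               list(trajectories$participant_id, trajectories$stage,
                    trajectories$trial), drop = TRUE)
  rows <- lapply(idx, function(rws) {
    rws <- rws[order(trajectories$t_s[rws])]
    tr <- trajectories[rws, c("t_s", "x_m", "y_m")]
    s <- trajectories$stage[rws[1]]
    cbind(data.frame(participant_id = trajectories$participant_id[rws[1]],
                     stage = s, trial = trajectories$trial[rws[1]]),
          compute_trial_metrics(tr, config, s))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$stage, out$trial), ]
  rownames(out) <- NULL
  out
}

#' Aggregate one participant's trials
#'
#' Per-stage and global means of the five continuous metrics (means over
#' available values, so a flagged-missing ratio propagates) plus per-stage
#' and global target-crossing totals.
#'
#' @param metrics per-trial metrics for exactly
#'   `n_stages * n_trials_per_stage` trials of one participant
#' @param config an `arena_config`
#' @return one-row data.frame of summaries
#' @export
aggregate_participant <- function(metrics, config = arena_config()) {
  expected <- config$n_stages * config$n_trials_per_stage
  if (nrow(metrics) != expected)
    stop("expected ", expected, " trials, got ", nrow(metrics))
  vars <- c("path_length", "latency", "path_distance_ratio",
            "quadrant_crossings", "time_in_target_quadrant")
  out <- list()
  for (v in vars) {
    out[[paste0(v, "_global")]] <- mean(metrics[[v]], na.rm = TRUE)
    for (s in seq_len(config$n_stages)) {
      out[[paste0(v, "_s", s)]] <-
        mean(metrics[[v]][metrics$stage == s], na.rm = TRUE)
    }
  }
  out[["target_total_global"]] <- sum(metrics$target_reached)
  for (s in seq_len(config$n_stages)) {
    out[[paste0("target_total_s", s)]] <-
      sum(metrics$target_reached[metrics$stage == s])
  }
  as.data.frame(out)
}

#' Participant-level summaries for a cohort
#'
#' @param metrics per-trial metrics table from [compute_metrics()]
#' @param cohort optional cohort data.frame; if given, the `group` column is
#'   joined onto the summaries
#' @param config an `arena_config`
#' @return data.frame with one row per participant
#' @export
summarize_participants <- function(metrics, cohort = NULL,
                                   config = arena_config()) {
  ids <- unique(metrics$participant_id)
  rows <- lapply(ids, function(id) {
    m <- metrics[metrics$participant_id == id, ]
    cbind(data.frame(participant_id = id), aggregate_participant(m, config))
  })
  out <- do.call(rbind, rows)
  if (!is.null(cohort)) {
    out <- merge(cohort[, c("participant_id", "group")], out,
                 by = "participant_id", sort = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Group summary table (mean and SE per group, level and variable)
#'
#' Mirrors the layout of the published navigation summary table: for each
#' variable, level (global, s1-s3) and group, the mean and standard error of
#' the participant-level values, with missing values excluded (and the
#' per-cell n reported).
#'
#' @param summaries data.frame from [summarize_participants()] including a
#'   `group` column
#' @return data.frame with columns variable, level, group, mean, se, n
#' @export
group_summary <- function(summaries) {
  if (!"group" %in% names(summaries)) stop("summaries must carry a group column")
  vars <- c("path_length", "latency", "path_distance_ratio",
            "quadrant_crossings", "time_in_target_quadrant", "target_total")
  levels_ <- c("global", "s1", "s2", "s3")
  rows <- list()
  for (v in vars) {
    for (lv in levels_) {
      col <- paste0(v, "_", lv)
      if (!col %in% names(summaries)) next
      for (g in unique(summaries$group)) {
        x <- summaries[[col]][summaries$group == g]
        x <- x[!is.na(x)]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv, group = g,
          mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
      }
    }
  }
  do.call(rbind, rows)
}
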
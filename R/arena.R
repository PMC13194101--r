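# Arena geometry, task configuration and quadrant conventions.

#' Default platform centres by stage
#'
#' The hidden/visible platform occupies a different quadrant in each stage:
#' Stage 1 (visible) in Q1, Stage 2 (hidden, fixed start) in Q3, Stage 3
#' (hidden, novel cues, variable start) in Q2. Coordinates are arena-centred
#' virtual metres.
#' @return list of three length-2 numeric vectors
#' @export
default_platform_centers <- function() {
  list(
    c(7.78, 7.78),    # stage 1, Q1, 11 m from centre
    c(-8.49, -8.49),  # stage 2, Q3, 12 m from centre
    c(-5.66, 5.66)    # stage 3, Q2, 8 m from centre
  )
}

#' Default start positions by stage and trial
#'
#' Stage 1 and Stage 3 vary the start across the seven trials; Stage 2 uses a
#' single fixed start for all trials. Positions are inside the arena and
#' outside every platform disc.
#' @return data.frame with columns stage, trial, x, y
#' @export
default_start_positions <- function() {
  deg <- pi / 180
  s1 <- cbind(angle = c(10, 80, 35, 55, 320, 130, 0),
              radius = c(19, 19, 19, 19, 17, 17, 18.5))
  s3 <- cbind(angle = c(190, 80, 135, 225, 45, 160, 100),
              radius = c(14, 14, 17.5, 12, 12, 15, 15))
  pos1 <- data.frame(stage = 1L, trial = 1:7,
                     x = s1[, "radius"] * cos(s1[, "angle"] * deg),
                     y = s1[, "radius"] * sin(s1[, "angle"] * deg))
  pos2 <- data.frame(stage = 2L, trial = 1:7, x = 13, y = 11)
  pos3 <- data.frame(stage = 3L, trial = 1:7,
                     x = s3[, "radius"] * cos(s3[, "angle"] * deg),
                     y = s3[, "radius"] * sin(s3[, "angle"] * deg))
  rbind(pos1, pos2, pos3)
}

#' Arena and task configuration
#'
#' Geometry, timing and sampling constants of the virtual water-maze task:
#' a circular arena of radius 20 virtual metres inside a 50 x 50 m room, a
#' platform of diameter 4.5 m whose location changes between the three
#' stages, trials of at most 60 s sampled at 15 Hz, and 7 trials per stage.
#'
#' @param arena_radius arena radius in virtual metres
#' @param room_side side of the enclosing square room (m)
#' @param platform_radius platform radius (m); default half of the 4.5 m
#'   diameter
#' @param max_trial_duration trial cap in seconds
#' @param sampling_rate trajectory sampling rate in Hz
#' @param n_stages number of stages
#' @param n_trials_per_stage trials per stage
#' @param platform_centers list of per-stage platform centres
#' @param start_positions data.frame (stage, trial, x, y) of start points
#' @param quadrant_rotation rotation (radians) of the quadrant boundaries
#'   relative to the coordinate axes; the published task does not state the
#'   angular placement, so it is exposed here (default 0 = axis-aligned)
#' @return object of class `arena_config`
#' @export
arena_config <- function(arena_radius = 20,
                         room_side = 50,
                         platform_radius = 2.25,
                         max_trial_duration = 60,
                         sampling_rate = 15,
                         n_stages = 3L,
                         n_trials_per_stage = 7L,
                         platform_centers = default_platform_centers(),
                         start_positions = default_start_positions(),
                         quadrant_rotation = 0) {
  cfg <- structure(list(
    arena_radius = arena_radius,
    room_side = room_side,
    platform_radius = platform_radius,
    max_trial_duration = max_trial_duration,
    sampling_rate = sampling_rate,
    n_stages = as.integer(n_stages),
    n_trials_per_stage = as.integer(n_trials_per_stage),
    platform_centers = platform_centers,
    start_positions = start_positions,
    quadrant_rotation = quadrant_rotation
  ), class = "arena_config")
  validate_arena_config(cfg)
  cfg
}

#' Validate an arena configuration
#'
#' Checks the geometric and protocol invariants: platform discs inside the
#' arena, arena inscribed in the room, starts inside the arena and outside
#' the platform disc of their stage, Stage 2 starts identical across trials,
#' Stage 1 and Stage 3 starts varying, and distinct platform centres per
#' stage.
#'
#' @param cfg an `arena_config`
#' @return `cfg`, invisibly; errors on violation
#' @export
validate_arena_config <- function(cfg) {
  stopifnot(inherits(cfg, "arena_config"))
  if (cfg$arena_radius <= 0 || cfg$platform_radius <= 0)
    stop("arena_radius and platform_radius must be positive")
  if (2 * cfg$arena_radius > cfg$room_side)
    stop("arena must be inscribed in the room (2*arena_radius <= room_side)")
  if (length(cfg$platform_centers) != cfg$n_stages)
    stop("need one platform centre per stage")
  for (s in seq_len(cfg$n_stages)) {
    ctr <- cfg$platform_centers[[s]]
    if (sqrt(sum(ctr^2)) + cfg$platform_radius > cfg$arena_radius)
      stop(sprintf("stage %d platform disc extends outside the arena", s))
  }
  dmat <- do.call(rbind, cfg$platform_centers)
  if (anyDuplicated(dmat))
    stop("platform centres must differ between stages")
  sp <- cfg$start_positions
  need <- c("stage", "trial", "x", "y")
  if (!all(need %in% names(sp))) stop("start_positions needs stage, trial, x, y")
  if (nrow(sp) != cfg$n_stages * cfg$n_trials_per_stage)
    stop("start_positions must cover every (stage, trial)")
  for (i in seq_len(nrow(sp))) {
    p <- c(sp$x[i], sp$y[i])
    if (sqrt(sum(p^2)) >= cfg$arena_radius)
      stop(sprintf("start position row %d outside the arena", i))
    ctr <- cfg$platform_centers[[sp$stage[i]]]
    if (sqrt(sum((p - ctr)^2)) <= cfg$platform_radius)
      stop(sprintf("start position row %d inside the platform disc", i))
  }
  s2 <- sp[sp$stage == 2L, c("x", "y")]
  if (nrow(unique(s2)) != 1L)
    stop("Stage 2 start positions must be identical across trials")
  for (s in c(1L, 3L)) {
    ss <- sp[sp$stage == s, c("x", "y")]
    if (nrow(unique(ss)) < 2L)
      stop(sprintf("Stage %d start positions must vary across trials", s))
  }
  invisible(cfg)
}

#' Assign arena quadrants to points
#'
#' The arena is partitioned into four equal quadrants by the two axis-aligned
#' lines through the centre (optionally rotated by
#' `config$quadrant_rotation`). Boundary points are resolved by the half-open
#' rule: x >= 0 & y >= 0 -> Q1, x < 0 & y >= 0 -> Q2, x < 0 & y < 0 -> Q3,
#' x >= 0 & y < 0 -> Q4, so (0, 0) belongs to Q1.
#'
#' @param x,y point coordinates (vectorised), arena-centred metres
#' @param config an `arena_config`
#' @param tol relative containment tolerance
#' @return character vector of labels "Q1".."Q4"
#' @export
assign_quadrant <- function(x, y, config, tol = 1e-6) {
  r <- sqrt(x^2 + y^2)
  lim <- config$arena_radius * (1 + tol)
  if (any(r > lim))
    stop(sprintf("%d point(s) outside the arena (max radius %.3f > %.3f)",
                 sum(r > lim), max(r), config$arena_radius))
  th <- config$quadrant_rotation
  if (th != 0) {
    xr <- cos(-th) * x - sin(-th) * y
    yr <- sin(-th) * x + cos(-th) * y
    x <- xr
    y <- yr
  }
  ifelse(x >= 0 & y >= 0, "Q1",
         ifelse(x < 0 & y >= 0, "Q2",
                ifelse(x < 0 & y < 0, "Q3", "Q4")))
}

#' Target quadrant of a stage
#'
#' @param config an `arena_config`
#' @param stage stage number
#' @return quadrant label containing the stage's platform centre
#' @export
target_quadrant <- function(config, stage) {
  if (!stage %in% seq_len(config$n_stages)) stop("unknown stage: ", stage)
  ctr <- cfg_platform(config, stage)
  assign_quadrant(ctr[1], ctr[2], config)
}

# Internal accessors.
cfg_platform <- function(config, stage) {
  config$platform_centers[[stage]]
}

cfg_start <- function(config, stage, trial) {
  sp <- config$start_positions
  row <- sp[sp$stage == stage & sp$trial == trial, , drop = FALSE]
  if (nrow(row) != 1L) stop("no start position for stage ", stage, " trial ", trial)
  c(row$x, row$y)
}
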
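# Shared fixtures: all test data is generated in code.

default_cfg <- arena_config()

# Fast simulator parameters: strongly goal-directed agents that finish trials
# quickly. Used where the test needs cohorts but not the calibrated dynamics.
fast_params <- function(...) {
  base <- list(
    speed_mean = 3.5, speed_sd = 0.2,
    heading_noise_kappa = 25,
    goal_weight_base = 0.8,
    belief_error_sd = 3,
    learning_rate = 0.8,
    search_dwell_s = 0.5,
    dwell_mult3 = 1,
    lapse_rate = 0,
    goal_impair = 0.5, belief_impair = 0.5, noise_impair = 0.2,
    hc_impairment_mean = 0.1, hc_impairment_sd = 0.1,
    amci_impairment_mean = 0.8, amci_impairment_sd = 0.3)
  do.call(simulator_params, utils::modifyList(base, list(...)))
}

# A hand-built trajectory data.frame at 15 Hz from a matrix of XY points.
make_traj <- function(xy, rate = 15) {
  xy <- matrix(xy, ncol = 2)
  data.frame(t_s = (seq_len(nrow(xy)) - 1) / rate,
             x_m = xy[, 1], y_m = xy[, 2])
}

# Random in-arena trajectory (bounded random walk), n samples.
random_traj <- function(n, cfg = default_cfg, step = 0.25) {
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, -8, 8); y[1] <- runif(1, -8, 8)
  for (i in seq_len(n - 1)) {
    repeat {
      a <- runif(1, 0, 2 * pi)
      nx <- x[i] + step * cos(a); ny <- y[i] + step * sin(a)
      if (nx^2 + ny^2 < cfg$arena_radius^2) break
    }
    x[i + 1] <- nx; y[i + 1] <- ny
  }
  make_traj(cbind(x, y), cfg$sampling_rate)
}

# Participant summaries with prescribed global metric values; the stage-level
# columns are filled with copies so aggregation-dependent code can run.
make_summaries <- function(values, group) {
  n <- nrow(values)
  df <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                   group = group)
  for (v in colnames(values)) {
    df[[paste0(v, "_global")]] <- values[, v]
    for (s in 1:3) df[[paste0(v, "_s", s)]] <- values[, v]
  }
  df$target_total_global <- df$target_total_global %||%
    rep(10, n)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
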
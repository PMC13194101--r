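# Agent-based cohort simulator.
#
# Each virtual participant is a goal-directed correlated random walker. Per
# 1/15 s step the heading is pulled toward the *believed* platform location
# with a gain (goal weight) and perturbed by von Mises noise; the belief is
# the true platform centre plus a Gaussian error whose SD shrinks across
# trials within a stage (learning) and grows with a latent impairment scalar
# that separates the aMCI-like from the HC-like group. When the walker
# reaches its believed location and finds no platform it draws a fresh
# belief, producing the roaming search that generates quadrant crossings.

#' Simulator parameters
#'
#' Latent steering, learning and impairment parameters of the trajectory
#' simulator, plus the group-level impairment distributions. The shipped
#' calibrated parameter file ([default_simulator_params()]) targets the
#' published cohort summaries.
#'
#' @param speed_mean,speed_sd per-participant walking speed distribution (m/s)
#' @param heading_noise_kappa von Mises concentration of per-step heading noise
#' @param goal_weight_base per-step steering gain toward the believed platform
#'   (0..1), before stage and impairment scaling
#' @param belief_error_sd SD (m) of the remembered platform location in Stage 2
#'   trial 1 for an unimpaired participant
#' @param learning_rate per-trial multiplicative shrinkage of the belief error
#'   within a stage (0..1]
#' @param search_dwell_s seconds spent searching around a believed location
#'   after reaching it, before a fresh belief is drawn; produces the
#'   concentrated, low-coverage search characteristic of hidden-platform
#'   stages; applied in Stages 2-3 only (a visible platform leaves nothing
#'   to search for)
#' @param dwell_mult3 Stage 3 multiplier of the search dwell (novel cues
#'   prolong local search)
#' @param lapse_rate per-unit-impairment probability that a visible-platform
#'   trial is navigated as if the platform were hidden (an attentional lapse:
#'   the trial proceeds with the Stage-2-like belief error and search);
#'   drives the occasional lost Stage 1 trials of impaired participants
#' @param lapse_sd_mult belief-error multiplier of lapse trials relative to
#'   the Stage 2 baseline (a lapsed visible-platform trial is searched over a
#'   narrower region than a truly hidden platform)
#' @param lapse_recover_s mean of the exponential time until attention
#'   recovers within a lapsed trial, after which the agent heads directly to
#'   the visible platform
#' @param goal_impair impairment scaling of the goal weight:
#'   `gw / (1 + goal_impair * impairment)`
#' @param belief_impair impairment scaling of the belief error:
#'   `sd * (1 + belief_impair * impairment)`
#' @param noise_impair impairment scaling of steering precision:
#'   effective concentration `kappa / (1 + noise_impair * impairment)`
#' @param learning_impair impairment-driven slowing of learning:
#'   effective rate `1 - (1 - learning_rate) / (1 + learning_impair * impairment)`
#' @param stage_goal_mult1,stage_goal_mult2,stage_goal_mult3 per-stage goal
#'   weight multipliers
#' @param stage_belief_mult1,stage_belief_mult2,stage_belief_mult3 per-stage
#'   belief error multipliers; Stage 1 has a visible platform (multiplier 0)
#'   and Stage 3 novel cues (multiplier > 1 for both groups)
#' @param hc_impairment_mean,hc_impairment_sd,amci_impairment_mean,amci_impairment_sd
#'   truncated-normal (>= 0) impairment distributions per group
#' @param trait_sd SD of per-participant log-normal trait multipliers applied
#'   independently to the goal weight, belief error, heading precision and
#'   search dwell; individual navigation styles vary in more than one
#'   dimension, which decouples the metrics and sets the within-group
#'   spreads
#' @param stage_trait_sd SD of per-participant, per-stage log-normal skill
#'   multipliers on the belief error (and on the Stage 1 lapse rate):
#'   executive, egocentric and allocentric abilities dissociate partially
#'   across people, which decouples the stage-weighted metrics
#' @param radial_bias_sd SD of the per-participant log-normal radial search
#'   bias: believed locations are pulled toward the centre (bias < 1) or
#'   the wall (bias > 1), the centre-vs-periphery search style seen as
#'   thigmotaxis variation; it modulates the quadrant-crossing rate per
#'   metre largely independently of overall performance
#' @param cognitive_coupling weak within-group link between navigation
#'   ability and the memory instruments: the latent MoCA/MoCA-MIS mean is
#'   shifted by `-coupling * instrument SD` per standardised unit of a
#'   navigation-deficit index combining the impairment and the
#'   performance-relevant style traits, giving the small (nonsignificant at
#'   these group sizes) within-group score-navigation correlations seen in
#'   clinical cohorts
#' @param cognitive_link per-group score distributions, see
#'   [default_cognitive_link()]
#' @return object of class `simulator_params`
#' @export
simulator_params <- function(speed_mean = 3.2, speed_sd = 0.3,
                             heading_noise_kappa = 10,
                             goal_weight_base = 0.35,
                             belief_error_sd = 7,
                             learning_rate = 0.75,
                             search_dwell_s = 2.5,
                             dwell_mult3 = 2.5,
                             lapse_rate = 0.15,
                             lapse_sd_mult = 0.6,
                             lapse_recover_s = 25,
                             goal_impair = 0.5,
                             belief_impair = 0.7,
                             noise_impair = 0.5,
                             learning_impair = 1.0,
                             stage_goal_mult1 = 1.0,
                             stage_goal_mult2 = 1.0,
                             stage_goal_mult3 = 1.0,
                             stage_belief_mult1 = 0.0,
                             stage_belief_mult2 = 1.0,
                             stage_belief_mult3 = 1.6,
                             hc_impairment_mean = 0.15,
                             hc_impairment_sd = 0.2,
                             amci_impairment_mean = 1.0,
                             amci_impairment_sd = 0.5,
                             trait_sd = 0.25,
                             stage_trait_sd = 0.35,
                             radial_bias_sd = 0.35,
                             cognitive_coupling = 0.35,
                             cognitive_link = default_cognitive_link()) {
  p <- structure(as.list(environment()), class = "simulator_params")
  validate_simulator_params(p)
  p
}

#' Validate simulator parameters
#' @param p a `simulator_params`
#' @return `p`, invisibly; errors on violation
#' @export
validate_simulator_params <- function(p) {
  stopifnot(inherits(p, "simulator_params"))
  if (p$speed_mean <= 0) stop("speed_mean must be > 0")
  if (p$speed_sd < 0) stop("speed_sd must be >= 0")
  if (p$heading_noise_kappa < 0) stop("heading_noise_kappa must be >= 0")
  if (p$goal_weight_base < 0 || p$goal_weight_base > 1)
    stop("goal_weight_base must be in [0, 1]")
  if (p$belief_error_sd < 0) stop("belief_error_sd must be >= 0")
  if (p$search_dwell_s < 0) stop("search_dwell_s must be >= 0")
  if (p$dwell_mult3 < 0) stop("dwell_mult3 must be >= 0")
  if (p$lapse_rate < 0 || p$lapse_rate > 1) stop("lapse_rate must be in [0, 1]")
  if (p$lapse_sd_mult < 0) stop("lapse_sd_mult must be >= 0")
  if (p$lapse_recover_s <= 0) stop("lapse_recover_s must be > 0")
  if (p$learning_rate <= 0 || p$learning_rate > 1)
    stop("learning_rate must be in (0, 1]")
  for (f in c("goal_impair", "belief_impair", "noise_impair", "learning_impair",
              "stage_goal_mult1", "stage_goal_mult2", "stage_goal_mult3",
              "stage_belief_mult1", "stage_belief_mult2", "stage_belief_mult3",
              "hc_impairment_mean", "hc_impairment_sd",
              "amci_impairment_mean", "amci_impairment_sd",
              "trait_sd", "stage_trait_sd", "radial_bias_sd",
              "cognitive_coupling")) {
    if (p[[f]] < 0) stop(f, " must be >= 0")
  }
  invisible(p)
}

#' Per-group cognitive score distributions
#'
#' Means and SDs (SD recovered from published SE * sqrt(n)) of the
#' neuropsychological instruments and demographics for each group, used by
#' [generate_cognitive_scores()]. Within a group the scores are drawn
#' independently of the navigation impairment, so within-group
#' score-navigation correlations are approximately zero by construction.
#'
#' @return named list with `HC` and `aMCI` entries
#' @export
default_cognitive_link <- function() {
  list(
    HC = list(age = c(73.0, 6.7), sex_f = 0.75, education = c(12.4, 3.13),
              moca = c(28.0, 1.79), moca_mis = c(14.1, 0.89),
              ad8 = c(0.6, 1.34), cdr = 0, cdr_sob = c(0.05, 0.134)),
    aMCI = list(age = c(76.1, 7.2), sex_f = 0.50, education = c(12.4, 3.39),
                moca = c(21.1, 2.55), moca_mis = c(7.2, 3.39),
                ad8 = c(4.7, 1.70), cdr = 0.5, cdr_sob = c(2.11, 1.23))
  )
}

#' Shipped calibrated simulator parameters
#'
#' Loads the parameter file calibrated against the published group-by-stage
#' navigation summaries (see the methods vignette for the calibration
#' procedure).
#'
#' @return a `simulator_params`
#' @export
default_simulator_params <- function() {
  path <- system.file("extdata", "params_calibrated.yaml", package = "vmnav")
  if (path == "") stop("calibrated parameter file not found")
  read_simulator_params(path)
}

#' Read simulator parameters from YAML
#' @param path YAML file path
#' @return a `simulator_params`
#' @export
read_simulator_params <- function(path) {
  lst <- yaml::read_yaml(path)
  link <- lst$cognitive_link
  lst$cognitive_link <- NULL
  args <- lapply(lst, as.numeric)
  if (!is.null(link)) {
    args$cognitive_link <- lapply(link, function(g) lapply(g, as.numeric))
  }
  do.call(simulator_params, args)
}

#' Write simulator parameters to YAML
#' @param p a `simulator_params`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_simulator_params <- function(p, path) {
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

#' Effective steering dynamics for one trial
#'
#' Resolves the stage- and impairment-scaled goal weight and belief error SD
#' for a given participant impairment, stage and trial.
#'
#' @param p a `simulator_params`
#' @param impairment latent impairment (>= 0)
#' @param stage,trial stage (1-3) and trial (1-7)
#' @return list with `goal_weight`, `belief_sd` and `kappa`
#' @export
resolve_trial_dynamics <- function(p, impairment, stage, trial) {
  gmult <- p[[paste0("stage_goal_mult", stage)]]
  bmult <- p[[paste0("stage_belief_mult", stage)]]
  gw <- p$goal_weight_base * gmult / (1 + p$goal_impair * impairment)
  gw <- min(max(gw, 0), 1)
  lr <- 1 - (1 - p$learning_rate) / (1 + p$learning_impair * impairment)
  # Stage 1 (visible platform): target-location uncertainty arises only from
  # impairment; hidden-platform stages have a baseline error scaled by it.
  sd0 <- if (stage == 1L) {
    p$belief_error_sd * bmult * impairment
  } else {
    p$belief_error_sd * bmult * (1 + p$belief_impair * impairment)
  }
  dwell <- switch(stage, 0, p$search_dwell_s, p$search_dwell_s * p$dwell_mult3)
  list(goal_weight = gw, belief_sd = sd0 * lr^(trial - 1),
       kappa = p$heading_noise_kappa / (1 + p$noise_impair * impairment),
       dwell_s = dwell)
}

#' Simulate one trial trajectory
#'
#' Discrete-time steering walk at the configured sampling rate. Per step the
#' heading is pulled toward the believed platform location with gain
#' `goal_weight` and perturbed by von Mises noise with concentration `kappa`;
#' the position advances by `speed / sampling_rate`. Positions that would
#' exit the arena are clamped to the boundary with the heading reflected
#' about the tangent. The walk stops at the first sample inside the platform
#' disc or at the 60 s cap (then exactly
#' `max_trial_duration * sampling_rate + 1` samples). Uses the current RNG
#' state; [simulate_cohort()] seeds a documented stream per
#' (participant, stage, trial).
#'
#' @param config an `arena_config`
#' @param stage stage number
#' @param trial trial number (only used to locate the start if `start` is NULL)
#' @param start length-2 start position; defaults to the configured one
#' @param speed walking speed (m/s), > 0
#' @param goal_weight steering gain in [0, 1]
#' @param belief_sd SD (m) of the believed platform location error; 0 means
#'   the platform is effectively visible
#' @param kappa heading noise concentration
#' @param dwell_s seconds of local search around a reached believed location
#'   before a fresh belief is drawn
#' @param visible visible-platform stage: a mistaken initial belief is
#'   replaced by the true platform location at the first re-orientation
#'   (looking around reveals the visible platform), so at most one wrong leg
#'   is walked
#' @param disoriented believed locations are drawn around the arena centre
#'   instead of the true platform (complete disorientation, as in an
#'   attentional lapse)
#' @param radial_bias multiplier applied to the radius of every drawn
#'   believed location (centre-seeking < 1 < wall-seeking), clipped into
#'   the arena
#' @param recover_step sample index at which a disoriented walker recovers
#'   and heads straight to the true platform (Inf = never)
#' @return data.frame with columns t_s, x_m, y_m
#' @export
simulate_trial <- function(config, stage, trial, start = NULL,
                           speed, goal_weight, belief_sd, kappa,
                           dwell_s = 0, visible = FALSE,
                           disoriented = FALSE, recover_step = Inf,
                           radial_bias = 1) {
  if (speed <= 0) stop("speed must be > 0")
  if (goal_weight < 0 || goal_weight > 1) stop("goal_weight must be in [0, 1]")
  if (belief_sd < 0) stop("belief_sd must be >= 0")
  if (is.null(start)) start <- cfg_start(config, stage, trial)
  ctr <- cfg_platform(config, stage)
  px <- ctr[1]; py <- ctr[2]
  R <- config$arena_radius
  pr <- config$platform_radius
  if (sqrt(sum(start^2)) >= R) stop("start position outside the arena")
  if (sqrt((start[1] - px)^2 + (start[2] - py)^2) <= pr)
    stop("start position inside the platform disc")

  n_steps <- round(config$max_trial_duration * config$sampling_rate)
  dt <- 1 / config$sampling_rate
  step <- speed * dt
  xs <- numeric(n_steps + 1L)
  ys <- numeric(n_steps + 1L)
  x <- start[1]; y <- start[2]
  xs[1L] <- x; ys[1L] <- y

  # believed platform location: true centre + Gaussian error, clipped into
  # the arena so the believed spot is always reachable
  bcx <- if (disoriented) 0 else px
  bcy <- if (disoriented) 0 else py
  draw_belief <- function() {
    b <- (c(bcx, bcy) + stats::rnorm(2, 0, belief_sd)) * radial_bias
    rb <- sqrt(sum(b^2))
    lim <- 0.88 * R
    if (rb > lim) b <- b * lim / rb
    b
  }
  if (belief_sd > 0) {
    b <- draw_belief()
    bx <- b[1]; by <- b[2]
  } else {
    bx <- px; by <- py
  }
  noise <- rvonmises(n_steps + 1L, kappa)
  heading <- atan2(by - y, bx - x) + noise[n_steps + 1L]

  dwell_steps <- as.integer(round(dwell_s * config$sampling_rate))
  dwell_left <- -1L  # negative = not currently dwelling
  n_used <- 1L
  for (i in seq_len(n_steps)) {
    if (i >= recover_step && belief_sd > 0) {
      bx <- px; by <- py
      belief_sd <- 0
    }
    des <- atan2(by - y, bx - x)
    heading <- heading + goal_weight * wrap_angle(des - heading) + noise[i]
    nx <- x + step * cos(heading)
    ny <- y + step * sin(heading)
    rr <- sqrt(nx * nx + ny * ny)
    if (rr > R) {
      ux <- nx / rr; uy <- ny / rr
      nx <- ux * R; ny <- uy * R
      vx <- cos(heading); vy <- sin(heading)
      dp <- vx * ux + vy * uy
      heading <- atan2(vy - 2 * dp * uy, vx - 2 * dp * ux)
    }
    x <- nx; y <- ny
    n_used <- i + 1L
    xs[n_used] <- x; ys[n_used] <- y
    if (sqrt((x - px)^2 + (y - py)^2) <= pr) break
    if (belief_sd > 0) {
      # a reached belief is searched locally for dwell_steps, then replaced
      if (dwell_left < 0L && sqrt((x - bx)^2 + (y - by)^2) <= pr)
        dwell_left <- dwell_steps
      if (dwell_left == 0L) {
        b <- if (visible) c(px, py) else draw_belief()
        bx <- b[1]; by <- b[2]
        dwell_left <- -1L
      } else if (dwell_left > 0L) {
        dwell_left <- dwell_left - 1L
      }
    }
  }
  data.frame(t_s = (seq_len(n_used) - 1L) * dt,
             x_m = xs[seq_len(n_used)],
             y_m = ys[seq_len(n_used)])
}

#' Generate cognitive and demographic scores for one group
#'
#' Truncated-normal draws within the instrument bounds, with the latent mean
#' adjusted so the truncated mean equals the target group mean. Integer
#' instruments (MoCA, MoCA-MIS, AD8, education) are rounded; CDR-SOB is
#' rounded to the 0.5 grid; CDR is the group's constant level. The
#' `impairment` argument is accepted for interface symmetry but unused:
#' within-group scores are independent of the navigation impairment by
#' construction.
#'
#' @param group "HC" or "aMCI"
#' @param n number of participants
#' @param link per-group distributions, see [default_cognitive_link()]
#' @param impairment_z standardised within-group impairment (length n or
#'   NULL); with `coupling > 0` it shifts the latent MoCA/MoCA-MIS means
#'   downwards for more impaired participants
#' @param coupling within-group impairment-memory coupling strength (0 =
#'   fully independent scores)
#' @return data.frame with age, sex, education_years, moca, moca_mis, ad8,
#'   cdr, cdr_sob
#' @export
generate_cognitive_scores <- function(group, n, link = default_cognitive_link(),
                                      impairment_z = NULL, coupling = 0) {
  g <- link[[group]]
  if (is.null(g)) stop("unknown group: ", group)
  if (is.null(impairment_z) || coupling == 0) impairment_z <- rep(0, n)
  draw <- function(spec, lo, hi, z = rep(0, n)) {
    mu <- truncnorm_latent_mean(spec[1], spec[2], lo, hi)
    shifted <- mu - coupling * spec[2] * z
    vapply(shifted, function(m) rtruncnorm(1, m, spec[2], lo, hi), numeric(1))
  }
  data.frame(
    age = round(draw(g$age, 55, 100), 1),
    sex = ifelse(stats::runif(n) < g$sex_f, "F", "M"),
    education_years = round(draw(g$education, 0, 25)),
    moca = round(draw(g$moca, 0, 30, impairment_z)),
    moca_mis = round(draw(g$moca_mis, 0, 15, impairment_z)),
    ad8 = round(draw(g$ad8, 0, 8)),
    cdr = rep(g$cdr[1], n),
    cdr_sob = pmax(0, round(draw(g$cdr_sob, 0, 18) * 2) / 2)
  )
}

#' Simulate a full cohort
#'
#' Draws per-participant impairment and speed, generates all
#' `n_stages * n_trials_per_stage` trajectories and the cognitive scores.
#' Fully reproducible from `seed`: each participant and each
#' (participant, stage, trial) has its own derived RNG stream
#' ([derive_seed()]), so partial regeneration is stable.
#'
#' @param params a `simulator_params`
#' @param config an `arena_config`
#' @param n_hc,n_amci group sizes (>= 1)
#' @param seed master seed
#' @return object of class `vm_cohort`: list with `cohort` (participant
#'   records), `trajectories` (long sample table), `truth` (latent
#'   impairment and speed per participant), `seed`
#' @export
simulate_cohort <- function(params = default_simulator_params(),
                            config = arena_config(),
                            n_hc = 20, n_amci = 18, seed = 1) {
  validate_simulator_params(params)
  stopifnot(n_hc >= 1, n_amci >= 1)
  n <- n_hc + n_amci
  groups <- c(rep("HC", n_hc), rep("aMCI", n_amci))
  ids <- sprintf("P%03d", seq_len(n))

  cohort <- vector("list", n)
  truth <- vector("list", n)
  traj <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, 1L, i))
    gmean <- if (groups[i] == "HC") params$hc_impairment_mean else params$amci_impairment_mean
    gsd <- if (groups[i] == "HC") params$hc_impairment_sd else params$amci_impairment_sd
    imp <- rtruncnorm(1, gmean, gsd, lower = 0)
    speed <- rtruncnorm(1, params$speed_mean, params$speed_sd, lower = 0.5)
    # independent per-participant navigation-style and per-stage skills;
    # log-normal multipliers are mean-one normalised so trait heterogeneity
    # widens the spread without shifting the group-average difficulty
    traits <- exp(stats::rnorm(4, 0, params$trait_sd) - params$trait_sd^2 / 2)
    stage_skill <- exp(stats::rnorm(3, 0, params$stage_trait_sd) -
                         params$stage_trait_sd^2 / 2)
    radial_bias <- exp(stats::rnorm(1, 0, params$radial_bias_sd))
    # standardise against the truncated distribution actually sampled from
    imp_z <- if (gsd > 0) {
      (imp - truncnorm_mean(gmean, gsd, 0, Inf)) /
        sqrt(truncnorm_var(gmean, gsd, 0, Inf))
    } else 0
    # navigation-deficit index: impairment plus the performance-relevant
    # style traits (wider belief error and longer dwell hurt, stronger goal
    # weight helps); each term is standard normal within group
    style_terms <- c(
      if (params$trait_sd > 0)
        c(log(traits[2]), log(traits[4]),
          -log(traits[1]) - params$trait_sd^2,
          -log(traits[3]) - params$trait_sd^2) /
          params$trait_sd + params$trait_sd / 2,
      if (params$stage_trait_sd > 0)
        log(stage_skill) / params$stage_trait_sd + params$stage_trait_sd / 2)
    style_z <- if (length(style_terms)) {
      sum(style_terms) / sqrt(length(style_terms))
    } else 0
    deficit_z <- (imp_z + style_z) / sqrt(2)
    scores <- generate_cognitive_scores(groups[i], 1, params$cognitive_link,
                                        impairment_z = deficit_z,
                                        coupling = params$cognitive_coupling)
    cohort[[i]] <- cbind(data.frame(participant_id = ids[i], group = groups[i]),
                         scores)
    truth[[i]] <- data.frame(participant_id = ids[i], impairment = imp,
                             speed = speed)
    tlist <- vector("list", config$n_stages * config$n_trials_per_stage)
    k <- 0L
    for (s in seq_len(config$n_stages)) {
      for (tr in seq_len(config$n_trials_per_stage)) {
        set.seed(derive_seed(seed, 2L, i, s, tr))
        dyn <- resolve_trial_dynamics(params, imp, s, tr)
        dyn$goal_weight <- min(1, dyn$goal_weight * traits[1])
        dyn$belief_sd <- dyn$belief_sd * traits[2] * stage_skill[s]
        dyn$kappa <- dyn$kappa * traits[3]
        dyn$dwell_s <- dyn$dwell_s * traits[4]
        visible <- (s == 1L)
        disoriented <- FALSE
        recover_step <- Inf
        if (visible &&
            stats::runif(1) < params$lapse_rate * imp * stage_skill[1L]) {
          # attentional lapse: the visible platform is ignored and the trial
          # is searched with beliefs scattered about the arena centre
          visible <- FALSE
          disoriented <- TRUE
          dyn$belief_sd <- params$lapse_sd_mult * params$belief_error_sd *
            (1 + params$belief_impair * imp) * traits[2] * stage_skill[1L]
          dyn$dwell_s <- 0
          recover_step <- ceiling(stats::rexp(1, 1 / params$lapse_recover_s) *
                                    config$sampling_rate)
        }
        tt <- simulate_trial(config, s, tr,
                             speed = speed,
                             goal_weight = dyn$goal_weight,
                             belief_sd = dyn$belief_sd,
                             kappa = dyn$kappa,
                             dwell_s = dyn$dwell_s,
                             visible = visible,
                             disoriented = disoriented,
                             recover_step = recover_step,
                             radial_bias = radial_bias)
        k <- k + 1L
        tlist[[k]] <- cbind(data.frame(participant_id = ids[i],
                                       stage = s, trial = tr), tt)
      }
    }
    traj[[i]] <- do.call(rbind, tlist)
  }
  structure(list(
    cohort = do.call(rbind, cohort),
    trajectories = do.call(rbind, traj),
    truth = do.call(rbind, truth),
    seed = seed
  ), class = "vm_cohort")
}

#' Flag one aMCI path-distance-ratio value as missing
#'
#' Marks exactly one aMCI participant's path-distance-ratio summary values as
#' missing (all levels), emulating the single missing value of the reference
#' cohort; downstream complete-case analyses then use n - 1 participants.
#' Idempotent: if an aMCI ratio value is already missing the input is
#' returned unchanged.
#'
#' @param summaries participant summary data.frame (see
#'   [summarize_participants()]); must contain a `group` column
#' @param enabled set FALSE to disable injection
#' @param seed optional seed for selecting the participant; default uses the
#'   current RNG state
#' @return `summaries` with the ratio columns of one aMCI participant set NA
#' @export
inject_missingness <- function(summaries, enabled = TRUE, seed = NULL) {
  if (!enabled) return(summaries)
  if (!"group" %in% names(summaries))
    stop("summaries must carry a group column")
  ratio_cols <- grep("^path_distance_ratio", names(summaries), value = TRUE)
  am <- which(summaries$group == "aMCI")
  if (!length(am)) stop("no aMCI participants")
  if (any(is.na(summaries[am, ratio_cols]))) return(summaries)
  if (!is.null(seed)) set.seed(seed)
  pick <- am[sample.int(length(am), 1L)]
  summaries[pick, ratio_cols] <- NA_real_
  summaries
}

#' Reference group-by-stage navigation summaries
#'
#' The published group-by-stage means and standard errors of the five
#' continuous navigation metrics plus target-crossing totals for the clinical
#' cohort the simulator emulates (HC n = 20, aMCI n = 18; aMCI n = 17 for
#' the path distance ratio). These are the calibration targets of
#' [calibrate()].
#'
#' @return data.frame with columns variable, level, group, mean, se
#' @export
reference_targets <- function() {
  lv <- c("global", "s1", "s2", "s3")
  tab <- rbind(
    data.frame(variable = "path_length", level = lv,
               hc_m = c(96.1, 24.1, 120.1, 143.9), hc_se = c(5.5, 2.1, 11.5, 9.9),
               am_m = c(118.5, 46.2, 161.8, 147.4), am_se = c(5.7, 7.5, 11.2, 9.1)),
    data.frame(variable = "path_distance_ratio", level = lv,
               hc_m = c(7.3, 1.8, 4.9, 15.1), hc_se = c(0.5, 0.2, 0.5, 1.3),
               am_m = c(8.7, 3.5, 6.6, 16.0), am_se = c(0.7, 0.9, 0.5, 2.3)),
    data.frame(variable = "quadrant_crossings", level = lv,
               hc_m = c(4.5, 1.3, 5.4, 6.7), hc_se = c(0.2, 0.1, 0.5, 0.5),
               am_m = c(5.5, 2.5, 7.5, 6.7), am_se = c(0.3, 0.4, 0.7, 0.6)),
    data.frame(variable = "time_in_target_quadrant", level = lv,
               hc_m = c(57.7, 82.2, 34.8, 56.1), hc_se = c(3.1, 5.6, 2.8, 5.1),
               am_m = c(41.7, 57.7, 26.8, 40.6), am_se = c(2.3, 4.3, 3.2, 3.0)),
    data.frame(variable = "target_total", level = lv,
               hc_m = c(15.5, 6.95, 4.65, 3.90), hc_se = c(0.63, 0.05, 0.47, 0.32),
               am_m = c(11.94, 6.17, 2.61, 3.17), am_se = c(0.99, 0.34, 0.45, 0.42))
  )
  rbind(
    data.frame(variable = tab$variable, level = tab$level, group = "HC",
               mean = tab$hc_m, se = tab$hc_se),
    data.frame(variable = tab$variable, level = tab$level, group = "aMCI",
               mean = tab$am_m, se = tab$am_se)
  )
}

#' Published composite-stage statistics used as calibration targets
#'
#' PC1 variance share (%), Cohen's d of the Route Efficiency group
#' difference, full-sample Spearman rho between Route Efficiency and MoCA,
#' nested-CV AUC, and the group Route Efficiency means, with the scale used
#' to standardise each discrepancy.
#'
#' @return data.frame with columns quantity, target, scale
#' @export
reference_derived_targets <- function() {
  data.frame(
    quantity = c("pc1_share", "cohens_d", "rho_moca", "cv_auc",
                 "re_hc", "re_amci"),
    target = c(53.5, 1.39, 0.599, 0.78, 0.86, -1.01),
    scale = c(3, 0.12, 0.04, 0.035, 0.2, 0.15)
  )
}

#' Calibrate simulator parameters to summary targets
#'
#' Derivative-free coordinate search minimising the mean squared standardised
#' discrepancy between simulated group-by-level summary means/SEs and the
#' targets. Each evaluation simulates `n_reps` cohorts (different derived
#' seeds), extracts metrics, and compares group summaries; when
#' `derived_targets` is supplied the composite-stage statistics (PC1
#' variance share, Cohen's d, Spearman rho with MoCA, nested-CV AUC, group
#' Route Efficiency means) enter the objective as well, each standardised by
#' its stated scale. With `max_sweeps = 0` the initial parameters are
#' returned unchanged (with their achieved discrepancy).
#'
#' @param params starting `simulator_params`
#' @param targets data.frame as [reference_targets()]
#' @param config an `arena_config`
#' @param tune character vector of scalar parameter names to search over
#' @param n_reps cohorts per objective evaluation
#' @param n_hc,n_amci cohort sizes used during search
#' @param max_sweeps maximum coordinate sweeps
#' @param step initial relative perturbation of each parameter
#' @param seed master seed for the evaluation cohorts
#' @param se_weight weight of the SE-matching term relative to the means
#' @param derived_targets optional data.frame (quantity, target, scale) of
#'   composite-stage statistics to match; see [reference_derived_targets()]
#' @param derived_weight weight of the derived-statistics term
#' @param verbose print progress
#' @return list with `params`, `discrepancy`, `trace`
#' @export
calibrate <- function(params, targets = reference_targets(),
                      config = arena_config(),
                      tune = c("goal_weight_base", "heading_noise_kappa",
                               "belief_error_sd", "learning_rate",
                               "goal_impair", "belief_impair",
                               "amci_impairment_mean", "stage_belief_mult3"),
                      n_reps = 2, n_hc = 20, n_amci = 18,
                      max_sweeps = 5, step = 0.25, seed = 1,
                      se_weight = 0.25, derived_targets = NULL,
                      derived_weight = 1, verbose = FALSE) {
  objective <- function(p) {
    vals <- vector("list", n_reps)
    der <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      co <- simulate_cohort(p, config, n_hc, n_amci,
                            seed = derive_seed(seed, 77L, r))
      met <- compute_metrics(co$trajectories, config)
      summ <- summarize_participants(met, co$cohort)
      if (!is.null(derived_targets)) {
        summ_m <- inject_missingness(summ, seed = derive_seed(seed, 78L, r))
        pca <- fit_pca(summ_m)
        sc <- orient_and_score(pca, summ_m)
        eff <- effect_size_and_power(sc)
        dd <- merge(sc, co$cohort[, c("participant_id", "moca")],
                    by = "participant_id")
        dd <- dd[!is.na(dd$route_efficiency), ]
        cv <- nested_cv_auc(summ_m, k = 5, reps = 3,
                            seed = derive_seed(seed, 79L, r))
        der[[r]] <- c(pc1_share = 100 * pca$var_share[1],
                      cohens_d = eff$d,
                      rho_moca = stats::cor(rank(dd$route_efficiency),
                                            rank(dd$moca)),
                      cv_auc = cv$auc,
                      re_hc = eff$mean_hc, re_amci = eff$mean_amci)
      }
      vals[[r]] <- group_summary(summ)
    }
    gs <- vals[[1]]
    if (n_reps > 1) {
      for (r in 2:n_reps) {
        gs$mean <- gs$mean + vals[[r]]$mean
        gs$se <- gs$se + vals[[r]]$se
      }
      gs$mean <- gs$mean / n_reps
      gs$se <- gs$se / n_reps
    }
    m <- merge(targets, gs, by = c("variable", "level", "group"),
               suffixes = c("_t", "_s"))
    if (!nrow(m)) stop("no overlap between targets and simulated summaries")
    d <- mean(((m$mean_s - m$mean_t) / m$se_t)^2 +
                se_weight * ((m$se_s - m$se_t) / m$se_t)^2)
    if (!is.null(derived_targets)) {
      dv <- colMeans(do.call(rbind, der))
      dt <- derived_targets
      d <- d + derived_weight *
        mean(((dv[dt$quantity] - dt$target) / dt$scale)^2)
    }
    if (!is.finite(d)) stop("non-finite calibration discrepancy")
    d
  }
  best <- params
  best_d <- objective(best)
  trace <- data.frame(sweep = 0L, discrepancy = best_d)
  cur_step <- step
  sweep <- 0L
  while (sweep < max_sweeps && cur_step >= 0.02) {
    sweep <- sweep + 1L
    improved <- FALSE
    for (nm in tune) {
      for (mult in c(1 + cur_step, 1 / (1 + cur_step))) {
        cand <- best
        val <- cand[[nm]] * mult
        if (nm == "learning_rate") val <- min(val, 1)
        if (nm == "goal_weight_base") val <- min(val, 1)
        cand[[nm]] <- val
        d <- tryCatch(objective(cand), error = function(e) Inf)
        if (d < best_d) {
          best <- cand
          best_d <- d
          improved <- TRUE
          if (verbose) message(sprintf("sweep %d: %s -> %.4g (D = %.3f)",
                                       sweep, nm, val, d))
        }
      }
    }
    trace <- rbind(trace, data.frame(sweep = sweep, discrepancy = best_d))
    if (!improved) cur_step <- cur_step / 2
  }
  list(params = best, discrepancy = best_d, trace = trace)
}
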
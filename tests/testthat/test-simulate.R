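cfg <- default_cfg

test_that("the noise-free limit walks essentially straight to the platform", {
  tr <- simulate_trial(cfg, 2, 1, speed = 3.2, goal_weight = 1,
                       belief_sd = 0, kappa = 1e8)
  arr <- detect_platform_arrival(tr, cfg, 2)
  expect_false(is.na(arr))
  start <- cfg_start <- c(tr$x_m[1], tr$y_m[1])
  ctr <- cfg$platform_centers[[2]]
  shortest <- sqrt(sum((start - ctr)^2)) - cfg$platform_radius
  expect_lt(compute_path_length(tr, arr), shortest * 1.05 + 0.5)
})

test_that("timed-out trials have exactly 901 samples spanning 60 s", {
  set.seed(81)
  censored <- 0
  for (i in 1:20) {
    tr <- simulate_trial(cfg, 3, 1, speed = 2.5, goal_weight = 0.02,
                         belief_sd = 18, kappa = 1)
    if (is.na(detect_platform_arrival(tr, cfg, 3))) {
      censored <- censored + 1
      expect_equal(nrow(tr), 901L)
      expect_equal(tr$t_s[901], 60)
      expect_equal(diff(tr$t_s), rep(1 / 15, 900), tolerance = 1e-12)
    }
  }
  expect_gt(censored, 3)
})

test_that("degenerate steering parameters are rejected", {
  expect_error(simulate_trial(cfg, 1, 1, speed = 0, goal_weight = 0.5,
                              belief_sd = 0, kappa = 5), "speed")
  expect_error(simulate_trial(cfg, 1, 1, speed = 3, goal_weight = 1.5,
                              belief_sd = 0, kappa = 5), "goal_weight")
  expect_error(simulate_trial(cfg, 1, 1, start = c(9, 9), speed = 3,
                              goal_weight = 0.5, belief_sd = 0, kappa = 5),
               "inside the platform")
  expect_error(simulator_params(speed_mean = -1), "speed_mean")
  expect_error(simulator_params(learning_rate = 0), "learning_rate")
})

test_that("a goal-blind walker hits the platform as often as an independent oracle walk", {
  # goal_weight 0 with near-zero concentration is an isotropic random walk;
  # compare the success fraction against a plain re-implementation
  nsim <- 250
  run_pkg <- function() {
    hit <- 0
    for (i in seq_len(nsim)) {
      tr <- simulate_trial(cfg, 2, 1, speed = 3.2, goal_weight = 0,
                           belief_sd = 0, kappa = 0)
      if (!is.na(detect_platform_arrival(tr, cfg, 2))) hit <- hit + 1
    }
    hit / nsim
  }
  run_oracle <- function() {
    ctr <- cfg$platform_centers[[2]]
    start <- c(13, 11)
    step <- 3.2 / 15
    hit <- 0
    for (i in seq_len(nsim)) {
      p <- start
      found <- FALSE
      for (s in 1:900) {
        a <- runif(1, -pi, pi)
        q <- p + step * c(cos(a), sin(a))
        r <- sqrt(sum(q^2))
        if (r > cfg$arena_radius) q <- q * cfg$arena_radius / r
        p <- q
        if (sqrt(sum((p - ctr)^2)) <= cfg$platform_radius) {
          found <- TRUE
          break
        }
      }
      if (found) hit <- hit + 1
    }
    hit / nsim
  }
  set.seed(82)
  p_pkg <- run_pkg()
  set.seed(83)
  p_orc <- run_oracle()
  se <- sqrt(p_orc * (1 - p_orc) / nsim)
  expect_lt(abs(p_pkg - p_orc), 4 * sqrt(2) * se + 0.02)
})

test_that("simulated cohorts are bit-identical under the same seed", {
  p <- fast_params()
  a <- simulate_cohort(p, n_hc = 3, n_amci = 2, seed = 11)
  b <- simulate_cohort(p, n_hc = 3, n_amci = 2, seed = 11)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_cohort(p, n_hc = 3, n_amci = 2, seed = 12)
  expect_false(identical(a$trajectories, c_$trajectories))
})

test_that("participant streams are stable under partial regeneration", {
  p <- fast_params()
  big <- simulate_cohort(p, n_hc = 3, n_amci = 2, seed = 13)
  small <- simulate_cohort(p, n_hc = 3, n_amci = 1, seed = 13)
  # shared participants are reproduced exactly even though cohort size changed
  for (id in sprintf("P%03d", 1:4)) {
    a <- big$trajectories[big$trajectories$participant_id == id, ]
    b <- small$trajectories[small$trajectories$participant_id == id, ]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
  }
})

test_that("a 1 + 1 cohort yields 42 trajectories that all satisfy the invariants", {
  p <- fast_params()
  co <- simulate_cohort(p, n_hc = 1, n_amci = 1, seed = 14)
  key <- unique(co$trajectories[, c("participant_id", "stage", "trial")])
  expect_equal(nrow(key), 42L)
  expect_silent(validate_trajectories(co$trajectories, cfg))
  expect_equal(nrow(co$cohort), 2L)
  expect_error(simulate_cohort(p, n_hc = 0, n_amci = 1, seed = 1))
})

test_that("cognitive scores centre on the target group means within bounds", {
  set.seed(84)
  link <- default_cognitive_link()
  hc <- generate_cognitive_scores("HC", 4000, link)
  expect_lt(abs(mean(hc$moca) - 28.0), 0.15)
  expect_true(all(hc$moca <= 30 & hc$moca >= 0))
  expect_true(all(hc$moca_mis <= 15))
  expect_lt(abs(mean(hc$age) - 73.0), 0.4)
  am <- generate_cognitive_scores("aMCI", 4000, link)
  expect_lt(abs(mean(am$moca_mis) - 7.2), 0.2)
  expect_lt(abs(mean(am$moca) - 21.1), 0.2)
  expect_equal(unique(am$cdr), 0.5)
  expect_lt(abs(mean(am$sex == "F") - 0.5), 0.03)
  expect_error(generate_cognitive_scores("other", 5, link), "unknown group")
})

test_that("a zero-variance cognitive link yields constant scores", {
  link <- default_cognitive_link()
  link$HC <- lapply(link$HC, function(v) if (length(v) == 2) c(v[1], 0) else v)
  link$HC$sex_f <- 1
  set.seed(85)
  hc <- generate_cognitive_scores("HC", 20, link)
  expect_equal(unique(hc$moca), 28)
  expect_equal(unique(hc$sex), "F")
})

test_that("within-group score-impairment coupling is weak, negative and tunable", {
  p <- fast_params(hc_impairment_sd = 0.4, cognitive_coupling = 0.45)
  co <- simulate_cohort(p, n_hc = 60, n_amci = 2, seed = 15)
  d <- merge(co$cohort, co$truth)
  hc <- d[d$group == "HC", ]
  r <- cor(hc$moca, hc$impairment)
  expect_lt(r, 0)
  expect_gt(r, -0.75)
  # with the coupling off, scores are independent of impairment
  p0 <- fast_params(hc_impairment_sd = 0.4, cognitive_coupling = 0)
  co0 <- simulate_cohort(p0, n_hc = 60, n_amci = 2, seed = 15)
  d0 <- merge(co0$cohort, co0$truth)
  hc0 <- d0[d0$group == "HC", ]
  expect_lt(abs(cor(hc0$moca, hc0$impairment)), 0.3)
})

test_that("expected difficulty is monotone in the impairment parameter", {
  set.seed(86)
  p <- fast_params(goal_weight_base = 0.3, belief_error_sd = 8,
                   heading_noise_kappa = 6, search_dwell_s = 2)
  grid <- c(0, 1, 2.5)
  stats_at <- sapply(grid, function(imp) {
    succ <- 0; plen <- 0; tiq <- 0; n <- 70
    for (i in 1:n) {
      dyn <- resolve_trial_dynamics(p, imp, 2L, 1L)
      tr <- simulate_trial(cfg, 2, 1, speed = 3.3,
                           goal_weight = dyn$goal_weight,
                           belief_sd = dyn$belief_sd, kappa = dyn$kappa,
                           dwell_s = dyn$dwell_s)
      m <- compute_trial_metrics(tr, cfg, 2)
      succ <- succ + m$target_reached
      plen <- plen + m$path_length
      tiq <- tiq + m$time_in_target_quadrant
    }
    c(success = succ / n, path = plen / n, tiq = tiq / n)
  })
  expect_true(all(diff(stats_at["success", ]) <= 0.05))
  expect_true(all(diff(stats_at["path", ]) >= -8))
  expect_gt(stats_at["success", 1], stats_at["success", 3])
  expect_lt(stats_at["path", 1], stats_at["path", 3])
  expect_gt(stats_at["tiq", 1], stats_at["tiq", 3])
})

test_that("belief error shrinks across Stage 2 trials (learning curve)", {
  p <- fast_params()
  sds <- vapply(1:7, function(tr)
    resolve_trial_dynamics(p, 0, 2L, tr)$belief_sd, numeric(1))
  expect_true(all(diff(sds) < 0))
  # and latency follows: first vs last trial at impairment 0
  set.seed(87)
  lat <- sapply(c(1L, 7L), function(trial) {
    mean(replicate(60, {
      dyn <- resolve_trial_dynamics(p, 0, 2L, trial)
      tr <- simulate_trial(cfg, 2, trial, speed = 3.3,
                           goal_weight = dyn$goal_weight,
                           belief_sd = dyn$belief_sd, kappa = dyn$kappa,
                           dwell_s = dyn$dwell_s)
      arr <- detect_platform_arrival(tr, cfg, 2)
      compute_latency(tr, arr, cfg)$latency
    }))
  })
  expect_lt(lat[2], lat[1])
})

test_that("missingness injection flags exactly one aMCI ratio value, idempotently", {
  p <- fast_params()
  co <- simulate_cohort(p, n_hc = 4, n_amci = 4, seed = 16)
  met <- compute_metrics(co$trajectories)
  summ <- summarize_participants(met, co$cohort)
  out <- inject_missingness(summ, seed = 1)
  miss <- is.na(out$path_distance_ratio_global)
  expect_equal(sum(miss), 1L)
  expect_equal(out$group[miss], "aMCI")
  expect_true(all(is.na(out[miss, grep("^path_distance_ratio",
                                       names(out))])))
  expect_false(anyNA(out$path_length_global))
  out2 <- inject_missingness(out, seed = 2)
  expect_identical(out, out2)
  expect_identical(inject_missingness(summ, enabled = FALSE), summ)
})

test_that("calibration with zero sweeps returns the input parameters", {
  p <- fast_params()
  tg <- reference_targets()
  res <- calibrate(p, tg, max_sweeps = 0, n_reps = 1, n_hc = 3, n_amci = 3,
                   seed = 3)
  expect_identical(res$params, p)
  expect_true(is.finite(res$discrepancy))
})

test_that("calibration recovers summaries generated by known truth parameters", {
  truth <- fast_params()
  co <- simulate_cohort(truth, n_hc = 8, n_amci = 8, seed = 17)
  met <- compute_metrics(co$trajectories)
  gs <- group_summary(summarize_participants(met, co$cohort))
  targets <- gs[, c("variable", "level", "group", "mean", "se")]
  targets$se[targets$se < 0.05] <- 0.05  # guard degenerate cells
  start <- fast_params(belief_error_sd = 3 * 1.6)
  res <- calibrate(start, targets, tune = "belief_error_sd",
                   n_reps = 1, n_hc = 8, n_amci = 8,
                   max_sweeps = 3, step = 0.25, seed = 18)
  d0 <- calibrate(start, targets, max_sweeps = 0, n_reps = 1,
                  n_hc = 8, n_amci = 8, seed = 18)$discrepancy
  expect_lt(res$discrepancy, d0)
  expect_lt(res$params$belief_error_sd, start$belief_error_sd)
})

test_that("the shipped calibrated parameters load and validate", {
  p <- default_simulator_params()
  expect_s3_class(p, "simulator_params")
  expect_invisible(validate_simulator_params(p))
  expect_gt(p$amci_impairment_mean, p$hc_impairment_mean)
})

test_that("von Mises heading noise has the right concentration behaviour", {
  set.seed(88)
  x <- rvonmises(20000, 8)
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(var(x) - 1 / 8), 0.02)  # high-kappa wrapped-normal limit
  u <- rvonmises(20000, 0)
  expect_gt(ks.test(u, "punif", -pi, pi)$p.value, 0.001)
})
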
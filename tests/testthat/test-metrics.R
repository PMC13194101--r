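cfg <- default_cfg

test_that("platform arrival detection matches a linear-scan oracle", {
  # first sample already inside the disc
  ctr <- cfg$platform_centers[[1]]
  tr <- make_traj(rbind(ctr, ctr + c(1, 0)))
  expect_equal(detect_platform_arrival(tr, cfg, 1), 1L)
  # skirting the disc at radius + epsilon never arrives
  ang <- seq(0, 2 * pi, length.out = 901)
  rad <- cfg$platform_radius + 1e-4
  skirt <- make_traj(cbind(ctr[1] + rad * cos(ang), ctr[2] + rad * sin(ang)))
  expect_true(is.na(detect_platform_arrival(skirt, cfg, 1)))
  expect_error(detect_platform_arrival(tr, cfg, 9), "unknown stage")
  # 200 random trajectories against a brute-force scan
  set.seed(21)
  for (i in 1:200) {
    tr <- random_traj(sample(5:60, 1))
    s <- sample(1:3, 1)
    ctr <- cfg$platform_centers[[s]]
    d <- sqrt((tr$x_m - ctr[1])^2 + (tr$y_m - ctr[2])^2)
    oracle <- NA_integer_
    for (j in seq_len(nrow(tr))) {
      if (d[j] <= cfg$platform_radius) { oracle <- j; break }
    }
    expect_identical(detect_platform_arrival(tr, cfg, s), oracle)
  }
})

test_that("path length is the segment sum up to arrival", {
  expect_equal(compute_path_length(make_traj(rbind(c(1, 1), c(1, 1), c(1, 1)))), 0)
  expect_equal(compute_path_length(make_traj(rbind(c(0, 0), c(3, 4)))), 5)
  expect_warning(compute_path_length(make_traj(rbind(c(1, 1)))), "single-sample")
  set.seed(22)
  for (i in 1:100) {
    tr <- random_traj(sample(2:50, 1))
    arr <- sample(c(NA_integer_, seq_len(nrow(tr))), 1)
    n <- if (is.na(arr)) nrow(tr) else arr
    oracle <- 0
    if (n >= 2) {
      for (j in 2:n) {
        oracle <- oracle + sqrt((tr$x_m[j] - tr$x_m[j - 1])^2 +
                                (tr$y_m[j] - tr$y_m[j - 1])^2)
      }
    }
    got <- if (n >= 2) compute_path_length(tr, arr) else
      suppressWarnings(compute_path_length(tr, arr))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("latency is arrival time, or the 60 s cap with a censor flag", {
  tr <- random_traj(100)
  # arrival at the 46th sample (45 steps of 1/15 s) is exactly 3 s
  expect_equal(compute_latency(tr, 46L, cfg), list(latency = 3, censored = FALSE))
  expect_equal(compute_latency(tr, NA_integer_, cfg),
               list(latency = 60, censored = TRUE))
  expect_equal(compute_latency(tr, 1L, cfg)$latency, 0)
})

test_that("path distance ratio is referenced to the platform edge", {
  ctr <- cfg$platform_centers[[1]]
  # straight path from a start 10 m from the centre of the platform,
  # ending exactly at the platform edge: ratio 1
  u <- c(1, 0)
  start <- ctr + 10 * u
  n <- 40
  pts <- t(sapply(seq(0, 10 - cfg$platform_radius, length.out = n),
                  function(d) start - d * u))
  tr <- make_traj(pts)
  arr <- detect_platform_arrival(tr, cfg, 1)
  expect_equal(compute_path_distance_ratio(tr, arr, cfg, 1), 1,
               tolerance = 1e-6)
  # an out-and-back path of length 2d where the shortest distance is d
  h <- 10 - cfg$platform_radius
  zig <- rbind(start, start + c(0, h), start)
  tr2 <- make_traj(zig)
  expect_equal(compute_path_distance_ratio(tr2, NA_integer_, cfg, 1), 2,
               tolerance = 1e-6)
  expect_error(compute_path_distance_ratio(make_traj(rbind(ctr, ctr)), 1L,
                                           cfg, 1), "inside the platform")
})

test_that("successful trials always have ratio >= 1 and match the oracle", {
  set.seed(23)
  p <- fast_params()
  hits <- 0
  for (i in 1:60) {
    s <- sample(1:3, 1)
    tr <- simulate_trial(cfg, s, 1, speed = 3.5, goal_weight = 0.7,
                         belief_sd = 2, kappa = 10)
    arr <- detect_platform_arrival(tr, cfg, s)
    if (is.na(arr)) next
    hits <- hits + 1
    ctr <- cfg$platform_centers[[s]]
    d0 <- sqrt(sum((c(tr$x_m[1], tr$y_m[1]) - ctr)^2)) - cfg$platform_radius
    oracle <- compute_path_length(tr, arr) / d0
    got <- compute_path_distance_ratio(tr, arr, cfg, s)
    expect_equal(got, oracle, tolerance = 1e-9)
    expect_gte(got, 1)
  }
  expect_gt(hits, 20)
})

test_that("quadrant crossings count differing adjacent labels", {
  # path confined to one quadrant
  expect_equal(count_quadrant_crossings(make_traj(rbind(c(1, 1), c(2, 2), c(3, 1))),
                                        config = cfg), 0L)
  # label sequence Q1,Q1,Q2,Q2,Q1 has two transitions
  seq5 <- make_traj(rbind(c(1, 1), c(2, 1), c(-1, 1), c(-2, 1), c(1, 2)))
  expect_equal(count_quadrant_crossings(seq5, config = cfg), 2L)
  set.seed(24)
  for (i in 1:200) {
    tr <- random_traj(sample(2:80, 1))
    arr <- sample(c(NA_integer_, seq_len(nrow(tr))), 1)
    n <- if (is.na(arr)) nrow(tr) else arr
    q <- assign_quadrant(tr$x_m[1:n], tr$y_m[1:n], cfg)
    oracle <- if (n < 2) 0L else sum(q[-1] != q[-n])
    expect_identical(count_quadrant_crossings(tr, arr, cfg),
                     as.integer(oracle))
  }
})

test_that("time in target quadrant is the sample percentage up to arrival", {
  ctr <- cfg$platform_centers[[1]]  # target quadrant Q1
  all_in <- make_traj(rbind(c(1, 1), c(2, 2), c(3, 3), c(4, 4)))
  expect_equal(compute_time_in_target_quadrant(all_in, NA_integer_, cfg, 1), 100)
  half <- make_traj(rbind(c(1, 1), c(2, 2), c(-1, 1), c(-2, 2)))
  expect_equal(compute_time_in_target_quadrant(half, NA_integer_, cfg, 1), 50)
  set.seed(25)
  for (i in 1:100) {
    tr <- random_traj(sample(2:60, 1))
    s <- sample(1:3, 1)
    q <- assign_quadrant(tr$x_m, tr$y_m, cfg)
    oracle <- 100 * mean(q == target_quadrant(cfg, s))
    expect_equal(compute_time_in_target_quadrant(tr, NA_integer_, cfg, s),
                 oracle, tolerance = 1e-12)
  }
})

test_that("trial metrics bundle is consistent and idempotent", {
  set.seed(26)
  tr <- simulate_trial(cfg, 2, 1, speed = 3.2, goal_weight = 0.02,
                       belief_sd = 18, kappa = 2)  # hard trial, often censored
  m1 <- compute_trial_metrics(tr, cfg, 2)
  m2 <- compute_trial_metrics(tr, cfg, 2)
  expect_identical(m1, m2)
  expect_identical(m1$latency_censored, !m1$target_reached)
  if (m1$latency_censored) {
    expect_equal(m1$latency, 60)
    expect_equal(nrow(tr), 901L)
  }
  # a noise-free success has ratio near 1
  tr2 <- simulate_trial(cfg, 1, 1, speed = 3.2, goal_weight = 1,
                        belief_sd = 0, kappa = 1e7)
  m3 <- compute_trial_metrics(tr2, cfg, 1)
  expect_true(m3$target_reached)
  expect_lt(m3$path_distance_ratio, 1.05)
})

test_that("metrics are invariant to a 90-degree rotation of the world", {
  rot <- function(xy) cbind(-xy[, 2], xy[, 1])
  cfg1 <- default_cfg
  sp <- cfg1$start_positions
  spr <- sp
  spr$x <- -sp$y
  spr$y <- sp$x
  cfg2 <- arena_config(
    platform_centers = lapply(cfg1$platform_centers,
                              function(p) c(-p[2], p[1])),
    start_positions = spr)
  set.seed(27)
  tr <- simulate_trial(cfg1, 2, 1, speed = 3.2, goal_weight = 0.3,
                       belief_sd = 6, kappa = 4)
  m1 <- compute_trial_metrics(tr, cfg1, 2)
  trr <- tr
  trr[, c("x_m", "y_m")] <- rot(as.matrix(tr[, c("x_m", "y_m")]))
  m2 <- compute_trial_metrics(trr, cfg2, 2)
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("participant aggregation produces stage and global summaries", {
  one <- data.frame(stage = rep(1:3, each = 7), trial = rep(1:7, 3),
                    path_length = 10, latency = 5, path_distance_ratio = 2,
                    quadrant_crossings = 3, time_in_target_quadrant = 50,
                    target_reached = TRUE)
  agg <- aggregate_participant(one, cfg)
  expect_equal(agg$path_length_global, 10)
  expect_equal(agg$latency_s2, 5)
  expect_equal(agg$target_total_global, 21)
  expect_equal(agg$target_total_s1, 7)
  expect_error(aggregate_participant(one[1:20, ], cfg), "expected 21")

  set.seed(28)
  rnd <- one
  for (v in c("path_length", "latency", "path_distance_ratio",
              "quadrant_crossings", "time_in_target_quadrant")) {
    rnd[[v]] <- runif(21, 0, 100)
  }
  rnd$target_reached <- runif(21) < 0.5
  agg2 <- aggregate_participant(rnd, cfg)
  expect_equal(agg2$path_length_global, mean(rnd$path_length))
  expect_equal(agg2$latency_s3, mean(rnd$latency[rnd$stage == 3]))
  expect_equal(agg2$target_total_global, sum(rnd$target_reached))
  expect_equal(agg2$target_total_global,
               agg2$target_total_s1 + agg2$target_total_s2 + agg2$target_total_s3)

  # a flagged-missing ratio propagates to the ratio means only
  rnd$path_distance_ratio <- NA_real_
  agg3 <- aggregate_participant(rnd, cfg)
  expect_true(is.nan(agg3$path_distance_ratio_global))
  expect_equal(agg3$path_length_global, agg2$path_length_global)
})

test_that("path length dominates the straight-line displacement", {
  set.seed(29)
  for (i in 1:40) {
    tr <- random_traj(sample(3:50, 1))
    arr <- detect_platform_arrival(tr, cfg, 1)
    n <- if (is.na(arr)) nrow(tr) else arr
    if (n < 2) next
    disp <- sqrt((tr$x_m[n] - tr$x_m[1])^2 + (tr$y_m[n] - tr$y_m[1])^2)
    expect_gte(compute_path_length(tr, arr) + 1e-12, disp)
  }
})

test_that("successful cross-quadrant trials register at least one crossing", {
  set.seed(30)
  p <- fast_params()
  found <- 0
  for (i in 1:40) {
    tr <- simulate_trial(cfg, 2, 1, speed = 3.5, goal_weight = 0.7,
                         belief_sd = 1, kappa = 15)
    arr <- detect_platform_arrival(tr, cfg, 2)
    if (is.na(arr)) next
    sq <- assign_quadrant(tr$x_m[1], tr$y_m[1], cfg)
    if (sq == target_quadrant(cfg, 2)) next
    found <- found + 1
    expect_gte(count_quadrant_crossings(tr, arr, cfg), 1L)
  }
  expect_gt(found, 10)
})
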
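# Cursor kinematics, angular classification, dwell selection, state machine
# gating, and familiarization trials.

test_that("cursor kinematics follow the polar convention", {
  mav <- data.frame(t = epoch_ct(1:3),
                    m1 = c(0.5, 0.3, 0),
                    m2 = c(0.0, 0.3, 0))
  cur <- mav_to_cursor(mav)
  expect_equal(cur$v[1], 0)
  expect_equal(cur$r[1], 0.5)
  expect_equal(cur$v[2], 45)
  expect_equal(cur$r[3], 0)
  expect_true(is.na(cur$v[3]))  # angle undefined at the origin
})

test_that("angle classification matches exhaustive interval search and tie-breaks upward", {
  b <- default_boundaries()
  expect_identical(classify_target(10, b), 1L)
  expect_identical(classify_target(22.5, b), 2L)  # boundary belongs above
  expect_identical(classify_target(45, b), 3L)
  expect_identical(classify_target(67.5, b), 4L)
  expect_error(classify_target(-1, b), class = "amo_data_error")
  expect_error(classify_target(95, b), class = "amo_data_error")

  grid <- seq(0, 90, by = 0.1)
  for (bb in list(b, decision_boundaries(19.1, 43.2, 64.9),
                  decision_boundaries(16, 45.4, 85.3))) {
    expect_identical(classify_target(grid, bb), oracle_classify(grid, bb))
  }
  # every grid angle maps to exactly one target, non-decreasing in v
  k <- classify_target(grid, b)
  expect_true(all(k %in% 1:4))
  expect_true(all(diff(k) >= 0))
})

test_that("dwell selection fires after continuous residence and resets on exit", {
  cfg <- task_space_config(dwell_ms = 500)
  ctr <- 0.7
  # reach target 3 (center 56.25 deg) and hold 1.2x dwell
  radii <- c(0, 0, seq(0, ctr, length.out = 8)[-1], rep(ctr, 13))
  traj <- make_ray(56.25, radii, sample_ms = 50)
  dec <- decode_mav_stream(traj, cfg)
  expect_identical(nrow(dec$commands), 1L)
  expect_identical(dec$commands$target, 3L)

  # oscillating in/out with max stay 0.8x dwell never fires
  stay <- rep(ctr, 8)                      # 8 x 50 ms = 400 ms < 500 ms
  out <- rep(0, 3)
  radii <- c(0, rep(c(stay, out), 4))
  traj <- make_ray(56.25, radii, sample_ms = 50)
  dec <- decode_mav_stream(traj, cfg)
  expect_identical(nrow(dec$commands), 0L)
})

test_that("fired targets equal a brute-force run-length replay on grazing trajectories", {
  set.seed(51)
  cfg <- task_space_config(dwell_ms = 300)
  for (rep in 1:20) {
    # wander between two adjacent target centres with jitter
    n <- 120
    ang <- 33.75 + cumsum(rnorm(n, 0, 4))
    ang <- pmin(pmax(ang, 0), 90)
    rad <- 0.7 + rnorm(n, 0, 0.08)
    mav <- data.frame(t = epoch_ct((1:n) * 0.05),
                      m1 = pmax(rad * cos(ang * pi / 180), 0),
                      m2 = pmax(rad * sin(ang * pi / 180), 0))
    oracle <- oracle_dwell_fires(mav, cfg)
    sel <- new_selection_state()
    cur <- mav_to_cursor(mav)
    memb <- cursor_in_target(cur$x, cur$y, cfg)
    fired <- data.frame(t = epoch_ct(numeric(0)), target = integer(0))
    for (i in seq_len(n)) {
      s <- update_selection(sel, cur$t[i], memb[i], cfg$dwell_ms)
      sel <- s$state
      if (s$fired > 0) {
        fired <- rbind(fired, data.frame(t = cur$t[i], target = s$fired))
      }
    }
    expect_equal(fired$target, oracle$target)
    expect_equal(as.numeric(fired$t), as.numeric(oracle$t))
  }
})

test_that("the hand state machine gates grasps: open+basket to close, closed to open", {
  cfg <- task_space_config()
  gmap <- grasp_map()
  b <- default_boundaries()
  hand <- new_hand_state()
  basket <- list(t = epoch_ct(0), x = 0.01, y = 0.01, r = 0.014, v = 45)
  at1 <- list(t = epoch_ct(1), x = 0.686, y = 0.137, r = 0.7, v = 11.25)
  at2 <- list(t = epoch_ct(2), x = 0.582, y = 0.389, r = 0.7, v = 33.75)
  at4 <- list(t = epoch_ct(3), x = 0.137, y = 0.686, r = 0.7, v = 78.75)

  # arm in the basket, then fire target 1 -> power command, hand closes
  hand <- step_state_machine(hand, 0L, basket, gmap, cfg, b)$hand
  st <- step_state_machine(hand, 1L, at1, gmap, cfg, b)
  expect_identical(st$command$grasp, "power")
  expect_identical(st$hand$state, "CLOSED")
  hand <- st$hand

  # closed hand ignores a new closing fire (discarded, no command)
  st <- step_state_machine(hand, 2L, at2, gmap, cfg, b)
  expect_null(st$command)
  expect_identical(st$discarded$reason, "hand_not_open")

  # target 4 while closed opens the hand
  st <- step_state_machine(hand, 4L, at4, gmap, cfg, b)
  expect_identical(st$command$grasp, "open")
  expect_identical(st$hand$state, "OPEN")

  # open hand ignores an open fire
  st <- step_state_machine(st$hand, 4L, at4, gmap, cfg, b)
  expect_null(st$command)
})

test_that("random fire sequences match the brute-force automaton and never double-close", {
  set.seed(52)
  cfg <- task_space_config()
  gmap <- grasp_map()
  b <- default_boundaries()
  centers <- c(11.25, 33.75, 56.25, 78.75)
  for (rep in 1:60) {
    n <- 50
    fires <- sample(0:4, n, replace = TRUE, prob = c(0.3, rep(0.175, 4)))
    in_basket <- runif(n) < 0.4
    hand <- new_hand_state()
    emitted <- integer(0)
    for (i in seq_len(n)) {
      v <- if (fires[i] > 0) centers[fires[i]] else 45
      r <- if (in_basket[i]) 0.05 else 0.7
      cursor <- list(t = epoch_ct(i), x = r * cospi(v / 180), y = r * sinpi(v / 180),
                     r = r, v = v)
      st <- step_state_machine(hand, fires[i], cursor, gmap, cfg, b)
      hand <- st$hand
      if (!is.null(st$command)) emitted <- c(emitted, st$command$target)
    }
    expect_identical(emitted, oracle_automaton(ifelse(fires == 0, NA, fires),
                                               in_basket))
    # no two closing commands without an open between them
    closes <- emitted <= 3
    if (length(emitted) > 1) {
      expect_false(any(closes[-1] & closes[-length(closes)]))
    }
  }
})

test_that("a stream that never leaves the basket emits no commands", {
  set.seed(53)
  n <- 200
  mav <- data.frame(t = epoch_ct((1:n) * 0.05),
                    m1 = runif(n, 0, 0.09), m2 = runif(n, 0, 0.09))
  dec <- decode_mav_stream(mav, task_space_config(basket_radius = 0.15))
  expect_identical(nrow(dec$commands), 0L)
  expect_identical(nrow(dec$discarded), 0L)
})

test_that("mid-stream boundary reconfiguration affects only later commands", {
  cfg <- task_space_config(dwell_ms = 300)
  # two identical reaches to v = 20 deg (disc 1, but region 2 under shifted
  # boundaries); boundaries change between the reaches
  ctr <- 0.7
  reach <- function(t0) {
    radii <- c(0, 0, seq(0, ctr, length.out = 6)[-1], rep(ctr, 9), rep(0, 3))
    make_ray(20, radii, sample_ms = 50, t0 = epoch_ct(t0))
  }
  open_reach <- function(t0) {
    radii <- c(0, 0, seq(0, ctr, length.out = 6)[-1], rep(ctr, 9), rep(0, 3))
    make_ray(78.75, radii, sample_ms = 50, t0 = epoch_ct(t0))
  }
  mav <- rbind(reach(0), open_reach(2), reach(4))
  updates <- data.frame(t = epoch_ct(3))
  updates$boundaries <- list(decision_boundaries(15, 45, 67.5))
  dec <- decode_mav_stream(mav, cfg, boundary_updates = updates)
  closing <- dec$commands[dec$commands$target != 4, ]
  expect_identical(nrow(closing), 2L)
  expect_identical(closing$target, c(1L, 2L))  # same angle, new region after update
})

test_that("familiarization trials use entry semantics with the 1.5 s timeout", {
  cfg <- task_space_config()
  # straight line reaching target 2's disc at 0.9 s
  radii <- c(seq(0, 0.7, length.out = 19), rep(0.7, 10))  # 50 ms steps
  traj <- make_ray(33.75, radii, sample_ms = 50)
  res <- run_familiarization_trial(traj, 2, cfg)
  expect_true(res$success)
  expect_lte(res$time_to_hit, 0.9)
  expect_gte(res$time_to_hit, 0.6)

  # never leaving the basket fails at timeout
  still <- make_ray(45, rep(0.05, 40), sample_ms = 50)
  res <- run_familiarization_trial(still, 2, cfg)
  expect_false(res$success)
  expect_true(is.na(res$time_to_hit))

  # trials must start in the basket
  out <- make_ray(45, rep(0.7, 10), sample_ms = 50)
  expect_error(run_familiarization_trial(out, 2, cfg),
               class = "amo_protocol_error")
})

test_that("a familiarization batch matches a per-trial oracle and the 70% stage rule", {
  set.seed(54)
  cfg <- task_space_config()
  profile <- virtual_user_profile(aim_sd = 6, tremor_sd = 0.005)
  prompted <- rep(1:4, each = 10)
  trajs <- lapply(prompted, function(k) simulate_reach(profile, k, cfg))
  success <- vapply(seq_along(prompted), function(i) {
    run_familiarization_trial(trajs[[i]], prompted[i], cfg)$success
  }, TRUE)
  # oracle: success iff any sample within the timeout lies in the prompted
  # target's disc, recomputed from raw coordinates
  centers <- cbind(0.7 * cospi(cfg$target_angles / 180),
                   0.7 * sinpi(cfg$target_angles / 180))
  oracle_succ <- vapply(seq_along(prompted), function(i) {
    tr <- trajs[[i]]
    el <- as.numeric(tr$t) - as.numeric(tr$t[1])
    cx <- centers[prompted[i], 1]; cy <- centers[prompted[i], 2]
    any(el <= cfg$trial_timeout_ms / 1000 &
          (tr$m1 - cx)^2 + (tr$m2 - cy)^2 <= cfg$target_radius^2)
  }, TRUE)
  expect_identical(success, oracle_succ)
  trials <- data.frame(prompted_target = prompted, success = success)
  stage <- familiarization_stage_result(trials)
  per_oracle <- vapply(1:4, function(k) mean(oracle_succ[prompted == k]), 1)
  expect_equal(stage$per_target$rate, per_oracle)
  expect_identical(stage$cleared, all(per_oracle > 0.7))
  expect_identical(sum(stage$per_target$n), 40L)
})
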
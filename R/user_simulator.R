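# Virtual users: aiming behaviour, cursor trajectories, synthetic EMG and
# complete pick-and-place sessions with out-of-band ground truth. The
# simulator stands in for the human participant and the hardware so every
# stage of the pipeline is testable end to end.

#' Virtual user aiming profile
#'
#' Aiming is Gaussian in angle: for each reach the user draws one aim angle
#' from a per-target normal distribution and moves the cursor outward along
#' it, with small positional tremor per sample. With probability
#' `misaim_prob` the reach is mis-aimed: the angle is drawn from the
#' intended target's aim distribution truncated to a neighbouring decision
#' region, producing the "unexpected grasp" events that feed adaptation.
#'
#' @param aim_mean Per-target mean aim angle in degrees (length 4); default
#'   the default target centres.
#' @param aim_sd Aim standard deviation in degrees (default 5).
#' @param reach_speed Radial cursor speed in task-space units per second.
#' @param tremor_sd Per-sample positional noise SD (task-space units).
#' @param misaim_prob Probability that a reach is mis-aimed.
#' @param seed Optional integer seed applied by [simulate_session()].
#' @return An object of class `virtual_user_profile`.
#' @export
virtual_user_profile <- function(aim_mean = c(11.25, 33.75, 56.25, 78.75),
                                 aim_sd = 5, reach_speed = 2,
                                 tremor_sd = 0.01, misaim_prob = 0,
                                 seed = NULL) {
  if (length(aim_mean) != 4) amo_config_error("aim_mean must have length 4")
  if (aim_sd <= 0) amo_config_error("aim_sd must be positive")
  if (misaim_prob < 0 || misaim_prob >= 1) {
    amo_config_error("misaim_prob must be in [0, 1)")
  }
  structure(list(aim_mean = aim_mean, aim_sd = aim_sd,
                 reach_speed = reach_speed, tremor_sd = tremor_sd,
                 misaim_prob = misaim_prob, seed = seed),
            class = "virtual_user_profile")
}

region_limits <- function(target, boundaries) {
  cuts <- c(0, boundaries$b12, boundaries$b23, boundaries$b34, 90)
  c(cuts[target], cuts[target + 1])
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) return(mean(c(lo, hi)))
  stats::qnorm(stats::runif(1, plo, phi), mean, sd)
}

#' Simulate one reach from the basket toward a target
#'
#' Generates the MAV trajectory of a reach: a short arming pause in the
#' rest basket, an outward ramp along the drawn aim angle at the profile's
#' reach speed, a hold at the target ring long enough to complete the dwell,
#' and a return to the basket. Per-sample tremor perturbs the position.
#'
#' @param profile A [virtual_user_profile()].
#' @param intended_target Target the user intends (1--4).
#' @param cfg A [task_space_config()].
#' @param boundaries Boundaries used to define mis-aim regions.
#' @param t_start Trajectory start time (`POSIXct`).
#' @param sample_ms Sample period of the MAV stream in ms (default 50,
#'   matching the default MAV step).
#' @return Data frame `t, m1, m2` with attributes `intended_target`,
#'   `aimed_target`, `theta` (the drawn aim angle) and `misaim`.
#' @export
simulate_reach <- function(profile, intended_target,
                           cfg = task_space_config(),
                           boundaries = default_boundaries(),
                           t_start = epoch_ct(0), sample_ms = 50) {
  stopifnot(inherits(profile, "virtual_user_profile"))
  misaim <- stats::runif(1) < profile$misaim_prob
  if (misaim) {
    nb <- intended_target + sample(c(-1L, 1L), 1)
    if (nb < 1L) nb <- 2L
    if (nb > 4L) nb <- 3L
    lim <- region_limits(nb, boundaries)
    theta <- rtruncnorm1(profile$aim_mean[intended_target], profile$aim_sd,
                         lim[1], lim[2])
    aimed <- nb
  } else {
    theta <- stats::rnorm(1, profile$aim_mean[intended_target], profile$aim_sd)
    theta <- min(max(theta, 0), 90)
    aimed <- intended_target
  }
  dt <- sample_ms / 1000
  r_out <- cfg$target_center_radius
  n_ramp <- max(2L, ceiling(r_out / profile$reach_speed / dt))
  n_hold <- ceiling(cfg$dwell_ms / sample_ms) + 3L
  n_rest <- 3L
  r_prof <- c(rep(0, n_rest),                       # arm in the basket
              seq(0, r_out, length.out = n_ramp + 1)[-1],
              rep(r_out, n_hold),
              seq(r_out, 0, length.out = n_ramp + 1)[-1],
              rep(0, 2))
  th <- theta * pi / 180
  n <- length(r_prof)
  x <- r_prof * cos(th) + stats::rnorm(n, 0, profile$tremor_sd)
  y <- r_prof * sin(th) + stats::rnorm(n, 0, profile$tremor_sd)
  out <- data.frame(t = t_start + (seq_len(n) - 1) * dt,
                    m1 = pmax(x, 0), m2 = pmax(y, 0))
  attr(out, "intended_target") <- intended_target
  attr(out, "aimed_target") <- aimed
  attr(out, "theta") <- theta
  attr(out, "misaim") <- misaim
  out
}

#' Pick-and-place block plan
#'
#' The study protocol: 16 blocks in two groups of eight. In the first eight
#' blocks the grasp order is point, tripod, power, point; in the second
#' eight it is point, pinch, power, point (the target-2 grasp is switched
#' from tripod to pinch remotely between groups).
#'
#' @param n_blocks Number of blocks (default 16).
#' @return An object of class `block_plan`: list of per-block grasp
#'   character vectors.
#' @export
block_plan <- function(n_blocks = 16) {
  first <- c("point", "tripod", "power", "point")
  second <- c("point", "pinch", "power", "point")
  plan <- lapply(seq_len(n_blocks), function(b) if (b <= 8) first else second)
  structure(plan, class = "block_plan")
}

#' Simulate a full pick-and-place session through the real decoder
#'
#' Runs every reach of the block plan through the actual dwell selection
#' and hand state machine. Each object manipulation is a closing reach
#' followed by an opening reach. When the executed grasp differs from the
#' intended one the virtual user submits a feedback event 1--5 s after the
#' command (before re-opening), and retries the grasp; reaches that fire no
#' selection are also retried. The tripod-to-pinch device reconfiguration is
#' logged between blocks 8 and 9.
#'
#' Ground truth (per-reach intent, aim, and executed command index) is
#' returned out of band and is never written into the bucket.
#'
#' @param profile A [virtual_user_profile()].
#' @param plan A [block_plan()].
#' @param cfg A [task_space_config()].
#' @param boundaries [decision_boundaries()] in force on the device.
#' @param seed Integer seed; defaults to `profile$seed`.
#' @param session_start Session start time.
#' @param max_attempts Maximum closing attempts per object.
#' @param keep_mav Store the full MAV stream in the bucket (default TRUE).
#' @return List with `bucket` (a [session_bucket()]) and `truth` (data
#'   frame: one row per reach).
#' @export
simulate_session <- function(profile, plan = block_plan(),
                             cfg = task_space_config(),
                             boundaries = default_boundaries(),
                             seed = profile$seed,
                             session_start = epoch_ct(0),
                             max_attempts = 3, keep_mav = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  gmap <- grasp_map("tripod")
  hand <- new_hand_state(); sel <- new_selection_state()
  clock <- as.numeric(session_start)
  mav_parts <- list(); cmd_parts <- list(); dis_parts <- list()
  fb_rows <- list(); marker_rows <- list(); config_rows <- list()
  truth_rows <- list()
  reach_idx <- 0L

  do_reach <- function(intended) {
    reach_idx <<- reach_idx + 1L
    traj <- simulate_reach(profile, intended, cfg, boundaries,
                           t_start = epoch_ct(clock))
    dec <- decode_mav_stream(traj, cfg, boundaries, gmap, hand, sel)
    hand <<- dec$hand; sel <<- dec$sel
    if (keep_mav) mav_parts[[length(mav_parts) + 1L]] <<- traj
    if (nrow(dec$commands)) cmd_parts[[length(cmd_parts) + 1L]] <<- dec$commands
    if (nrow(dec$discarded)) dis_parts[[length(dis_parts) + 1L]] <<- dec$discarded
    clock <<- as.numeric(traj$t[nrow(traj)]) + 0.25
    executed <- if (nrow(dec$commands)) dec$commands$target[1] else NA_integer_
    truth_rows[[reach_idx]] <<- data.frame(
      reach = reach_idx, t_start = traj$t[1],
      intended_target = attr(traj, "intended_target"),
      aimed_target = attr(traj, "aimed_target"),
      theta = attr(traj, "theta"), misaim = attr(traj, "misaim"),
      executed_target = executed,
      command_t = if (nrow(dec$commands)) dec$commands$t[1] else epoch_ct(NA))
    dec$commands
  }

  for (b in seq_along(plan)) {
    if (b == 9) {
      gmap <- grasp_map("pinch")
      config_rows[[length(config_rows) + 1L]] <- data.frame(
        t = epoch_ct(clock), name = "grasp_map.target2", value = "\"pinch\"")
      clock <- clock + 1
    }
    marker_rows[[length(marker_rows) + 1L]] <- data.frame(
      t = epoch_ct(clock), marker = "start", block = b)
    clock <- clock + 0.5
    for (g in plan[[b]]) {
      intended <- grasp_to_target(g)
      for (attempt in seq_len(max_attempts)) {
        cmds <- do_reach(intended)
        if (!nrow(cmds)) next                      # missed every disc: retry
        correct <- cmds$grasp[1] == g
        if (!correct) {
          fb_t <- cmds$t[1] + stats::runif(1, 1, 5)
          fb_rows[[length(fb_rows) + 1L]] <- data.frame(
            t = fb_t, intended_grasp = g,
            command_idx = NA_integer_, orphan = FALSE)
          clock <- max(clock, as.numeric(fb_t) + 0.5)
        }
        for (o in 1:5) {                           # release / re-open
          do_reach(4L)
          if (hand$state == "OPEN") break
        }
        if (correct) break
      }
    }
    marker_rows[[length(marker_rows) + 1L]] <- data.frame(
      t = epoch_ct(clock), marker = "stop", block = b)
    clock <- clock + 1
  }

  bind <- function(parts, empty) if (length(parts)) do.call(rbind, parts) else empty
  bucket <- session_bucket(
    mav = if (keep_mav) bind(mav_parts, NULL),
    commands = bind(cmd_parts, empty_commands()),
    feedback = bind(fb_rows, empty_feedback()),
    discarded = bind(dis_parts, empty_discarded()),
    config_updates = bind(config_rows, empty_config_updates()),
    block_markers = bind(marker_rows, empty_markers()),
    session_start = session_start
  )
  list(bucket = bucket, truth = do.call(rbind, truth_rows))
}

#' Synthesize two-channel surface EMG from activation envelopes
#'
#' Band-limited (20--230 Hz) Gaussian noise, scaled to unit standard
#' deviation and amplitude-modulated by the activation envelope, plus an
#' additive mains (50 Hz) component and white sensor noise. The commanded
#' envelope is attached as attribute `envelope` for ground-truth checks.
#'
#' @param envelopes Numeric matrix (n x 2) of non-negative per-channel
#'   activation envelopes.
#' @param fs Sampling rate in Hz (default 500).
#' @param mains_amp Amplitude of the 50 Hz mains component.
#' @param sensor_sd SD of additive white sensor noise.
#' @param band Passband of the EMG noise carrier in Hz.
#' @param t0 Start timestamp.
#' @return An [emg_record()] with attribute `envelope`.
#' @export
synthesize_emg <- function(envelopes, fs = 500, mains_amp = 0.05,
                           sensor_sd = 0.01, band = c(20, 230),
                           t0 = epoch_ct(0)) {
  if (is.data.frame(envelopes)) envelopes <- as.matrix(envelopes)
  if (!is.matrix(envelopes) || ncol(envelopes) != 2) {
    amo_config_error("envelopes must be an n x 2 matrix")
  }
  n <- nrow(envelopes)
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  tt <- (seq_len(n) - 1) / fs
  samples <- vapply(1:2, function(ch) {
    carrier <- signal::filtfilt(bp$b, bp$a, stats::rnorm(n))
    s <- stats::sd(carrier)
    if (s > 0) carrier <- carrier / s
    envelopes[, ch] * carrier +
      mains_amp * sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(n, 0, sensor_sd)
  }, numeric(n))
  rec <- emg_record(samples, fs = fs, t0 = t0)
  attr(rec, "envelope") <- envelopes
  rec
}
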
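# Abstract two-dimensional myoelectric decoder.
#
# The normalized MAV pair drives a cursor in the first quadrant (x = channel
# 1, y = channel 2). Four circular targets sit on a ring; the user selects a
# grasp by holding the cursor inside a target disc for a dwell period. The
# executed target is the angular decision region (three boundaries
# partitioning [0, 90] degrees) containing the cursor angle v at dwell
# completion, so updating the boundaries reshapes behaviour without moving
# the visual targets. A two-state hand machine gates commands: a closing
# grasp is accepted only when the hand is open and the cursor has re-armed
# in the rest basket near the origin.

#' Task-space geometry and timing configuration
#'
#' Defaults place the four target centres on the bisectors of the default
#' decision regions (11.25, 33.75, 56.25, 78.75 degrees) at radius 0.7 in
#' normalized MAV units, with disc radius 0.12 (the largest round value
#' keeping adjacent discs disjoint, so each disc sits inside its own
#' decision region) and a rest basket of radius 0.15 around the origin.
#'
#' @param target_angles Four strictly increasing angles in (0, 90) degrees.
#' @param target_center_radius Radial distance of target centres.
#' @param target_radius Radius of each circular target disc.
#' @param basket_radius Cursor radius below which the cursor is "in the rest
#'   basket".
#' @param dwell_ms Continuous in-target time required to fire a selection.
#' @param trial_timeout_ms Per-trial time limit for familiarization trials.
#' @return An object of class `task_space_config`.
#' @export
task_space_config <- function(target_angles = c(11.25, 33.75, 56.25, 78.75),
                              target_center_radius = 0.7,
                              target_radius = 0.12,
                              basket_radius = 0.15,
                              dwell_ms = 500,
                              trial_timeout_ms = 1500) {
  if (length(target_angles) != 4 || any(diff(target_angles) <= 0) ||
      any(target_angles <= 0) || any(target_angles >= 90)) {
    amo_config_error("target_angles must be 4 strictly increasing angles in (0, 90)")
  }
  if (!(basket_radius > 0 && basket_radius < target_center_radius)) {
    amo_config_error("need 0 < basket_radius < target_center_radius")
  }
  if (dwell_ms <= 0) amo_config_error("dwell_ms must be positive")
  # non-overlap: chord between adjacent centres must exceed 2 * target_radius
  chord <- 2 * target_center_radius *
    sin(min(diff(target_angles)) * pi / 360)
  if (chord <= 2 * target_radius) {
    amo_config_error("target discs overlap; shrink target_radius or spread angles")
  }
  structure(
    list(target_angles = target_angles,
         target_center_radius = target_center_radius,
         target_radius = target_radius,
         basket_radius = basket_radius,
         dwell_ms = dwell_ms,
         trial_timeout_ms = trial_timeout_ms),
    class = "task_space_config"
  )
}

#' Angular decision boundaries partitioning the first quadrant
#'
#' Three ordered angles split `[0, 90]` degrees into four target regions.
#' The symmetric default is 22.5 / 45 / 67.5 degrees; customized values come
#' from [adapt_boundaries()].
#'
#' @param b12,b23,b34 Boundary angles in degrees, `0 < b12 < b23 < b34 < 90`.
#' @return An object of class `decision_boundaries`.
#' @export
decision_boundaries <- function(b12 = 22.5, b23 = 45, b34 = 67.5) {
  b <- c(b12 = b12, b23 = b23, b34 = b34)
  if (any(!is.finite(b)) || b[1] <= 0 || b[3] >= 90 || any(diff(b) <= 0)) {
    amo_config_error("boundaries must satisfy 0 < b12 < b23 < b34 < 90")
  }
  structure(as.list(b), class = "decision_boundaries")
}

#' @rdname decision_boundaries
#' @export
default_boundaries <- function() decision_boundaries()

#' @export
print.decision_boundaries <- function(x, ...) {
  cat(sprintf("<decision_boundaries> 1-2: %.2f  2-3: %.2f  3-4: %.2f (degrees)\n",
              x$b12, x$b23, x$b34))
  invisible(x)
}

#' Target-to-grasp assignment
#'
#' Targets 1--3 carry closing grasps (power; tripod or pinch; point) and
#' target 4 opens the hand. The target-2 slot is switchable between tripod
#' and pinch, mirroring a remote device reconfiguration.
#'
#' @param target2 `"tripod"` or `"pinch"`.
#' @return Character vector of length 4, class `grasp_map`.
#' @export
grasp_map <- function(target2 = c("tripod", "pinch")) {
  target2 <- match.arg(target2)
  structure(c("power", target2, "point", "open"), class = "grasp_map")
}

#' Map a grasp name to its target index
#'
#' Tripod and pinch share target 2 regardless of which is currently loaded.
#'
#' @param grasp Character vector of grasp names.
#' @return Integer target indices (1--4).
#' @export
grasp_to_target <- function(grasp) {
  idx <- c(power = 1L, tripod = 2L, pinch = 2L, point = 3L, open = 4L)[grasp]
  if (any(!is.na(grasp) & is.na(idx))) amo_data_error("unknown grasp name")
  unname(idx)
}

#' Convert normalized MAV samples to cursor states
#'
#' x = m1, y = m2, `r = sqrt(x^2 + y^2)`, `v = atan2(y, x)` in degrees. The
#' angle is undefined (`NA`) at the origin.
#'
#' @param mav Data frame with columns `t`, `m1`, `m2`.
#' @return Data frame `t, x, y, r, v`.
#' @export
mav_to_cursor <- function(mav) {
  x <- mav$m1; y <- mav$m2
  r <- sqrt(x^2 + y^2)
  v <- ifelse(r > 0, atan2(y, x) * 180 / pi, NA_real_)
  data.frame(t = mav$t, x = x, y = y, r = r, v = v)
}

#' Classify a decision angle into a target region
#'
#' Half-open intervals: `v < b12 -> 1`, `b12 <= v < b23 -> 2`,
#' `b23 <= v < b34 -> 3`, `v >= b34 -> 4`. A boundary angle belongs to the
#' higher-indexed target.
#'
#' @param v Angle(s) in degrees, in `[0, 90]`.
#' @param b A [decision_boundaries()] object.
#' @return Integer target indices.
#' @export
classify_target <- function(v, b = default_boundaries()) {
  stopifnot(inherits(b, "decision_boundaries"))
  if (any(!is.na(v) & (v < 0 | v > 90))) {
    amo_data_error("decision angle v must lie in [0, 90] degrees")
  }
  out <- findInterval(v, c(b$b12, b$b23, b$b34)) + 1L
  out[is.na(v)] <- NA_integer_
  out
}

target_centers <- function(cfg) {
  a <- cfg$target_angles * pi / 180
  cbind(x = cfg$target_center_radius * cos(a),
        y = cfg$target_center_radius * sin(a))
}

#' Which target disc contains a cursor position (0 if none)
#'
#' @param x,y Cursor coordinates (vectors).
#' @param cfg A [task_space_config()].
#' @return Integer vector: disc index 1--4 or 0.
#' @export
cursor_in_target <- function(x, y, cfg) {
  ctr <- target_centers(cfg)
  out <- integer(length(x))
  for (k in 1:4) {
    d2 <- (x - ctr[k, 1])^2 + (y - ctr[k, 2])^2
    hit <- d2 <= cfg$target_radius^2
    out[hit & out == 0L] <- k  # discs are non-overlapping by construction
  }
  out
}

#' Dwell-selection stepper
#'
#' Tracks continuous residence of the cursor in a target disc. A target
#' fires once when the cursor has stayed inside its disc for at least
#' `dwell_ms`; leaving the disc resets the timer, and a fired target cannot
#' re-fire until the cursor has left the disc.
#'
#' @param sel Selection state from [new_selection_state()].
#' @param t Sample timestamp (`POSIXct` or numeric seconds).
#' @param in_target Disc index at this sample (0 = none), from
#'   [cursor_in_target()].
#' @param dwell_ms Dwell requirement in ms.
#' @return List with the updated `state` and `fired` (target index or 0).
#' @export
update_selection <- function(sel, t, in_target, dwell_ms) {
  t <- as.numeric(t)
  fired <- 0L
  if (in_target == 0L || in_target != sel$target) {
    sel$target <- in_target
    sel$since <- if (in_target > 0L) t else NA_real_
    sel$latched <- FALSE
  } else if (!sel$latched && (t - sel$since) * 1000 >= dwell_ms) {
    fired <- in_target
    sel$latched <- TRUE
  }
  list(state = sel, fired = fired)
}

#' @rdname update_selection
#' @export
new_selection_state <- function() {
  list(target = 0L, since = NA_real_, latched = FALSE)
}

#' Hand state machine
#'
#' The hand is either `OPEN` or `CLOSED` in some grasp. A closing command
#' (targets 1--3) is accepted only when the hand is open *and* the cursor
#' has re-armed by visiting the rest basket since the hand last opened; an
#' open command (target 4) is accepted only when the hand is closed. This
#' removes inadvertent grasps: no two closing commands can occur without an
#' opening between them.
#'
#' @return `new_hand_state()`: a fresh open, unarmed hand state.
#' @export
new_hand_state <- function() {
  list(state = "OPEN", grasp = NA_character_, armed = FALSE)
}

#' Advance the hand state machine by one cursor sample
#'
#' @param hand Hand state from [new_hand_state()].
#' @param fired_target Target fired by dwell selection at this sample (0 =
#'   none). The *executed* target is re-derived from the decision angle and
#'   the boundaries in force, so boundary updates take effect immediately.
#' @param cursor One-row cursor state (`t, x, y, r, v`).
#' @param gmap A [grasp_map()].
#' @param cfg A [task_space_config()].
#' @param boundaries A [decision_boundaries()].
#' @return List: updated `hand`, `command` (one-row data frame or `NULL`),
#'   and `discarded` (one-row data frame or `NULL` for an ineligible fire).
#' @export
step_state_machine <- function(hand, fired_target, cursor, gmap, cfg,
                               boundaries = default_boundaries()) {
  if (hand$state == "OPEN" && cursor$r < cfg$basket_radius) hand$armed <- TRUE
  command <- NULL; discarded <- NULL
  if (fired_target > 0L) {
    exec <- if (is.na(cursor$v)) fired_target else
      classify_target(cursor$v, boundaries)
    if (exec <= 3L) {
      if (hand$state == "OPEN" && hand$armed) {
        command <- data.frame(t = cursor$t, target = exec,
                              grasp = gmap[exec], x = cursor$x, y = cursor$y,
                              r = cursor$r, v = cursor$v)
        hand$state <- "CLOSED"; hand$grasp <- gmap[exec]; hand$armed <- FALSE
      } else {
        discarded <- data.frame(t = cursor$t, target = exec,
                                reason = if (hand$state != "OPEN")
                                  "hand_not_open" else "not_armed")
      }
    } else {
      if (hand$state == "CLOSED") {
        command <- data.frame(t = cursor$t, target = 4L, grasp = "open",
                              x = cursor$x, y = cursor$y,
                              r = cursor$r, v = cursor$v)
        hand$state <- "OPEN"; hand$grasp <- NA_character_; hand$armed <- FALSE
      } else {
        discarded <- data.frame(t = cursor$t, target = exec,
                                reason = "hand_already_open")
      }
    }
  }
  list(hand = hand, command = command, discarded = discarded)
}

#' Decode a normalized MAV stream into motor commands
#'
#' Runs the full online decoder: cursor kinematics, dwell selection in the
#' target discs, and the hand state machine. Boundaries may change
#' mid-stream by passing `boundary_updates`.
#'
#' @param mav Data frame `t, m1, m2`, time-ordered.
#' @param cfg A [task_space_config()].
#' @param boundaries Initial [decision_boundaries()].
#' @param gmap A [grasp_map()].
#' @param hand Optional hand state carried over from a previous segment.
#' @param sel Optional selection state carried over.
#' @param boundary_updates Optional data frame with columns `t` and a list
#'   column `boundaries`; each row replaces the boundaries for samples at or
#'   after `t`.
#' @return List: `commands` and `discarded` data frames, plus final `hand`
#'   and `sel` states for chaining.
#' @export
decode_mav_stream <- function(mav, cfg = task_space_config(),
                              boundaries = default_boundaries(),
                              gmap = grasp_map(),
                              hand = new_hand_state(),
                              sel = new_selection_state(),
                              boundary_updates = NULL) {
  if (nrow(mav) && is.unsorted(as.numeric(mav$t))) {
    amo_data_error("MAV stream must be time-ordered")
  }
  cur <- mav_to_cursor(mav)
  in_tgt <- cursor_in_target(cur$x, cur$y, cfg)
  commands <- list(); discarded <- list()
  upd_i <- 1L
  for (i in seq_len(nrow(cur))) {
    if (!is.null(boundary_updates)) {
      while (upd_i <= nrow(boundary_updates) &&
             as.numeric(boundary_updates$t[upd_i]) <= as.numeric(cur$t[i])) {
        boundaries <- boundary_updates$boundaries[[upd_i]]
        upd_i <- upd_i + 1L
      }
    }
    s <- update_selection(sel, cur$t[i], in_tgt[i], cfg$dwell_ms)
    sel <- s$state
    st <- step_state_machine(hand, s$fired, cur[i, ], gmap, cfg, boundaries)
    hand <- st$hand
    if (!is.null(st$command)) commands[[length(commands) + 1L]] <- st$command
    if (!is.null(st$discarded)) discarded[[length(discarded) + 1L]] <- st$discarded
  }
  empty_cmd <- data.frame(t = epoch_ct(numeric(0)), target = integer(0),
                          grasp = character(0), x = numeric(0), y = numeric(0),
                          r = numeric(0), v = numeric(0))
  empty_dis <- data.frame(t = epoch_ct(numeric(0)), target = integer(0),
                          reason = character(0))
  list(
    commands = if (length(commands)) do.call(rbind, commands) else empty_cmd,
    discarded = if (length(discarded)) do.call(rbind, discarded) else empty_dis,
    hand = hand, sel = sel
  )
}

#' Run a single familiarization trial
#'
#' Stage-1 semantics: the trial succeeds if the cursor *enters* the prompted
#' target's disc (no dwell required) within the trial timeout. The stream
#' must start with the cursor in the rest basket.
#'
#' @param mav Data frame `t, m1, m2` for the trial.
#' @param prompted_target Target index 1--4.
#' @param cfg A [task_space_config()].
#' @return List: `success` (logical), `time_to_hit` (seconds, `NA` on
#'   failure).
#' @export
run_familiarization_trial <- function(mav, prompted_target,
                                      cfg = task_space_config()) {
  if (!nrow(mav)) amo_protocol_error("empty trial stream")
  cur <- mav_to_cursor(mav)
  if (cur$r[1] >= cfg$basket_radius) {
    amo_protocol_error("familiarization trial must start with the cursor in the basket")
  }
  in_tgt <- cursor_in_target(cur$x, cur$y, cfg)
  elapsed <- as.numeric(cur$t) - as.numeric(cur$t[1])
  hit <- which(in_tgt == prompted_target & elapsed * 1000 <= cfg$trial_timeout_ms)
  if (length(hit)) {
    list(success = TRUE, time_to_hit = elapsed[hit[1]])
  } else {
    list(success = FALSE, time_to_hit = NA_real_)
  }
}

#' Score a familiarization stage
#'
#' The stage is cleared when the per-target success rate exceeds the pass
#' threshold (default 70 percent) for every target.
#'
#' @param trials Data frame with columns `prompted_target` and `success`.
#' @param pass_rate Required per-target success fraction.
#' @return List: `per_target` data frame (target, n, successes, rate) and
#'   `cleared`.
#' @export
familiarization_stage_result <- function(trials, pass_rate = 0.7) {
  per <- do.call(rbind, lapply(1:4, function(k) {
    sub <- trials[trials$prompted_target == k, , drop = FALSE]
    data.frame(target = k, n = nrow(sub), successes = sum(sub$success),
               rate = if (nrow(sub)) mean(sub$success) else NA_real_)
  }))
  list(per_target = per,
       cleared = all(!is.na(per$rate)) && all(per$rate > pass_rate))
}
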
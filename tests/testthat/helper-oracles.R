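# Independent brute-force oracles used to cross-check the implementation.

# Interval search by explicit enumeration of the four regions.
oracle_classify <- function(v, b) {
  cuts <- c(0, b$b12, b$b23, b$b34, 90)
  vapply(v, function(x) {
    for (k in 1:4) {
      lo <- cuts[k]; hi <- cuts[k + 1]
      if ((x >= lo && x < hi) || (k == 4 && x == 90)) return(k)
    }
    NA_integer_
  }, integer(1))
}

# Dwell-fire detection by run-length encoding of disc membership: a run of
# >= dwell_ms in one disc produces exactly one fire at the first sample
# reaching the dwell.
oracle_dwell_fires <- function(mav, cfg) {
  cur <- mav_to_cursor(mav)
  memb <- cursor_in_target(cur$x, cur$y, cfg)
  r <- rle(memb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  fires <- data.frame(t = epoch_ct(numeric(0)), target = integer(0))
  for (i in seq_along(r$values)) {
    k <- r$values[i]
    if (k == 0) next
    tt <- as.numeric(cur$t[starts[i]:ends[i]])
    dwell_at <- which((tt - tt[1]) * 1000 >= cfg$dwell_ms)
    if (length(dwell_at)) {
      fires <- rbind(fires, data.frame(
        t = epoch_ct(tt[dwell_at[1]]), target = k))
    }
  }
  fires
}

# Two-state hand automaton replayed naively over a fire sequence.
# Each row of seq_df: fired target (1-4, already region-classified) and
# in_basket (was the cursor in the rest basket at/before this fire while
# the hand was open).
oracle_automaton <- function(targets, in_basket) {
  state <- "OPEN"; armed <- FALSE
  emitted <- integer(0)
  for (i in seq_along(targets)) {
    if (state == "OPEN" && in_basket[i]) armed <- TRUE
    k <- targets[i]
    if (is.na(k) || k == 0) next
    if (k <= 3) {
      if (state == "OPEN" && armed) {
        emitted <- c(emitted, k); state <- "CLOSED"; armed <- FALSE
      }
    } else {
      if (state == "CLOSED") {
        emitted <- c(emitted, 4L); state <- "OPEN"; armed <- FALSE
      }
    }
  }
  emitted
}

# Backward-scan feedback labeling, one feedback at a time.
oracle_label <- function(cmd_t, fb_t) {
  taken <- logical(length(cmd_t))
  links <- rep(NA_integer_, length(fb_t))
  for (i in seq_along(fb_t)) {
    best <- NA_integer_
    for (j in seq_along(cmd_t)) {
      if (cmd_t[j] < fb_t[i] && !taken[j]) best <- j
    }
    if (!is.na(best)) { taken[best] <- TRUE; links[i] <- best }
  }
  links
}

# Equal-density boundary by bisection on the log-density difference.
oracle_boundary_bisect <- function(mu_i, s_i, mu_j, s_j,
                                   pi_i = 0.5, pi_j = 0.5, tol = 1e-10) {
  f <- function(v) {
    log(pi_i) + stats::dnorm(v, mu_i, s_i, log = TRUE) -
      log(pi_j) - stats::dnorm(v, mu_j, s_j, log = TRUE)
  }
  stats::uniroot(f, c(mu_i, mu_j), tol = tol)$root
}

# Straight-line MAV trajectory builder: radius profile along a fixed angle,
# sampled every `sample_ms`.
make_ray <- function(theta_deg, radii, sample_ms = 50, t0 = epoch_ct(0)) {
  th <- theta_deg * pi / 180
  data.frame(t = t0 + (seq_along(radii) - 1) * sample_ms / 1000,
             m1 = radii * cos(th), m2 = radii * sin(th))
}

# A sine-wave EMG record for filter response checks.
make_sine_record <- function(freq_hz, fs = 500, dur_s = 4, amp = 1) {
  tt <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq_hz * tt)
  emg_record(cbind(x, x), fs = fs)
}

# RMS after dropping the filter transient at both ends.
steady_rms <- function(x, drop_frac = 0.15) {
  n <- length(x)
  keep <- seq.int(floor(n * drop_frac) + 1, ceiling(n * (1 - drop_frac)))
  sqrt(mean(x[keep]^2))
}

# Labeled-decision frame from explicit angle vectors.
decisions_from_angles <- function(v_by_target) {
  do.call(rbind, lapply(seq_along(v_by_target), function(k) {
    if (!length(v_by_target[[k]])) return(NULL)
    data.frame(v = v_by_target[[k]], executed_target = k,
               intended_target = k, unexpected = FALSE)
  }))
}

# Decision angles harvested by running reaches through the real decoder.
collect_decisions <- function(profile, n_per_target, cfg = task_space_config(),
                              boundaries = default_boundaries()) {
  out <- vector("list", 4)
  counts <- integer(4)
  clock <- 0
  gmap <- grasp_map()
  hand <- new_hand_state(); sel <- new_selection_state()
  while (any(counts < n_per_target)) {
    k <- which(counts[1:3] < n_per_target)
    k <- if (length(k)) k[1] else 1L
    # closing reach then opening reach keeps the state machine cycling and
    # harvests target-4 decisions along the way
    for (tgt in c(k, 4L)) {
      traj <- simulate_reach(profile, tgt, cfg, boundaries,
                             t_start = epoch_ct(clock))
      dec <- decode_mav_stream(traj, cfg, boundaries, gmap, hand, sel)
      hand <- dec$hand; sel <- dec$sel
      clock <- as.numeric(traj$t[nrow(traj)]) + 0.2
      if (nrow(dec$commands)) {
        ex <- dec$commands$target[1]
        if (counts[ex] < n_per_target) {
          out[[ex]] <- c(out[[ex]], dec$commands$v[1])
          counts[ex] <- counts[ex] + 1L
        }
      }
    }
  }
  decisions_from_angles(out)
}
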
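# Two-channel surface EMG -> normalized MAV control signals.
#
# The signal chain mirrors a wearable myoelectric controller sampling two
# forearm muscles (flexor/extensor carpi radialis) at 500 Hz: bandpass +
# mains-notch filtering, trailing-window mean-absolute-value (MAV)
# extraction, and calibration-based normalization to [0, m_cap].

#' Construct a two-channel EMG record
#'
#' @param samples Numeric matrix with one column per channel (exactly 2), or
#'   a data frame / list of two equal-length numeric vectors.
#' @param fs Sampling rate in Hz (default 500).
#' @param t0 Start timestamp (`POSIXct`, UTC). Defaults to the Unix epoch so
#'   purely synthetic records have a reproducible timebase.
#' @param channel_names Two channel labels.
#' @return An object of class `emg_record`.
#' @export
emg_record <- function(samples, fs = 500,
                       t0 = epoch_ct(0),
                       channel_names = c("FCR", "ECR")) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (is.list(samples)) samples <- do.call(cbind, samples)
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || ncol(samples) != 2) {
    amo_config_error("an EMG record needs exactly 2 channels (columns)")
  }
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    amo_config_error("fs must be a single positive number")
  }
  if (length(channel_names) != 2) amo_config_error("need 2 channel names")
  structure(
    list(samples = unname(samples), fs = fs,
         t0 = as.POSIXct(t0, tz = "UTC"),
         channel_names = as.character(channel_names)),
    class = "emg_record"
  )
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf("<emg_record> %d samples x 2 ch (%s, %s), fs = %g Hz, %.2f s\n",
              nrow(x$samples), x$channel_names[1], x$channel_names[2],
              x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' Filter specification for EMG preprocessing
#'
#' Defaults are a 20--230 Hz 4th-order Butterworth bandpass (fs = 500 Hz
#' leaves margin below the 250 Hz Nyquist limit) plus a 50 Hz mains notch
#' with quality factor 30. Set `notch_hz = NA` to disable the notch.
#'
#' @param band_low_hz,band_high_hz Passband edges in Hz.
#' @param band_order Butterworth order (applied forward-backward by default,
#'   so the effective order doubles).
#' @param notch_hz Mains frequency in Hz, or `NA` for no notch.
#' @param notch_q Notch quality factor (centre frequency / -3 dB width).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(band_low_hz = 20, band_high_hz = 230, band_order = 4,
                        notch_hz = 50, notch_q = 30) {
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz)) {
    amo_config_error("need 0 < band_low_hz < band_high_hz")
  }
  structure(
    list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
         band_order = band_order, notch_hz = notch_hz, notch_q = notch_q),
    class = "filter_spec"
  )
}

validate_filter_spec <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$band_high_hz >= nyq) {
    amo_config_error(sprintf(
      "band_high_hz (%g) must be below the Nyquist frequency (%g)",
      spec$band_high_hz, nyq))
  }
  if (!is.na(spec$notch_hz) && spec$notch_hz >= nyq) {
    amo_config_error("notch_hz must be below the Nyquist frequency")
  }
  invisible(spec)
}

# RBJ biquad notch coefficients (b, a), normalized to a[1] = 1.
notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Bandpass- and notch-filter an EMG record
#'
#' Zero-phase (forward-backward) filtering is the default, suitable for
#' offline analysis; `zero_phase = FALSE` gives the causal single-pass
#' variant for closed-loop simulation realism.
#'
#' @param rec An [emg_record()].
#' @param spec A [filter_spec()].
#' @param zero_phase Apply each filter forward-backward (`signal::filtfilt`).
#' @return A filtered `emg_record` on the same timebase.
#' @export
apply_filters <- function(rec, spec = filter_spec(), zero_phase = TRUE) {
  stopifnot(inherits(rec, "emg_record"), inherits(spec, "filter_spec"))
  validate_filter_spec(spec, rec$fs)
  bp <- signal::butter(spec$band_order,
                       c(spec$band_low_hz, spec$band_high_hz) / (rec$fs / 2),
                       type = "pass")
  nt <- if (!is.na(spec$notch_hz)) {
    notch_coefficients(spec$notch_hz, rec$fs, spec$notch_q)
  }
  run <- function(b, a, x) {
    if (zero_phase) signal::filtfilt(b, a, x) else
      as.numeric(signal::filter(b, a, x))
  }
  out <- apply(rec$samples, 2, function(x) {
    y <- run(bp$b, bp$a, x)
    if (!is.null(nt)) y <- run(nt$b, nt$a, y)
    y
  })
  rec$samples <- out
  rec
}

#' Trailing-window mean-absolute value of an EMG record
#'
#' Each output sample is the mean of the rectified signal over the trailing
#' window, per channel; its timestamp is the window end. This is the control
#' feature driving the task-space cursor.
#'
#' @param rec An [emg_record()].
#' @param window_ms Window length in ms (default 150).
#' @param step_ms Step between consecutive windows in ms (default 50).
#' @return Data frame with columns `t` (POSIXct), `m1`, `m2` (raw MAV in the
#'   record's amplitude units). Empty (with a warning) if the record is
#'   shorter than one window.
#' @export
compute_mav <- function(rec, window_ms = 150, step_ms = 50) {
  stopifnot(inherits(rec, "emg_record"))
  if (!(window_ms >= step_ms && step_ms > 0)) {
    amo_config_error("need window_ms >= step_ms > 0")
  }
  wn <- max(1L, round(window_ms / 1000 * rec$fs))
  sn <- max(1L, round(step_ms / 1000 * rec$fs))
  n <- nrow(rec$samples)
  if (n < wn) {
    warning("EMG record shorter than one MAV window; empty MAV stream")
    return(data.frame(t = epoch_ct(numeric(0)), m1 = numeric(0), m2 = numeric(0)))
  }
  ends <- seq.int(wn, n, by = sn)
  absx <- abs(rec$samples)
  # trailing-window mean via cumulative sums
  cs <- rbind(0, apply(absx, 2, cumsum))
  m <- (cs[ends + 1, , drop = FALSE] - cs[ends + 1 - wn, , drop = FALSE]) / wn
  data.frame(
    t = rec$t0 + (ends - 1) / rec$fs,
    m1 = m[, 1], m2 = m[, 2]
  )
}

#' Calibration parameters for MAV normalization
#'
#' @param rest_level Per-channel baseline MAV (length 2).
#' @param max_level Per-channel maximum-contraction MAV (length 2).
#' @return An object of class `calibration_params`.
#' @export
calibration_params <- function(rest_level, max_level) {
  rest_level <- as.numeric(rest_level); max_level <- as.numeric(max_level)
  if (length(rest_level) != 2 || length(max_level) != 2) {
    amo_config_error("rest_level and max_level must each have length 2")
  }
  if (any(rest_level < 0) || any(max_level <= rest_level)) {
    amo_stop("calibration requires max_level > rest_level >= 0 per channel",
             "amo_calibration_error")
  }
  structure(list(rest_level = rest_level, max_level = max_level),
            class = "calibration_params")
}

#' Calibrate MAV normalization levels from rest and contraction recordings
#'
#' The baseline is the median MAV of the rest recording; the top of the range
#' is a high percentile (default 95th) of the MAV during the channel's
#' maximum voluntary contraction -- robust to transient spikes.
#'
#' @param rest An [emg_record()] of relaxed muscles (>= 2 s).
#' @param contractions List of two [emg_record()]s, one per channel, each a
#'   maximum contraction of that channel's muscle (>= 2 s).
#' @param window_ms,step_ms MAV settings used during calibration.
#' @param percentile Contraction percentile defining `max_level`.
#' @return A [calibration_params()] object.
#' @export
calibrate <- function(rest, contractions, window_ms = 150, step_ms = 50,
                      percentile = 0.95) {
  stopifnot(inherits(rest, "emg_record"), is.list(contractions),
            length(contractions) == 2)
  min_s <- 2
  if (nrow(rest$samples) / rest$fs < min_s) {
    amo_data_error("rest recording must be at least 2 s")
  }
  rest_mav <- compute_mav(rest, window_ms, step_ms)
  rest_level <- c(stats::median(rest_mav$m1), stats::median(rest_mav$m2))
  max_level <- vapply(1:2, function(ch) {
    rec <- contractions[[ch]]
    stopifnot(inherits(rec, "emg_record"))
    if (nrow(rec$samples) / rec$fs < min_s) {
      amo_data_error(sprintf("contraction recording %d must be at least 2 s", ch))
    }
    mav <- compute_mav(rec, window_ms, step_ms)
    stats::quantile(mav[[ch + 1]], percentile, names = FALSE)
  }, numeric(1))
  if (any(max_level <= rest_level)) {
    amo_stop(paste("calibration failed: contraction MAV does not exceed rest",
                   "baseline on every channel"),
             "amo_calibration_error")
  }
  calibration_params(rest_level, max_level)
}

#' Normalize a raw MAV stream to calibration-relative units
#'
#' `m = gain * max(0, raw - rest_level) / (max_level - rest_level)`, clipped
#' at `m_cap` so overshoot beyond the calibrated maximum is representable but
#' bounded.
#'
#' @param mav_raw Data frame from [compute_mav()] (`t`, `m1`, `m2`).
#' @param params A [calibration_params()] object.
#' @param gain Per-channel scale factors (length 2).
#' @param m_cap Upper clip for the normalized MAV.
#' @return Data frame `t`, `m1`, `m2` with dimensionless MAV in `[0, m_cap]`.
#' @export
normalize_mav <- function(mav_raw, params, gain = c(1, 1), m_cap = 1.5) {
  stopifnot(inherits(params, "calibration_params"), length(gain) == 2)
  rng <- params$max_level - params$rest_level
  out <- mav_raw
  for (ch in 1:2) {
    m <- gain[ch] * pmax(0, mav_raw[[ch + 1]] - params$rest_level[ch]) / rng[ch]
    out[[ch + 1]] <- pmin(m, m_cap)
  }
  out
}

#' Write / read a two-channel EMG record as CSV plus a JSON header sidecar
#'
#' The CSV has columns `t_iso8601, ch1, ch2`; the sidecar (`<path>.json`)
#' stores `fs`, `channel_names` and `units`.
#'
#' @param rec An [emg_record()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_emg_csv` the path, invisibly; `read_emg_csv` an
#'   `emg_record`.
#' @export
write_emg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_record"))
  t <- rec$t0 + (seq_len(nrow(rec$samples)) - 1) / rec$fs
  df <- data.frame(t_iso8601 = format_iso_ms(t),
                   ch1 = fmt_num(rec$samples[, 1]),
                   ch2 = fmt_num(rec$samples[, 2]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_names = rec$channel_names, units = "a.u."),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path) {
  hdr_path <- paste0(path, ".json")
  if (!file.exists(hdr_path)) amo_parse_error(paste("missing sidecar", hdr_path))
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  df <- utils::read.csv(path, colClasses = c("character", "numeric", "numeric"))
  if (!identical(names(df), c("t_iso8601", "ch1", "ch2"))) {
    amo_parse_error("EMG CSV must have columns t_iso8601, ch1, ch2")
  }
  t0 <- if (nrow(df)) parse_iso_ms(df$t_iso8601[1]) else epoch_ct(0)
  emg_record(cbind(df$ch1, df$ch2), fs = hdr$fs, t0 = t0,
             channel_names = hdr$channel_names)
}

#' Write / read a normalized MAV stream as CSV
#'
#' Columns `t_iso8601, m1, m2`; timestamps are ISO-8601 UTC, millisecond
#' precision.
#'
#' @param mav Data frame `t`, `m1`, `m2`.
#' @param path CSV path.
#' @export
write_mav_csv <- function(mav, path) {
  df <- data.frame(t_iso8601 = format_iso_ms(mav$t),
                   m1 = fmt_num(mav$m1), m2 = fmt_num(mav$m2))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mav_csv
#' @export
read_mav_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric", "numeric"))
  if (!identical(names(df), c("t_iso8601", "m1", "m2"))) {
    amo_parse_error("MAV CSV must have columns t_iso8601, m1, m2")
  }
  data.frame(t = parse_iso_ms(df$t_iso8601), m1 = df$m1, m2 = df$m2)
}
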
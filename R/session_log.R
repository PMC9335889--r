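# Session "data bucket": synchronized, timestamped MAV stream, motor
# commands, user feedback, configuration updates and block markers, with
# feedback-to-command labeling and CSV / NDJSON / ARFF export.

empty_commands <- function() {
  data.frame(t = epoch_ct(numeric(0)), target = integer(0),
             grasp = character(0), x = numeric(0), y = numeric(0),
             r = numeric(0), v = numeric(0),
             intended_grasp = character(0), unexpected = logical(0))
}
empty_feedback <- function() {
  data.frame(t = epoch_ct(numeric(0)), intended_grasp = character(0),
             command_idx = integer(0), orphan = logical(0))
}
empty_markers <- function() {
  data.frame(t = epoch_ct(numeric(0)), marker = character(0), block = integer(0))
}
empty_config_updates <- function() {
  data.frame(t = epoch_ct(numeric(0)), name = character(0), value = character(0))
}
empty_discarded <- function() {
  data.frame(t = epoch_ct(numeric(0)), target = integer(0), reason = character(0))
}

normalize_commands <- function(commands) {
  n <- nrow(commands)
  if (is.null(commands$intended_grasp)) {
    commands$intended_grasp <- rep(NA_character_, n)
  }
  if (is.null(commands$unexpected)) commands$unexpected <- rep(FALSE, n)
  commands
}

#' Construct a session bucket
#'
#' The bucket is the per-user session store: every event stream is
#' individually time-ordered and timestamp-synchronized.
#'
#' @param mav Normalized MAV stream (`t, m1, m2`) or `NULL`.
#' @param commands Motor command data frame
#'   (`t, target, grasp, x, y, r, v[, intended_grasp, unexpected]`).
#' @param feedback User feedback data frame (`t, intended_grasp`).
#' @param discarded Ineligible selection fires rejected by the state machine.
#' @param config_updates Timestamped device-configuration changes
#'   (`t, name, value`), values serialized as JSON strings.
#' @param block_markers Block start/stop markers (`t, marker, block`).
#' @param session_start Session start timestamp.
#' @return An object of class `session_bucket`.
#' @export
session_bucket <- function(mav = NULL,
                           commands = empty_commands(),
                           feedback = empty_feedback(),
                           discarded = empty_discarded(),
                           config_updates = empty_config_updates(),
                           block_markers = empty_markers(),
                           session_start = epoch_ct(0)) {
  commands <- normalize_commands(commands)
  if (is.null(feedback$command_idx)) feedback$command_idx <- NA_integer_
  if (is.null(feedback$orphan)) feedback$orphan <- FALSE
  for (nm in c("commands", "feedback", "block_markers", "config_updates")) {
    df <- get(nm)
    if (nrow(df) && is.unsorted(as.numeric(df$t))) {
      amo_data_error(sprintf("%s stream is not time-ordered", nm))
    }
  }
  structure(
    list(mav = mav, commands = commands, feedback = feedback,
         discarded = discarded, config_updates = config_updates,
         block_markers = block_markers,
         session_start = as.POSIXct(session_start, tz = "UTC"),
         labeled = FALSE),
    class = "session_bucket"
  )
}

#' @export
print.session_bucket <- function(x, ...) {
  cat(sprintf(
    "<session_bucket> %d commands, %d feedback, %d discarded, %d blocks, %s MAV samples%s\n",
    nrow(x$commands), nrow(x$feedback), nrow(x$discarded),
    sum(x$block_markers$marker == "start"),
    if (is.null(x$mav)) "no" else nrow(x$mav),
    if (x$labeled) " [labeled]" else ""))
  invisible(x)
}

#' Label user feedback to motor commands
#'
#' Each feedback event attaches to the most recent motor command that
#' precedes it and has not already been labeled; that command is marked
#' `unexpected` with the reported intended grasp. Feedback with no eligible
#' preceding command is retained but flagged as orphan (with a warning), as
#' is feedback arriving implausibly long after its command.
#'
#' Labeling recomputes all links from scratch, so it is idempotent.
#'
#' @param bucket A [session_bucket()].
#' @param max_lag_s Lag above which a link triggers a QC warning (the link
#'   is still made; the real system imposed no bound).
#' @return The bucket with command/feedback links filled in and
#'   `labeled = TRUE`.
#' @export
label_feedback <- function(bucket, max_lag_s = 60) {
  stopifnot(inherits(bucket, "session_bucket"))
  cmd <- normalize_commands(bucket$commands)
  cmd$intended_grasp <- rep(NA_character_, nrow(cmd))
  cmd$unexpected <- rep(FALSE, nrow(cmd))
  fb <- bucket$feedback
  fb$command_idx <- rep(NA_integer_, nrow(fb))
  fb$orphan <- rep(FALSE, nrow(fb))
  taken <- logical(nrow(cmd))
  cmd_t <- as.numeric(cmd$t)
  for (i in seq_len(nrow(fb))) {
    cand <- which(cmd_t < as.numeric(fb$t[i]) & !taken)
    if (!length(cand)) {
      fb$orphan[i] <- TRUE
      warning(sprintf("orphan feedback at %s: no unlabeled preceding command",
                      format_iso_ms(fb$t[i])))
      next
    }
    j <- cand[length(cand)]
    taken[j] <- TRUE
    fb$command_idx[i] <- j
    cmd$intended_grasp[j] <- fb$intended_grasp[i]
    cmd$unexpected[j] <- TRUE
    lag <- as.numeric(fb$t[i]) - cmd_t[j]
    if (lag > max_lag_s) {
      warning(sprintf("feedback at %s lags its command by %.1f s (> %g s QC limit)",
                      format_iso_ms(fb$t[i]), lag, max_lag_s))
    }
  }
  bucket$commands <- cmd
  bucket$feedback <- fb
  bucket$labeled <- TRUE
  bucket
}

#' Extract labeled decisions from a session bucket
#'
#' One record per motor command: the decision angle `v`, the executed target,
#' and the intended target (from feedback when the command was flagged
#' unexpected, otherwise equal to the executed target). Commands without an
#' unexpected-grasp label form the training set; labeled commands form the
#' verification set.
#'
#' @param bucket A labeled [session_bucket()] (see [label_feedback()]).
#' @param include_open Keep hand-open commands (target 4)? Default `TRUE`.
#' @return Data frame `v, executed_target, intended_target, unexpected`.
#' @export
extract_labeled_decisions <- function(bucket, include_open = TRUE) {
  stopifnot(inherits(bucket, "session_bucket"))
  if (!bucket$labeled) {
    amo_data_error("bucket is unlabeled; run label_feedback() first")
  }
  cmd <- bucket$commands
  if (!include_open) cmd <- cmd[cmd$target != 4L, , drop = FALSE]
  intended <- ifelse(cmd$unexpected, grasp_to_target(cmd$intended_grasp),
                     cmd$target)
  data.frame(v = cmd$v, executed_target = cmd$target,
             intended_target = as.integer(intended),
             unexpected = cmd$unexpected)
}

# ---- serialization ---------------------------------------------------------

event_columns <- c("type", "t", "target", "grasp", "x", "y", "r", "v",
                   "intended_grasp", "unexpected", "command_idx", "orphan",
                   "marker", "block", "name", "value", "reason", "m1", "m2")

bucket_to_events <- function(bucket) {
  blank <- function(n) {
    df <- data.frame(matrix(NA, nrow = n, ncol = length(event_columns)))
    names(df) <- event_columns
    df
  }
  rows <- list()
  add <- function(type, src, fields) {
    n <- nrow(src)
    if (!n) return()
    df <- blank(n)
    df$type <- type
    df$t <- format_iso_ms(src$t)
    for (f in fields) df[[f]] <- src[[f]]
    rows[[length(rows) + 1L]] <<- df
  }
  meta <- blank(1)
  meta$type <- "session"
  meta$t <- format_iso_ms(bucket$session_start)
  rows[[1]] <- meta
  if (!is.null(bucket$mav)) add("mav", bucket$mav, c("m1", "m2"))
  add("command", bucket$commands,
      c("target", "grasp", "x", "y", "r", "v", "intended_grasp", "unexpected"))
  add("feedback", bucket$feedback, c("intended_grasp", "command_idx", "orphan"))
  add("discarded", bucket$discarded, c("target", "reason"))
  add("config_update", bucket$config_updates, c("name", "value"))
  add("block_marker", bucket$block_markers, c("marker", "block"))
  ev <- do.call(rbind, rows)
  ev[order(match(ev$type, c("session", "mav", "command", "feedback",
                            "discarded", "config_update", "block_marker"))), ]
}

events_to_bucket <- function(ev, labeled = FALSE) {
  pick <- function(type) ev[ev$type == type, , drop = FALSE]
  ses <- pick("session")
  if (nrow(ses) != 1) amo_parse_error("session file must contain exactly one session record")
  num <- function(x) as.numeric(x)
  int <- function(x) as.integer(x)
  chr <- function(x) { x <- as.character(x); x[!nzchar(x) & !is.na(x)] <- NA; x }
  lgl <- function(x) as.logical(x)
  mv <- pick("mav")
  cm <- pick("command")
  fb <- pick("feedback")
  di <- pick("discarded")
  cu <- pick("config_update")
  bm <- pick("block_marker")
  bucket <- session_bucket(
    mav = if (nrow(mv)) data.frame(t = parse_iso_ms(mv$t),
                                   m1 = num(mv$m1), m2 = num(mv$m2)),
    commands = if (nrow(cm)) data.frame(
      t = parse_iso_ms(cm$t), target = int(cm$target), grasp = chr(cm$grasp),
      x = num(cm$x), y = num(cm$y), r = num(cm$r), v = num(cm$v),
      intended_grasp = chr(cm$intended_grasp), unexpected = lgl(cm$unexpected)
    ) else empty_commands(),
    feedback = if (nrow(fb)) data.frame(
      t = parse_iso_ms(fb$t), intended_grasp = chr(fb$intended_grasp),
      command_idx = int(fb$command_idx), orphan = lgl(fb$orphan)
    ) else empty_feedback(),
    discarded = if (nrow(di)) data.frame(
      t = parse_iso_ms(di$t), target = int(di$target), reason = chr(di$reason)
    ) else empty_discarded(),
    config_updates = if (nrow(cu)) data.frame(
      t = parse_iso_ms(cu$t), name = chr(cu$name), value = chr(cu$value)
    ) else empty_config_updates(),
    block_markers = if (nrow(bm)) data.frame(
      t = parse_iso_ms(bm$t), marker = chr(bm$marker), block = int(bm$block)
    ) else empty_markers(),
    session_start = parse_iso_ms(ses$t)
  )
  bucket$labeled <- labeled
  bucket
}

#' Write a session bucket to disk
#'
#' Three dialects: `csv` (one events file with a `type` column and per-type
#' payload columns), `json` (newline-delimited JSON, one event object per
#' line), and `arff` (flat relation of motor commands with executed and
#' intended attributes; write-only). CSV and NDJSON round-trip losslessly.
#'
#' @param bucket A [session_bucket()].
#' @param path Output file path.
#' @param format `"csv"`, `"json"` or `"arff"`; inferred from the path
#'   extension by default.
#' @return `path`, invisibly.
#' @export
write_bucket <- function(bucket, path,
                         format = c("auto", "csv", "json", "arff")) {
  stopifnot(inherits(bucket, "session_bucket"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", json = "json", ndjson = "json",
                     arff = "arff",
                     amo_config_error("cannot infer bucket format from extension"))
  }
  if (format == "arff") return(write_bucket_arff(bucket, path))
  ev <- bucket_to_events(bucket)
  for (col in c("x", "y", "r", "v", "m1", "m2")) ev[[col]] <- fmt_num(num_or_na(ev[[col]]))
  if (format == "csv") {
    out <- ev
    out[] <- lapply(out, function(col) {
      col <- as.character(col); col[is.na(col)] <- ""; col
    })
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    lines <- vapply(seq_len(nrow(ev)), function(i) {
      row <- as.list(ev[i, ])
      row <- row[!vapply(row, function(x) is.na(x) || identical(x, ""), logical(1))]
      jsonlite::toJSON(row, auto_unbox = TRUE, null = "null", digits = NA)
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a session bucket written by [write_bucket()]
#'
#' @param path Path to a `.csv` or `.json`/`.ndjson` session file.
#' @param labeled Mark the bucket as already feedback-labeled. Default
#'   re-derives this from whether any command carries a label.
#' @return A [session_bucket()].
#' @export
read_bucket <- function(path, labeled = NULL) {
  if (!file.exists(path)) amo_data_error(paste("no such session file:", path))
  ext <- tolower(tools::file_ext(path))
  ev <- if (ext == "csv") {
    df <- tryCatch(
      utils::read.csv(path, colClasses = "character", fill = FALSE),
      error = function(e) amo_parse_error(paste("malformed session CSV:",
                                                conditionMessage(e))),
      warning = function(w) amo_parse_error(paste("malformed session CSV:",
                                                  conditionMessage(w))))
    if (!identical(names(df), event_columns)) {
      amo_parse_error("session CSV has unexpected columns")
    }
    df[df == ""] <- NA
    df
  } else if (ext %in% c("json", "ndjson")) {
    lines <- readLines(path)
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) amo_parse_error(
                        sprintf("malformed JSON at line %d of %s", i, path)))
      out <- as.list(rep(NA, length(event_columns)))
      names(out) <- event_columns
      out[names(rec)] <- rec
      as.data.frame(out, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    amo_config_error("read_bucket understands .csv and .json/.ndjson only")
  }
  bucket <- events_to_bucket(ev)
  bucket$labeled <- if (is.null(labeled)) {
    nrow(bucket$feedback) > 0 && any(!is.na(bucket$feedback$command_idx)) ||
      any(bucket$commands$unexpected)
  } else labeled
  bucket
}

# Minimal flat ARFF export of the motor commands (write-only).
write_bucket_arff <- function(bucket, path) {
  cmd <- bucket$commands
  grasps <- c("power", "tripod", "pinch", "point", "open")
  lines <- c(
    "@RELATION motor_commands",
    "@ATTRIBUTE t STRING",
    "@ATTRIBUTE target NUMERIC",
    sprintf("@ATTRIBUTE grasp {%s}", paste(grasps, collapse = ",")),
    "@ATTRIBUTE v NUMERIC",
    sprintf("@ATTRIBUTE intended_grasp {%s}", paste(grasps, collapse = ",")),
    "@ATTRIBUTE unexpected {true,false}",
    "@DATA"
  )
  if (nrow(cmd)) {
    rows <- sprintf("'%s',%d,%s,%s,%s,%s",
                    format_iso_ms(cmd$t), cmd$target, cmd$grasp,
                    fmt_num(cmd$v),
                    ifelse(is.na(cmd$intended_grasp), "?", cmd$intended_grasp),
                    ifelse(cmd$unexpected, "true", "false"))
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  invisible(path)
}
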
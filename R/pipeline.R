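# Device configuration and end-to-end pipeline: the DeviceConfig document
# models everything a remote server could reconfigure (boundaries, grasp
# map, gains, MAV window, dwell), and the pipeline chains signal
# processing, decoding, logging and adaptation into reproducible runs.

#' Default device configuration
#'
#' A single document holding every remotely reconfigurable parameter:
#' task-space geometry and timing, decision boundaries, grasp map, per-
#' channel gains, MAV window/step, the filter specification and the
#' calibration levels. Serialized as YAML or JSON.
#'
#' @return A list of class `device_config`.
#' @export
default_device_config <- function() {
  structure(list(
    task_space = unclass(task_space_config()),
    boundaries = unclass(default_boundaries()),
    grasp_map = list(target2 = "tripod"),
    gains = c(1, 1),
    mav = list(window_ms = 150, step_ms = 50, m_cap = 1.5),
    filter = unclass(filter_spec()),
    calibration = list(rest_level = c(0, 0), max_level = c(1, 1)),
    streaming = list(data = TRUE, mav = TRUE)
  ), class = "device_config")
}

config_objects <- function(config) {
  list(
    cfg = do.call(task_space_config, config$task_space),
    boundaries = do.call(decision_boundaries, config$boundaries),
    gmap = grasp_map(config$grasp_map$target2),
    params = calibration_params(config$calibration$rest_level,
                                config$calibration$max_level)
  )
}

#' Read / write a device configuration (YAML or JSON)
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @param config A `device_config` list (for writing).
#' @return `read_device_config`: a validated `device_config`.
#' @export
read_device_config <- function(path) {
  if (!file.exists(path)) amo_config_error(paste("no such config file:", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    amo_config_error("config must be .yaml/.yml or .json")
  }
  config <- utils::modifyList(default_device_config(), raw)
  config_objects(config)  # validates; errors are configuration errors
  config
}

#' @rdname read_device_config
#' @export
write_device_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  stripped <- rapply(unclass(config), identity, how = "replace")
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(stripped, path)
  } else if (ext == "json") {
    jsonlite::write_json(stripped, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    amo_config_error("config must be .yaml/.yml or .json")
  }
  invisible(path)
}

#' Run the full decoding pipeline
#'
#' Chains the stages: raw EMG (filter, MAV, normalize) or a precomputed
#' normalized MAV stream, then the abstract decoder and the session bucket.
#' Deterministic given its inputs: a MAV-only run equals the equivalent
#' pre-filtered EMG run downstream.
#'
#' @param emg An [emg_record()] of raw EMG, or `NULL` if `mav` is given.
#' @param mav A normalized MAV stream (`t, m1, m2`), or `NULL`.
#' @param config A `device_config` (see [default_device_config()]).
#' @param keep_mav Store the MAV stream in the bucket.
#' @return A [session_bucket()] with decoded motor commands.
#' @export
run_pipeline <- function(emg = NULL, mav = NULL,
                         config = default_device_config(),
                         keep_mav = TRUE) {
  if (is.null(emg) == is.null(mav)) {
    amo_config_error("supply exactly one of emg or mav")
  }
  ob <- config_objects(config)
  if (!is.null(emg)) {
    filt <- apply_filters(emg, do.call(filter_spec, config$filter))
    raw <- compute_mav(filt, config$mav$window_ms, config$mav$step_ms)
    mav <- normalize_mav(raw, ob$params, gain = config$gains,
                         m_cap = config$mav$m_cap)
  }
  dec <- decode_mav_stream(mav, ob$cfg, ob$boundaries, ob$gmap)
  session_bucket(
    mav = if (keep_mav) mav,
    commands = dec$commands,
    discarded = dec$discarded,
    session_start = if (nrow(mav)) mav$t[1] else epoch_ct(0)
  )
}

#' Adapt a device configuration from a session bucket
#'
#' Labels the feedback, partitions the decisions, fits the angle models,
#' computes the equal-density boundaries and verifies them on the
#' unexpected decisions. Returns the updated configuration together with
#' the adaptation report data.
#'
#' @param bucket A [session_bucket()].
#' @param config The `device_config` in force during the session.
#' @param priors_mode Passed to [adapt_boundaries()].
#' @return List: `config` (updated), `boundaries`, `result` (an
#'   `adaptation_result`), `decisions`, `models`.
#' @export
adapt_from_bucket <- function(bucket, config = default_device_config(),
                              priors_mode = "equal") {
  if (!bucket$labeled) bucket <- label_feedback(bucket)
  decisions <- extract_labeled_decisions(bucket)
  training <- decisions[!decisions$unexpected, , drop = FALSE]
  verification <- decisions[decisions$unexpected, , drop = FALSE]
  defaults <- do.call(decision_boundaries, config$boundaries)
  adapted <- adapt_boundaries(training, defaults, priors_mode = priors_mode)
  result <- verify_boundaries(adapted, verification)
  config$boundaries <- list(b12 = adapted$b12, b23 = adapted$b23,
                            b34 = adapted$b34)
  list(config = config, boundaries = adapted, result = result,
       decisions = decisions, models = attr(adapted, "models"))
}

#' Session report: boundary table and feedback/correction counts
#'
#' Emits the per-user report shape of the study: default versus customized
#' boundary angles for the three adjacent-target pairs, and the number of
#' user feedback events with the number of corrections under the adapted
#' boundaries. Optionally written as JSON and markdown.
#'
#' @param bucket A *labeled* [session_bucket()] (run [label_feedback()]
#'   first, or use [adapt_from_bucket()]).
#' @param config Device configuration in force during the session.
#' @param out_dir Optional directory to write `report.json` and
#'   `report.md` into.
#' @param priors_mode Passed to [adapt_boundaries()].
#' @return List of class `session_report`: `boundary_table` (data frame
#'   with `default` and `customized` rows), `counts` (n_commands,
#'   n_training, n_feedback, n_corrected).
#' @export
session_report <- function(bucket, config = default_device_config(),
                           out_dir = NULL, priors_mode = "equal") {
  if (!bucket$labeled) {
    amo_data_error(paste("bucket is unlabeled; run label_feedback() (or",
                         "adapt_from_bucket()) before reporting"))
  }
  ad <- adapt_from_bucket(bucket, config, priors_mode)
  defaults <- do.call(decision_boundaries, config$boundaries)
  boundary_table <- data.frame(
    row = c("default", "customized"),
    boundary_1_2 = c(defaults$b12, ad$boundaries$b12),
    boundary_2_3 = c(defaults$b23, ad$boundaries$b23),
    boundary_3_4 = c(defaults$b34, ad$boundaries$b34)
  )
  counts <- data.frame(
    n_commands = nrow(bucket$commands),
    n_training = sum(!ad$decisions$unexpected),
    n_feedback = ad$result$n_feedback,
    n_corrected = ad$result$n_corrected
  )
  rep <- structure(list(boundary_table = boundary_table, counts = counts,
                        models = ad$models, config = ad$config),
                   class = "session_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(boundary_table = boundary_table, counts = counts),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    writeLines(format_report_md(rep), file.path(out_dir, "report.md"))
  }
  rep
}

format_report_md <- function(rep) {
  bt <- rep$boundary_table
  cn <- rep$counts
  c("# Session report",
    "",
    "## Decision boundaries (degrees)",
    "",
    "| | boundary 1-2 | boundary 2-3 | boundary 3-4 |",
    "|---|---|---|---|",
    sprintf("| %s | %.1f | %.1f | %.1f |", bt$row, bt$boundary_1_2,
            bt$boundary_2_3, bt$boundary_3_4),
    "",
    "## Feedback and corrections",
    "",
    "| commands | training | feedback | corrections |",
    "|---|---|---|---|",
    sprintf("| %d | %d | %d | %d |", cn$n_commands, cn$n_training,
            cn$n_feedback, cn$n_corrected))
}

#' @export
print.session_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}

#' Write a run manifest for a pipeline invocation
#'
#' Every output directory gets exactly one manifest: the command, a
#' snapshot of the configuration, MD5 hashes of the inputs, the seed, the
#' package version and a timestamp -- enough to reproduce the run.
#'
#' @param out_dir Output directory.
#' @param command Command name (e.g. `"simulate"`).
#' @param config The `device_config` used.
#' @param inputs Character vector of input file paths (hashed).
#' @param seed Integer seed or `NULL`.
#' @return Path to `manifest.json`, invisibly.
#' @export
write_run_manifest <- function(out_dir, command, config, inputs = character(),
                               seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else list()
  manifest <- list(
    command = command,
    config = rapply(unclass(config), identity, how = "replace"),
    input_md5 = hashes,
    seed = seed,
    package_version = as.character(utils::packageVersion("abstractmyo")),
    created = format_iso_ms(Sys.time())
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
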
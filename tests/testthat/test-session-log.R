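# Feedback labeling, decision extraction, and session serialization.

mk_commands <- function(t, target = NULL, v = NULL) {
  n <- length(t)
  if (is.null(target)) target <- rep(1L, n)
  if (is.null(v)) v <- rep(10, n)
  gm <- grasp_map()
  data.frame(t = epoch_ct(t), target = as.integer(target),
             grasp = unclass(gm)[target], x = cospi(v / 180) * 0.7,
             y = sinpi(v / 180) * 0.7, r = 0.7, v = v)
}

mk_feedback <- function(t, grasp = "tripod") {
  data.frame(t = epoch_ct(t), intended_grasp = rep(grasp, length(t)))
}

test_that("feedback labels the most recent unlabeled preceding command", {
  b <- session_bucket(commands = mk_commands(c(10, 20)),
                      feedback = mk_feedback(25))
  b <- label_feedback(b)
  expect_identical(b$feedback$command_idx, 2L)
  expect_identical(b$commands$unexpected, c(FALSE, TRUE))
  expect_identical(b$commands$intended_grasp, c(NA, "tripod"))

  # a second feedback after the same command walks back to the first command
  b2 <- session_bucket(commands = mk_commands(c(10, 20)),
                       feedback = mk_feedback(c(25, 26)))
  b2 <- suppressWarnings(label_feedback(b2))
  expect_identical(b2$feedback$command_idx, c(2L, 1L))

  # feedback with no preceding command at all is an orphan, retained
  expect_warning(label_feedback(session_bucket(feedback = mk_feedback(25))),
                 "orphan")
  b3 <- session_bucket(commands = mk_commands(30),
                       feedback = mk_feedback(c(25, 40, 41)))
  b3 <- suppressWarnings(label_feedback(b3))
  expect_identical(b3$feedback$orphan, c(TRUE, FALSE, TRUE))
  expect_identical(nrow(b3$feedback), 3L)
})

test_that("labeling is idempotent and warns on implausible lags", {
  b <- session_bucket(commands = mk_commands(c(10, 20)),
                      feedback = mk_feedback(25))
  b1 <- label_feedback(b)
  b2 <- label_feedback(b1)
  expect_identical(b1$commands, b2$commands)
  expect_identical(b1$feedback, b2$feedback)

  blag <- session_bucket(commands = mk_commands(10),
                         feedback = mk_feedback(200))
  expect_warning(label_feedback(blag), "lags")
})

test_that("labeling equals the brute-force backward scan on fuzzed interleavings", {
  set.seed(61)
  for (rep in 1:25) {
    n_cmd <- 30; n_fb <- 8
    cmd_t <- sort(runif(n_cmd, 0, 1000))
    fb_t <- sort(runif(n_fb, 0, 1100))
    b <- session_bucket(commands = mk_commands(cmd_t),
                        feedback = mk_feedback(fb_t))
    b <- suppressWarnings(label_feedback(b, max_lag_s = Inf))
    expect_identical(b$feedback$command_idx, oracle_label(cmd_t, fb_t))
  }
})

test_that("decision extraction partitions commands and conserves counts", {
  b <- session_bucket(commands = mk_commands(seq(10, 100, by = 10)))
  b <- label_feedback(b)
  d <- extract_labeled_decisions(b)
  expect_identical(nrow(d), 10L)
  expect_identical(sum(d$unexpected), 0L)

  b2 <- session_bucket(
    commands = mk_commands(seq(10, 100, by = 10), target = rep(1:2, 5)),
    feedback = mk_feedback(c(15, 35, 75)))
  b2 <- label_feedback(b2)
  d2 <- extract_labeled_decisions(b2)
  expect_identical(sum(!d2$unexpected), 7L)
  expect_identical(sum(d2$unexpected), 3L)
  expect_identical(sum(!d2$unexpected) + sum(d2$unexpected), nrow(b2$commands))
  # intended target from feedback where labeled, else the executed target
  expect_true(all(d2$intended_target[d2$unexpected] == 2L))
  expect_true(all(d2$intended_target[!d2$unexpected] ==
                    d2$executed_target[!d2$unexpected]))
  # unlabeled bucket refuses extraction
  expect_error(extract_labeled_decisions(session_bucket()),
               class = "amo_data_error")
})

test_that("the verification set is exactly the mis-executed reaches of a simulated session", {
  p <- virtual_user_profile(misaim_prob = 0.25, seed = 99)
  sim <- simulate_session(p, block_plan(8), keep_mav = FALSE)
  b <- label_feedback(sim$bucket)
  d <- extract_labeled_decisions(b)
  wrong <- sim$truth[!is.na(sim$truth$executed_target) &
                       sim$truth$executed_target != sim$truth$intended_target, ]
  expect_identical(sum(d$unexpected), nrow(wrong))
  # each unexpected decision's executed/intended pair appears in the truth
  expect_setequal(
    paste(d$executed_target[d$unexpected], d$intended_target[d$unexpected]),
    paste(wrong$executed_target, wrong$intended_target))
})

test_that("session buckets round-trip through CSV and NDJSON", {
  p <- virtual_user_profile(misaim_prob = 0.2, seed = 7)
  sim <- simulate_session(p, block_plan(4))
  b <- suppressWarnings(label_feedback(sim$bucket))
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_bucket(b, path)
    back <- read_bucket(path)
    for (fld in c("commands", "feedback", "discarded", "config_updates",
                  "block_markers", "mav")) {
      got <- back[[fld]]; want <- b[[fld]]
      expect_identical(dim(got), dim(want))
      for (col in names(want)) {
        if (inherits(want[[col]], "POSIXct")) {
          expect_equal(as.numeric(got[[col]]), as.numeric(want[[col]]),
                       tolerance = 2e-3)
        } else {
          expect_equal(got[[col]], want[[col]])
        }
      }
    }
    # write-read-write is byte-stable
    path2 <- withr::local_tempfile(fileext = ext)
    write_bucket(back, path2)
    expect_identical(readLines(path2), readLines(path))
  }
})

test_that("an empty session round-trips and truncated CSV fails loudly", {
  b <- session_bucket()
  path <- withr::local_tempfile(fileext = ".csv")
  write_bucket(b, path)
  back <- read_bucket(path)
  expect_identical(nrow(back$commands), 0L)
  expect_identical(nrow(back$feedback), 0L)

  # chop the last line mid-record: no partial silent load
  p2 <- withr::local_tempfile(fileext = ".csv")
  full <- readLines(write_bucket(
    session_bucket(commands = mk_commands(c(1, 2, 3))),
    withr::local_tempfile(fileext = ".csv")))
  writeLines(c(full[-length(full)],
               substr(full[length(full)], 1, 20)), p2)
  expect_error(read_bucket(p2), class = "amo_parse_error")

  pj <- withr::local_tempfile(fileext = ".json")
  writeLines(c('{"type":"session","t":"2026-01-01T00:00:00.000Z"}',
               '{"type":"command","t":'), pj)
  expect_error(read_bucket(pj), class = "amo_parse_error")
})

test_that("ARFF export writes a flat command relation", {
  b <- session_bucket(commands = mk_commands(c(1, 2), target = c(1, 4)))
  b <- label_feedback(b)
  path <- withr::local_tempfile(fileext = ".arff")
  write_bucket(b, path)
  lines <- readLines(path)
  expect_identical(lines[1], "@RELATION motor_commands")
  expect_identical(sum(grepl("^@ATTRIBUTE", lines)), 6L)
  expect_identical(length(lines) - which(lines == "@DATA"), 2L)
})
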
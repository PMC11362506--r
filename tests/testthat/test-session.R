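# Sessions, familiarisation, the two CSV datafiles, and log replay.

short_exhibition_config <- function() {
  staircase_config(2, phases = list(c(2, 2), c(4, sqrt(2))),
                   start_delta = 100, reversal_threshold_k = 4)
}

test_that("familiarisation passes after the required streak and resets on errors", {
  sp <- experiment_spec("freq_disc_tone")
  set.seed(1)
  fam <- run_familiarisation(sp, correctness_responder(rep(TRUE, 6)))
  expect_true(fam$passed)
  expect_equal(fam$n_trials, 6L)
  expect_true(all(fam$log$delta %in% c(100, 50)))
  # CCCCEC...: the error at trial 5 resets the streak
  set.seed(2)
  fam <- run_familiarisation(
    sp, correctness_responder(c(TRUE, TRUE, TRUE, TRUE, FALSE, rep(TRUE, 6))))
  expect_true(fam$passed)
  expect_equal(fam$n_trials, 11L)
  # a guessing responder essentially never makes six in a row within the cap
  set.seed(3)
  fam <- run_familiarisation(sp, observer_responder(chance_observer(3)),
                             max_trials = 30)
  expect_false(fam$passed)
  expect_equal(fam$n_trials, 30L)
})

test_that("a scripted block reproduces the hand-computed reversal ledger", {
  sp <- experiment_spec("freq_disc_tone")
  cfg <- staircase_config(2, phases = list(c(6, 2)), start_delta = 100,
                          reversal_threshold_k = 4)
  # ++ ++ - ++ - ++ - ++ : reversals at deltas 25,50,25,50,25,50
  script <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE,
              FALSE, TRUE, TRUE)
  set.seed(9)
  blk <- run_block(sp, cfg, correctness_responder(script))
  expect_equal(blk$result$reversal_deltas, c(25, 50, 25, 50, 25, 50))
  expect_equal(blk$result$reversal_trials, c(5L, 7L, 8L, 10L, 11L, 13L))
  expect_equal(blk$result$n_trials, 13L)
  expect_equal(nrow(blk$records), 13L)               # one record per trial
  expect_equal(blk$result$threshold$value, mean(c(50, 25, 50, 25)))
  expect_equal(blk$records$Reversals[13], 6L)
  expect_equal(blk$records$Delta, c(100, 100, 50, 50, 25, 50, 50, 25, 50,
                                    50, 25, 50, 50))
})

test_that("the short exhibition configuration stops at its sixth reversal", {
  sp <- experiment_spec("freq_disc_tone")
  obs <- psychometric_observer(10, 4, gamma = 1 / 3)
  set.seed(14)
  blk <- run_block(sp, short_exhibition_config(), observer_responder(obs))
  expect_length(blk$result$reversal_deltas, 6L)
  expect_true(blk$result$complete)
  expect_equal(blk$result$threshold$n_reversals_used, 4L)
})

test_that("the session threshold is the mean of the block thresholds", {
  sp <- experiment_spec("freq_disc_tone")
  cfg <- staircase_config(2, phases = list(c(6, 2)), start_delta = 100,
                          reversal_threshold_k = 4)
  script <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE,
              FALSE, TRUE, TRUE)
  # identical scripted blocks: session threshold equals the block threshold
  s1 <- run_session(sp, cfg, correctness_responder(rep(script, 3)),
                    n_blocks = 3, seed = 4)
  expect_equal(s1$block_thresholds, rep(37.5, 3))
  expect_equal(s1$threshold, 37.5)
  s2 <- run_session(sp, cfg, correctness_responder(script), n_blocks = 1,
                    seed = 4)
  expect_equal(s2$threshold, s2$block_thresholds[1])
})

test_that("an eight-block session writes eight rows to the reduced file", {
  sp <- experiment_spec("freq_disc_tone")
  obs <- psychometric_observer(10, 4, gamma = 1 / 3)
  out <- tempfile(); dir.create(out)
  s <- run_session(sp, short_exhibition_config(), observer_responder(obs),
                   n_blocks = 8, seed = 21, out_dir = out, basename = "lab")
  red <- utils::read.csv(file.path(out, "lab_reduced.csv"),
                         check.names = FALSE)
  expect_equal(nrow(red), 8L)
  expect_equal(mean(red$Threshold), s$threshold)     # cross-file consistency
  expect_equal(red$Threshold, s$block_thresholds)
})

test_that("the extended datafile carries the documented columns and exact deltas", {
  sp <- experiment_spec("freq_disc_tone")
  obs <- psychometric_observer(10, 4, gamma = 1 / 3)
  out <- tempfile(); dir.create(out)
  s <- run_session(sp, short_exhibition_config(), observer_responder(obs),
                   n_blocks = 2, seed = 33, out_dir = out,
                   participant = participant_info("Ada", "L.", 36, "F",
                                                  "pilot run"))
  df <- read_extended_csv(file.path(out, "session_extended.csv"))
  expect_true(all(c("nAFC", "ISI", "ITI", "Reversal threshold", "Algorithm",
                    "Delta", "Correct", "Reversals") %in% names(df)))
  expect_equal(nrow(df), nrow(s$records))
  expect_identical(df$Delta, s$records$Delta)        # exact round trip
  expect_equal(unique(df$Algorithm), "2-down/1-up")
  expect_equal(unique(df$nAFC), 3L)
  expect_equal(df$Name[1], "Ada")
  # the last record of each block reports the full reversal count
  for (b in 1:2) {
    rows <- df[df$Block == b, ]
    expect_equal(rows$Reversals[nrow(rows)],
                 length(s$blocks[[b]]$reversal_deltas))
  }
})

test_that("missing demographics are written as empty fields", {
  sp <- experiment_spec("freq_disc_tone")
  out <- tempfile(); dir.create(out)
  cfg <- staircase_config(2, phases = list(c(6, 2)), start_delta = 100,
                          reversal_threshold_k = 4)
  script <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE,
              FALSE, TRUE, TRUE)
  set.seed(8)
  run_session(sp, cfg, correctness_responder(script), n_blocks = 1,
              out_dir = out)
  line2 <- readLines(file.path(out, "session_reduced.csv"))[2]
  expect_match(line2, '^"","",,"",""')
})

test_that("replaying an extended log reproduces the datafile byte for byte", {
  obs <- psychometric_observer(10, 4, gamma = 1 / 3)
  out <- tempfile(); dir.create(out)
  # one tone task and one noise task, multiple blocks each
  cases <- list(
    list(spec = experiment_spec("freq_disc_tone"), seed = 101),
    list(spec = experiment_spec("gap_detection_noise", start_delta = 20),
         seed = 102))
  for (case in cases) {
    cfg <- staircase_config(2, phases = list(c(2, 2), c(4, sqrt(2))),
                            start_delta = case$spec$start_delta,
                            reversal_threshold_k = 4)
    base <- paste0("replay", case$seed)
    s <- run_session(case$spec, cfg, observer_responder(obs), n_blocks = 2,
                     seed = case$seed, out_dir = out, basename = base)
    orig <- file.path(out, paste0(base, "_extended.csv"))
    replayed <- replay_session(orig)
    expect_equal(replayed$threshold, s$threshold)
    expect_equal(replayed$records$Delta, s$records$Delta)
    copy <- tempfile(fileext = ".csv")
    write_extended_csv(replayed, copy)
    expect_identical(readBin(orig, "raw", file.size(orig) + 10),
                     readBin(copy, "raw", file.size(copy) + 10))
  }
})

test_that("incomplete blocks are flagged and the session mean uses completed ones", {
  sp <- experiment_spec("freq_disc_tone")
  cfg <- staircase_config(2, phases = list(c(4, 2), c(8, sqrt(2))),
                          start_delta = 100, max_trials = 10L)
  obs <- psychometric_observer(10, 4, gamma = 1 / 3)
  set.seed(77)
  w <- capture_warnings(
    s <- run_session(sp, cfg, observer_responder(obs), n_blocks = 2))
  expect_true(any(grepl("trial cap", w)))
  expect_true(any(grepl("incomplete", w)))
  expect_true(any(!vapply(s$blocks, function(b) b$complete, logical(1))))
})
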
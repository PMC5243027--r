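# Session-level contracts of the task protocol. Small simulations only;
# the larger study-condition fixtures live with the acceptance tests.

tiny_session <- function(n_trials = 3, coherence = 0.512, isi = 2,
                         continuity = "continuous", stimulation = "none") {
  trials <- data.frame(coherence = rep(coherence, n_trials),
                       direction = rep(c("right", "left"),
                                       length.out = n_trials))
  session_spec(trials, isi = isi, continuity = continuity,
               stimulation = stimulation)
}

tiny_subject <- function(seed = 1, architecture = "attractor") {
  with_local <- attractorchoice:::with_local_seed
  with_local(seed, sample_virtual_subject(1, architecture))
}

test_that("a session produces one record per trial with the record
          dialect", {
  subj <- tiny_subject(3)
  res <- run_session(subj, tiny_session(3))
  rec <- res$records
  expect_equal(nrow(rec), 3)
  expect_true(all(c("subject_id", "block", "condition", "trial_index",
                    "coherence_signed", "direction", "choice", "responded",
                    "decision_time_s", "prestim_rate_chosen_hz",
                    "prestim_rate_unchosen_hz", "previous_choice", "correct")
                  %in% names(rec)))
  expect_equal(rec$previous_choice[1], "none")
  expect_identical(rec$previous_choice[-1], rec$choice[-3])
  expect_identical(rec$coherence_signed,
                   ifelse(rec$direction == "left", -0.512, 0.512))
  # decision times, when present, fall inside the response window
  dt <- rec$decision_time_s[rec$responded == 1]
  expect_true(all(dt >= 0 & dt <= 2))
})

test_that("an empty trial list yields an empty record table", {
  subj <- tiny_subject(3)
  res <- run_session(subj, tiny_session(0))
  expect_equal(nrow(res$records), 0)
})

test_that("an unattainable response threshold flags every trial as
          no-response", {
  subj <- tiny_subject(4)
  subj$response_threshold <- 10000
  res <- run_session(subj, tiny_session(2))
  expect_true(all(res$records$choice == "none"))
  expect_true(all(res$records$responded == 0))
  expect_true(all(is.na(res$records$decision_time_s)))
})

test_that("task input events reach only the selective populations", {
  subj <- tiny_subject(5)
  res <- run_session(subj, tiny_session(2))
  expect_equal(res$task_events_other, 0)
  expect_gt(res$task_events_selective, 0)
})

test_that("identical subject, session and seeds reproduce records
          exactly", {
  subj <- tiny_subject(6)
  sess <- tiny_session(3)
  res1 <- run_session(subj, sess, return_traces = FALSE)
  res2 <- run_session(subj, sess, return_traces = FALSE)
  expect_identical(res1$records, res2$records)
  subj2 <- tiny_subject(7)
  res3 <- run_session(subj2, sess, return_traces = FALSE)
  expect_false(identical(res1$records, res3$records))
})

test_that("stimulation conditions change the trajectory while sharing the
          wiring", {
  subj <- tiny_subject(8)
  none <- run_session(subj, tiny_session(2), return_traces = FALSE)
  depol <- run_session(subj, tiny_session(2, stimulation = "depolarizing"),
                       return_traces = FALSE)
  expect_false(identical(none$state$V, depol$state$V))
})

test_that("winner-take-all: high-coherence input separates the selective
          pools in nearly every trial", {
  subj <- tiny_subject(9)
  n_trials <- 50
  sess <- tiny_session(n_trials)
  res <- run_session(subj, sess)
  steps_per_s <- 2000
  separated <- vapply(seq_len(n_trials), function(k) {
    i0 <- (k - 1) * res$trial_steps
    input_win <- (i0 + steps_per_s + 1):(i0 + 2 * steps_per_s)
    late <- tail(input_win, 1000)  # last 500 ms of input
    peak_l <- max(res$traces$left[input_win])
    peak_r <- max(res$traces$right[input_win])
    winner <- if (peak_l > peak_r) "left" else "right"
    loser_late <- if (winner == "left") res$traces$right[late] else
      res$traces$left[late]
    max(peak_l, peak_r) > 20 && min(loser_late) < 5
  }, logical(1))
  expect_gte(mean(separated), 0.9)
})

test_that("trial records round-trip through the CSV dialect", {
  subj <- tiny_subject(10)
  rec <- run_session(subj, tiny_session(2), return_traces = FALSE)$records
  path <- tempfile(fileext = ".csv")
  write_trial_records(rec, path)
  back <- read_trial_records(path)
  expect_equal(back$coherence_signed, rec$coherence_signed)
  expect_equal(back$choice, rec$choice)
  expect_equal(back$decision_time_s, rec$decision_time_s)
  # missing columns are rejected
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_trial_records(bad), "missing columns")
})

test_that("rate traces and spike lists serialize to plain text", {
  tr <- population_rate_trace(c(5, 7.5), n_neurons = 10, duration_ms = 20,
                              population = "left")
  path <- tempfile(fileext = ".csv")
  write_rate_trace(tr, path)
  back <- read.csv(path)
  expect_equal(back$rate_hz, tr$rate_hz)
  spath <- tempfile(fileext = ".txt")
  write_spikes(c(3L, 8L), c(5, 7.5), spath)
  sp <- read.table(spath, header = TRUE)
  expect_equal(sp$neuron_id, c(3, 8))
  expect_equal(sp$time_ms, c(5, 7.5))
})
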
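# Shared simulation fixtures, computed once per test run and reused across
# files (test files run in one process). Scales are the package's desk-scale
# study conditions: the trial protocol, coherence levels, ISI and
# stimulation conditions follow the full design, with fewer subjects and
# repetitions per cell.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, compute) {
  if (!exists(name, envir = .fixture_env)) {
    message("computing fixture '", name, "' ...")
    assign(name, compute(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Within-subject stimulation experiment: 8 subjects x {none, depolarizing,
# hyperpolarizing}, continuous sessions, ISI 2 s. The no-stimulation block
# uses the full 100-trial design; the stimulation blocks use 60 trials.
stim_experiment <- function() fixture("stim", function() {
  run_stimulation_experiment(experiment_config(
    experiment = "stimulation", n_subjects = 8,
    reps_per_direction = c(10, 6, 6),
    master_seed = 101))
})

# Between-group ISI comparison: 5 independent subjects per level, no
# stimulation; 40 trials at 1.5 s and 30 trials at 5 s (those sessions are
# twice as long).
isi_experiment_fixture <- function() fixture("isi", function() {
  seeded <- attractorchoice:::seeded_subject
  records <- list()
  sid <- 0L
  for (spec in list(list(isi = 1.5, reps = 4), list(isi = 5, reps = 3))) {
    for (s in 1:5) {
      subject <- seeded(202, paste0("isi", spec$isi), s, "attractor")
      sid <- sid + 1L
      subject$subject_id <- sid
      rec <- run_subject_conditions(subject, "none", isi = spec$isi,
                                    reps_per_direction = spec$reps)
      records[[sid]] <- transform(rec, isi = spec$isi)
    }
  }
  records <- do.call(rbind, records)
  summary <- summarize_subjects(records)
  summary$isi <- records$isi[match(summary$subject_id, records$subject_id)]
  list(records = records, summary = summary)
})

# Reinitialized control: 6 subjects, no stimulation, 40 trials.
reinit_experiment <- function() fixture("reinit", function() {
  run_stimulation_experiment(experiment_config(
    experiment = "controls", n_subjects = 6, reps_per_direction = 4,
    conditions = "none", continuity = "reinitialized", master_seed = 303))
})

# Accumulator control: 6 subjects, no stimulation, 40 trials.
accumulator_experiment <- function() fixture("accumulator", function() {
  run_stimulation_experiment(experiment_config(
    experiment = "accumulator", n_subjects = 6, reps_per_direction = 4,
    conditions = "none", architecture = "accumulator", master_seed = 404))
})

# Prestimulus bias per trial from the record columns (chosen minus
# unchosen mean rate over the 500 ms before input onset).
record_bias <- function(records) {
  use <- records$responded == 1 &
    records$previous_choice %in% c("left", "right") &
    is.finite(records$prestim_rate_chosen_hz)
  rec <- records[use, ]
  data.frame(subject_id = rec$subject_id,
             condition = rec$condition,
             bias_hz = rec$prestim_rate_chosen_hz - rec$prestim_rate_unchosen_hz,
             repeated = rec$choice == rec$previous_choice)
}

# One-sample Wilcoxon against zero via the paired interface.
wilcoxon_vs_zero <- function(x) {
  x <- x[is.finite(x)]
  wilcoxon_signed_rank(x, rep(0, length(x)))
}
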
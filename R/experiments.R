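#' Experiment configuration
#'
#' Bundles the scale, conditions and variant flags of a simulated experiment.
#' All subject- and block-level seeds derive deterministically from
#' `master_seed`, so a configuration reproduces its results exactly.
#'
#' @param experiment one of `"stimulation"`, `"isi"`, `"controls"`,
#'   `"accumulator"`, `"synthetic_recovery"`.
#' @param n_subjects virtual subjects per group.
#' @param coherences coherence levels.
#' @param reps_per_direction trials per coherence x direction cell per block.
#' @param conditions stimulation condition names (see
#'   [stimulation_currents()]).
#' @param isi_levels inter-stimulus intervals (s) for the ISI experiment.
#' @param total_rate,refresh_hz task-input variant flags.
#' @param continuity `"continuous"` or `"reinitialized"`.
#' @param architecture `"attractor"` or `"accumulator"`.
#' @param master_seed integer master seed.
#' @param output_dir optional directory for result files.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("stimulation", "isi", "controls",
                                             "accumulator", "synthetic_recovery"),
                              n_subjects = 20,
                              coherences = c(0.032, 0.064, 0.128, 0.256, 0.512),
                              reps_per_direction = 10,
                              conditions = c("none", "depolarizing", "hyperpolarizing"),
                              isi_levels = c(1.5, 2, 3, 5),
                              total_rate = 80, refresh_hz = 60,
                              continuity = c("continuous", "reinitialized"),
                              architecture = c("attractor", "accumulator"),
                              master_seed = 1L,
                              output_dir = NULL) {
  experiment <- match.arg(experiment)
  continuity <- match.arg(continuity)
  architecture <- match.arg(architecture)
  if (n_subjects < 1) stop("need at least one subject", call. = FALSE)
  structure(list(experiment = experiment, n_subjects = n_subjects,
                 coherences = coherences,
                 reps_per_direction = reps_per_direction,
                 conditions = conditions, isi_levels = isi_levels,
                 total_rate = total_rate, refresh_hz = refresh_hz,
                 continuity = continuity, architecture = architecture,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = c("experiment_config", "list"))
}

# deterministic subject for (master_seed, group label, id)
seeded_subject <- function(master_seed, group, id, architecture) {
  with_local_seed(derive_seed(master_seed, "subject", group, id),
                  sample_virtual_subject(id, architecture))
}

#' Simulate one subject under several conditions
#'
#' Runs one block per condition with identical wiring and subject
#' parameters, reusing the built network, as in a within-subject design.
#'
#' @param subject a [sample_virtual_subject()] result.
#' @param conditions character vector of stimulation condition names.
#' @param isi inter-stimulus interval (s).
#' @param continuity session continuity mode.
#' @param coherences,reps_per_direction trial design;
#'   `reps_per_direction` may be a vector, one entry per condition.
#' @param input an [input_spec()].
#' @param config optional [network_config()] override.
#' @return Row-bound trial records for all blocks.
#' @export
run_subject_conditions <- function(subject, conditions, isi = 2,
                                   continuity = "continuous",
                                   coherences = c(0.032, 0.064, 0.128, 0.256, 0.512),
                                   reps_per_direction = 10,
                                   input = input_spec(),
                                   config = NULL) {
  if (is.null(config)) {
    config <- network_preset(
      if (subject$architecture == "attractor") "competitive" else "accumulator",
      wiring_seed = subject$wiring_seed)
  }
  network <- build_network(config)
  reps <- rep_len(reps_per_direction, length(conditions))
  out <- list()
  for (b in seq_along(conditions)) {
    cond <- conditions[b]
    trials <- with_local_seed(derive_seed(subject$session_seed, "trials", cond),
                              make_trial_list(coherences, reps[b]))
    sess <- session_spec(trials, isi = isi, continuity = continuity,
                         stimulation = cond, input = input)
    res <- run_session(subject, sess, config = config, block = b,
                       network = network, return_traces = FALSE)
    out[[b]] <- res$records
  }
  do.call(rbind, out)
}

#' Per-subject, per-condition behavioral summary
#'
#' Applies the standard pipeline to each subject x condition cell of a trial
#' table: outlier filtering, Weibull accuracy threshold, indecision-point
#' shift and the sequential logistic hysteresis fit.
#'
#' @param records trial records (several subjects/conditions).
#' @param target accuracy-threshold target.
#' @return Data frame with one row per subject x condition.
#' @export
summarize_subjects <- function(records, target = 0.8) {
  records <- filter_trials(records)
  cells <- unique(records[, c("subject_id", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    rec <- records[records$subject_id == cells$subject_id[i] &
                     records$condition == cells$condition[i], ]
    val <- rec[rec$valid, ]
    acc <- aggregate(correct ~ coherence, data = transform(
      val, coherence = abs(coherence_signed)), FUN = mean)
    names(acc)[2] <- "p_correct"
    acc$n <- aggregate(correct ~ coherence, data = transform(
      val, coherence = abs(coherence_signed)), FUN = length)$correct
    wb <- tryCatch(weibull_accuracy_threshold(acc, target),
                   error = function(e) list(accuracy_threshold = NA_real_,
                                            converged = FALSE))
    ip <- tryCatch(indecision_points(rec), error = function(e) list(shift = NA_real_))
    hy <- tryCatch(hysteresis_logistic(rec),
                   error = function(e) list(a0 = NA_real_, a1 = NA_real_,
                                            a2 = NA_real_, ratio = NA_real_))
    data.frame(subject_id = cells$subject_id[i], condition = cells$condition[i],
               n_valid = sum(rec$valid), n_trials = nrow(rec),
               accuracy_threshold = wb$accuracy_threshold,
               threshold_converged = isTRUE(wb$converged),
               shift = ip$shift, a0 = hy$a0, a1 = hy$a1, a2 = hy$a2,
               ratio = hy$ratio)
  })
  do.call(rbind, rows)
}

# per-subject, per-coherence mean decision times for one condition
dt_cell_means <- function(records, condition) {
  rec <- records[records$condition == condition & records$valid, ]
  out <- aggregate(decision_time_s ~ subject_id + coherence,
                   data = transform(rec, coherence = abs(coherence_signed)),
                   FUN = mean)
  names(out)[3] <- "dt_mean"
  out
}

paired_by_subject <- function(summary, cond, baseline, column) {
  a <- summary[summary$condition == cond, ]
  b <- summary[summary$condition == baseline, ]
  shared <- intersect(a$subject_id, b$subject_id)
  list(x = a[[column]][match(shared, a$subject_id)],
       y = b[[column]][match(shared, b$subject_id)])
}

#' Run the stimulation experiment
#'
#' For every virtual subject, one block per stimulation condition with
#' identical wiring (within-subject design), followed by the full behavioral
#' comparison: paired tests of accuracy threshold, indecision-point shift
#' and hysteresis ratio against the no-stimulation baseline, and the
#' decision-time difference regressions on coherence.
#'
#' @param config an [experiment_config()].
#' @return List with `records`, `summary` (subject x condition),
#'   `dt_regressions` and `tests`; files are written when
#'   `config$output_dir` is set.
#' @export
run_stimulation_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  input <- input_spec(total_rate = config$total_rate,
                      refresh_hz = config$refresh_hz)
  records <- list()
  for (s in seq_len(config$n_subjects)) {
    subject <- seeded_subject(config$master_seed, "stim", s, config$architecture)
    records[[s]] <- run_subject_conditions(
      subject, config$conditions, isi = 2, continuity = config$continuity,
      coherences = config$coherences,
      reps_per_direction = config$reps_per_direction, input = input)
  }
  records <- do.call(rbind, records)
  records <- filter_trials(records)
  summary <- summarize_subjects(records)

  baseline <- if ("none" %in% config$conditions) "none" else config$conditions[1]
  stim_conds <- setdiff(config$conditions, baseline)
  tests <- list()
  dt_regressions <- list()
  for (cond in stim_conds) {
    for (col in c("accuracy_threshold", "shift", "ratio")) {
      pair <- paired_by_subject(summary, cond, baseline, col)
      keep <- complete.cases(pair$x, pair$y)
      tests[[paste(cond, col, sep = ".")]] <- tryCatch(
        wilcoxon_signed_rank(pair$x[keep], pair$y[keep]),
        error = function(e) list(error = conditionMessage(e)))
    }
    dt_regressions[[cond]] <- tryCatch(
      dt_difference_regression(dt_cell_means(records, cond),
                               dt_cell_means(records, baseline)),
      error = function(e) list(error = conditionMessage(e)))
  }
  out <- list(records = records, summary = summary,
              dt_regressions = dt_regressions, tests = tests,
              config = config)
  maybe_write_outputs(out, config, "stimulation")
  out
}

#' Run the inter-stimulus-interval experiment
#'
#' Independent subject groups per ISI level (a between-group design), no
#' stimulation, continuous sessions; hysteresis measures per subject and a
#' one-way ANOVA across ISI levels.
#'
#' @param config an [experiment_config()] with at least 2 `isi_levels`.
#' @return List with `records`, `summary` (including `isi`), and `tests`
#'   (`anova_ratio`, `anova_shift`).
#' @export
run_isi_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$isi_levels) < 2) stop("need at least 2 ISI levels", call. = FALSE)
  input <- input_spec(total_rate = config$total_rate,
                      refresh_hz = config$refresh_hz)
  records <- list()
  summary <- list()
  for (g in seq_along(config$isi_levels)) {
    isi <- config$isi_levels[g]
    for (s in seq_len(config$n_subjects)) {
      subject <- seeded_subject(config$master_seed, paste0("isi", isi), s,
                                config$architecture)
      subject$subject_id <- as.integer((g - 1) * config$n_subjects + s)
      rec <- run_subject_conditions(
        subject, "none", isi = isi, continuity = config$continuity,
        coherences = config$coherences,
        reps_per_direction = config$reps_per_direction, input = input)
      records[[length(records) + 1]] <- transform(rec, isi = isi)
    }
  }
  records <- do.call(rbind, records)
  summary <- summarize_subjects(records)
  summary$isi <- records$isi[match(summary$subject_id, records$subject_id)]

  groups_ratio <- split(summary$ratio, summary$isi)
  groups_shift <- split(summary$shift, summary$isi)
  drop_na <- function(g) lapply(g, function(x) x[is.finite(x)])
  tests <- list(
    anova_ratio = tryCatch(anova_oneway(drop_na(groups_ratio)),
                           error = function(e) list(error = conditionMessage(e))),
    anova_shift = tryCatch(anova_oneway(drop_na(groups_shift)),
                           error = function(e) list(error = conditionMessage(e)))
  )
  out <- list(records = records, summary = summary, tests = tests,
              config = config)
  maybe_write_outputs(out, config, "isi")
  out
}

#' Run the falsification-control variants
#'
#' Re-runs the stimulation experiment under the control variants: changed
#' total input rate or refresh rate, stimulation restricted to one cell
#' class or applied uniformly, reinitialized sessions, and the accumulator
#' architecture. Each variant emits the same metric set as
#' [run_stimulation_experiment()] so the sign pattern across variants can be
#' compared.
#'
#' @param config an [experiment_config()]; its scale fields set the per-variant
#'   size.
#' @param variants character vector choosing which variants to run.
#' @return Named list of [run_stimulation_experiment()] results.
#' @export
run_control_experiments <- function(config,
                                    variants = c("input60", "refresh30",
                                                 "refresh120", "pyramidal_only",
                                                 "interneuron_only", "uniform",
                                                 "reinitialization", "accumulator")) {
  stopifnot(inherits(config, "experiment_config"))
  if (!length(variants)) stop("variant list must be non-empty", call. = FALSE)
  out <- list()
  for (v in variants) {
    vc <- config
    vc$output_dir <- if (is.null(config$output_dir)) NULL else
      file.path(config$output_dir, v)
    vc$master_seed <- derive_seed(config$master_seed, "variant", v)
    switch(v,
      input60 = { vc$total_rate <- 60 },
      refresh30 = { vc$refresh_hz <- 30 },
      refresh120 = { vc$refresh_hz <- 120 },
      pyramidal_only = {
        vc$conditions <- c("none", "pyramidal_only_depol", "pyramidal_only_hyper")
      },
      interneuron_only = {
        vc$conditions <- c("none", "interneuron_only_depol", "interneuron_only_hyper")
      },
      uniform = { vc$conditions <- c("none", "uniform_depol", "uniform_hyper") },
      reinitialization = { vc$continuity <- "reinitialized" },
      accumulator = { vc$architecture <- "accumulator" },
      stop("unknown control variant: ", v, call. = FALSE)
    )
    out[[v]] <- run_stimulation_experiment(vc)
  }
  out
}

# serialize test results (lists of attractor_test) to plain lists
tests_to_plain <- function(tests) {
  lapply(tests, function(t) {
    if (inherits(t, "attractor_test"))
      list(test = t$test_name, statistic = t$statistic,
           df = t$df, p_value = t$p_value, n = t$n)
    else if (is.list(t) && !is.null(t$beta1))
      list(test = "dt_difference_regression", beta0 = t$beta0,
           beta1 = t$beta1, p_slope = t$p_slope)
    else t
  })
}

maybe_write_outputs <- function(result, config, label) {
  dir <- config$output_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network_config(network_preset(
    if (config$architecture == "attractor") "competitive" else "accumulator"),
    file.path(dir, "network_config.yaml"))
  yaml::write_yaml(unclass(config)[setdiff(names(unclass(config)), "output_dir")],
                   file.path(dir, "experiment_config.yaml"))
  write_trial_records(result$records, file.path(dir, paste0(label, "_trials.csv")))
  write.csv(result$summary, file.path(dir, paste0(label, "_summary.csv")),
            row.names = FALSE)
  tests <- c(tests_to_plain(result$tests),
             if (!is.null(result$dt_regressions))
               tests_to_plain(result$dt_regressions))
  jsonlite::write_json(tests, file.path(dir, paste0(label, "_tests.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_lines <- c(
    paste("experiment:", label),
    paste("timestamp:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("master_seed:", config$master_seed),
    paste("n_subjects:", config$n_subjects),
    paste("records:", nrow(result$records)))
  writeLines(log_lines, file.path(dir, paste0(label, "_log.txt")))
  seeds <- data.frame(subject_id = unique(result$records$subject_id),
                      master_seed = config$master_seed)
  write.csv(seeds, file.path(dir, "seed_manifest.csv"), row.names = FALSE)
  invisible(dir)
}
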
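#' Map motion coherence to the two task-input rates
#'
#' The two mean task-related input rates vary linearly with coherence and
#' always sum to `total_rate`, so the overall input drive is identical across
#' difficulty levels: `mu_high = total_rate/2 (1 + c)`,
#' `mu_low = total_rate/2 (1 - c)`.
#'
#' @param c motion coherence as a proportion in \[0, 1\]; vectorized.
#' @param total_rate sum of the two mean input rates (Hz).
#' @return A list with components `mu_high` and `mu_low` (Hz).
#' @examples
#' coherence_to_rates(0.512)  # 60.48 and 19.52 Hz
#' coherence_to_rates(0)      # both 40 Hz
#' @export
coherence_to_rates <- function(c, total_rate = 80) {
  if (any(c < 0 | c > 1)) stop("coherence must lie in [0, 1]", call. = FALSE)
  if (total_rate <= 0) stop("total_rate must be positive", call. = FALSE)
  list(mu_high = total_rate / 2 * (1 + c), mu_low = total_rate / 2 * (1 - c))
}

#' Task-input specification
#'
#' @param total_rate sum of the two mean task-input rates (Hz).
#' @param sigma standard deviation of the per-refresh rate jitter (Hz).
#' @param refresh_hz monitor refresh rate at which the momentary input rate
#'   is resampled (Hz).
#' @param background_fan_in number of independent background-pool spike
#'   trains converging on each pyramidal cell and interneuron
#'   (`c(pyramidal, interneuron)`); the delivered per-neuron rate is the
#'   subject's background rate times the fan-in. `NULL` (default) resolves
#'   to the architecture-specific calibration: `c(1.3, 1.1)` for the
#'   attractor and `c(1.2, 1.1)` for the accumulator, whose recurrent pools
#'   sit close to a self-sustaining transition and need less drive.
#' @param task_fan_in number of task-input-pool trains converging on each
#'   selective neuron; the delivered per-neuron rate is the momentary pool
#'   rate times the fan-in.
#'
#' @details The pool rates (the 80 Hz task total and the subject's
#' background rate) describe the input channels; each neuron samples the
#' pool through several independent generators. The fan-in defaults are
#' fixed package constants that place the circuit in its documented
#' operating regime (few to 15 Hz prestimulus selective-pool rates, winners
#' crossing 18-22 Hz response thresholds, losers suppressed).
#' @return An object of class `input_spec`.
#' @export
input_spec <- function(total_rate = 80, sigma = 4, refresh_hz = 60,
                       background_fan_in = NULL,
                       task_fan_in = 2) {
  if (total_rate <= 0) stop("total_rate must be positive", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (refresh_hz <= 0) stop("refresh_hz must be positive", call. = FALSE)
  if (!is.null(background_fan_in) && any(background_fan_in <= 0))
    stop("fan-in factors must be positive", call. = FALSE)
  if (task_fan_in <= 0) stop("fan-in factors must be positive", call. = FALSE)
  structure(list(total_rate = total_rate, sigma = sigma,
                 refresh_hz = refresh_hz,
                 background_fan_in = if (is.null(background_fan_in)) NULL else
                   rep_len(as.numeric(background_fan_in), 2),
                 task_fan_in = task_fan_in),
            class = c("input_spec", "list"))
}

# architecture-specific background fan-in calibrations
background_fan_for <- function(input, architecture) {
  if (!is.null(input$background_fan_in)) return(input$background_fan_in)
  if (architecture == "attractor") c(1.3, 1.1) else c(1.2, 1.1)
}

#' Sample a piecewise-constant input-rate trace
#'
#' One normal draw `N(mu, sigma^2)` per refresh frame, truncated at zero and
#' held constant within the frame, emulating frame-by-frame variation of the
#' momentary motion evidence.
#'
#' @param mu mean rate (Hz).
#' @param sigma per-frame jitter SD (Hz).
#' @param refresh_hz frame rate (Hz).
#' @param duration trace duration (s).
#' @return An object of class `rate_trace_frames`: numeric frame rates (Hz)
#'   with attributes `frame_ms` and `refresh_hz`.
#' @export
sample_rate_trace <- function(mu, sigma, refresh_hz, duration) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  n <- ceiling(duration * refresh_hz)
  rates <- pmax(0, rnorm(n, mean = mu, sd = sigma))
  structure(rates, frame_ms = 1000 / refresh_hz, refresh_hz = refresh_hz,
            class = "rate_trace_frames")
}

# Expand frame rates to one value per integration step. Frame length is
# quantized to whole steps (e.g. 60 Hz -> 33 steps of 0.5 ms).
expand_frames <- function(frames, dt, n_steps) {
  steps_per_frame <- max(1L, as.integer(round(attr(frames, "frame_ms") / dt)))
  out <- rep(as.numeric(frames), each = steps_per_frame)
  length(out) <- n_steps  # pad with NA then zero-fill
  out[is.na(out)] <- if (length(frames)) as.numeric(frames[length(frames)]) else 0
  out
}

#' Build a balanced, randomized trial list
#'
#' The full crossing of coherence levels and the two motion directions,
#' `reps_per_direction` trials per cell, in uniformly random order (uses R's
#' RNG; seed with [set.seed()] for reproducibility).
#'
#' @param coherences coherence levels (proportions).
#' @param reps_per_direction trials per coherence x direction cell.
#' @return Data frame with columns `coherence` and `direction`
#'   (`"left"`/`"right"`).
#' @examples
#' set.seed(1)
#' trials <- make_trial_list()
#' nrow(trials)  # 5 coherences x 2 directions x 10 reps = 100
#' @export
make_trial_list <- function(coherences = c(0.032, 0.064, 0.128, 0.256, 0.512),
                            reps_per_direction = 10) {
  if (!length(coherences)) stop("coherence list must be non-empty", call. = FALSE)
  if (reps_per_direction < 1) stop("reps_per_direction must be >= 1", call. = FALSE)
  grid <- expand.grid(coherence = coherences, direction = c("left", "right"),
                      rep = seq_len(reps_per_direction),
                      stringsAsFactors = FALSE)
  grid <- grid[sample.int(nrow(grid)), c("coherence", "direction")]
  rownames(grid) <- NULL
  grid
}

#' Sample a virtual subject
#'
#' A virtual subject is one model instantiation standing in for
#' between-participant variability: a background input rate, a response
#' threshold, and seeds fixing its wiring and its session-level stochastic
#' inputs. The attractor architecture samples the background rate uniformly
#' in \[880, 950\] Hz and the response threshold independently in
#' \[18, 22\] Hz. The accumulator architecture (more sensitive to background
#' drive) samples the background rate in \[855, 870\] Hz and maps it
#' affinely onto a threshold in \[19, 36\] Hz (855 -> 19, 870 -> 36).
#'
#' Uses R's RNG; seed with [set.seed()] for reproducibility.
#'
#' @param subject_id integer identifier.
#' @param architecture `"attractor"` or `"accumulator"`.
#' @return An object of class `virtual_subject`.
#' @export
sample_virtual_subject <- function(subject_id,
                                   architecture = c("attractor", "accumulator")) {
  architecture <- match.arg(architecture)
  if (architecture == "attractor") {
    bg <- runif(1, 880, 950)
    thr <- runif(1, 18, 22)
  } else {
    bg <- runif(1, 855, 870)
    thr <- 19 + (bg - 855) / (870 - 855) * (36 - 19)
  }
  structure(list(subject_id = as.integer(subject_id),
                 architecture = architecture,
                 background_rate = bg,
                 response_threshold = thr,
                 wiring_seed = sample.int(.Machine$integer.max, 1),
                 session_seed = sample.int(.Machine$integer.max, 1)),
            class = c("virtual_subject", "list"))
}

#' Stimulation conditions as injected current pairs
#'
#' Polarizing stimulation is modeled as a constant transmembrane current
#' injected into every neuron for the whole session. Positive values
#' depolarize. Depolarizing stimulation injects +0.75 pA into pyramidal
#' cells and -0.375 pA into interneurons (the sign difference reflecting
#' cellular orientation and morphology under an external field);
#' hyperpolarizing stimulation reverses both signs. The `_only` variants
#' zero the other population's current and the `uniform` variants apply the
#' pyramidal current with the same sign to both classes (a falsification
#' control that contradicts the known physiology).
#'
#' @param name condition name.
#' @return An object of class `stimulation_currents` with fields `name`,
#'   `I_pyr` and `I_int` (pA, injected convention).
#' @examples
#' stimulation_currents("depolarizing")
#' @export
stimulation_currents <- function(name = c("none", "depolarizing", "hyperpolarizing",
                                          "pyramidal_only_depol", "pyramidal_only_hyper",
                                          "interneuron_only_depol", "interneuron_only_hyper",
                                          "uniform_depol", "uniform_hyper")) {
  name <- match.arg(name)
  currents <- switch(name,
    none = c(0, 0),
    depolarizing = c(0.75, -0.375),
    hyperpolarizing = c(-0.75, 0.375),
    pyramidal_only_depol = c(0.75, 0),
    pyramidal_only_hyper = c(-0.75, 0),
    interneuron_only_depol = c(0, -0.375),
    interneuron_only_hyper = c(0, 0.375),
    uniform_depol = c(0.75, 0.75),
    uniform_hyper = c(-0.75, -0.75)
  )
  structure(list(name = name, I_pyr = currents[1], I_int = currents[2]),
            class = c("stimulation_currents", "list"))
}

#' Session specification
#'
#' Trial list, timing and condition labels for one simulated block. Trials
#' are laid out as 1 s of pre-input time, 1 s of task input, and
#' `isi - 1` s of post-input time, so the inter-stimulus interval (input
#' offset to next input onset) equals `isi` exactly.
#'
#' @param trials data frame from [make_trial_list()].
#' @param isi inter-stimulus interval (s), at least 1.
#' @param continuity `"continuous"` carries the full network state across
#'   trials; `"reinitialized"` resets it at every trial start.
#' @param stimulation a condition name or [stimulation_currents()] object.
#' @param input an [input_spec()].
#' @param input_duration task-input duration (s).
#' @param pre_input pre-input time per trial (s); the 500 ms prestimulus
#'   analysis window must fit inside it.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(trials, isi = 2,
                         continuity = c("continuous", "reinitialized"),
                         stimulation = "none",
                         input = input_spec(),
                         input_duration = 1, pre_input = 1) {
  continuity <- match.arg(continuity)
  if (is.character(stimulation)) stimulation <- stimulation_currents(stimulation)
  stopifnot(inherits(stimulation, "stimulation_currents"),
            inherits(input, "input_spec"))
  if (isi < pre_input)
    stop("isi must be at least the pre-input time (", pre_input, " s)", call. = FALSE)
  if (pre_input < 0.5)
    stop("pre_input must cover the 500 ms prestimulus window", call. = FALSE)
  structure(list(trials = trials, isi = isi, continuity = continuity,
                 stimulation = stimulation, input = input,
                 input_duration = input_duration, pre_input = pre_input,
                 post_input = isi - pre_input,
                 trial_duration = pre_input + input_duration + (isi - pre_input)),
            class = c("session_spec", "list"))
}

# deterministic 31-bit seed derived from arbitrary labels
derive_seed <- function(...) {
  parts <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                        character(1)), collapse = "::")
  bytes <- utf8ToInt(parts)
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h + 1)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a full session of trials
#'
#' Runs the network through every trial of a session in order. In continuous
#' mode the complete network state (membrane potentials, conductances,
#' refractory clocks, pending spikes and the input RNG) carries across
#' trials, so decaying activity from one trial can bias the next; in
#' reinitialized mode the state is reset to baseline at each trial start.
#' Task inputs target only the two selective pools; background input drives
#' every neuron at the subject's background rate; stimulation currents are
#' applied at every step of the whole session.
#'
#' @param subject a [sample_virtual_subject()] result (or a list with the
#'   same fields).
#' @param session a [session_spec()].
#' @param config optional [network_config()]; defaults to the preset matching
#'   the subject's architecture, wired with the subject's `wiring_seed`.
#' @param block block label recorded in the trial records.
#' @param network optional pre-built [build_network()] result (must match
#'   `config`); avoids rewiring when the same subject runs several blocks.
#' @param return_traces keep the smoothed population rate traces.
#' @param init_state optional state to continue from.
#' @return An object of class `session_result`: `records` (one row per
#'   trial), `traces` (smoothed rates, Hz), `state`, and diagnostics.
#'   Record columns follow the package's trial-record dialect; see
#'   [write_trial_records()].
#' @export
run_session <- function(subject, session, config = NULL, block = 1L,
                        network = NULL, return_traces = TRUE,
                        init_state = NULL) {
  stopifnot(inherits(session, "session_spec"))
  if (is.null(config)) {
    config <- network_preset(
      if (subject$architecture == "attractor") "competitive" else "accumulator",
      wiring_seed = subject$wiring_seed)
  }
  if ((config$architecture == "attractor") != (subject$architecture == "attractor"))
    stop("subject and config architectures disagree", call. = FALSE)
  if (is.null(network)) network <- build_network(config)

  dt <- config$dt
  n_trials <- nrow(session$trials)
  steps_per_s <- round(1000 / dt)
  trial_steps <- round(session$trial_duration * steps_per_s)
  onset_step <- round(session$pre_input * steps_per_s)
  offset_step <- onset_step + round(session$input_duration * steps_per_s)
  n_steps <- trial_steps * max(n_trials, 0)

  cond_name <- session$stimulation$name
  session_seed <- derive_seed(subject$session_seed, block, cond_name)

  rate_l <- numeric(n_steps)
  rate_r <- numeric(n_steps)
  if (n_trials > 0) {
    with_local_seed(session_seed, {
      for (k in seq_len(n_trials)) {
        co <- session$trials$coherence[k]
        dir <- session$trials$direction[k]
        mus <- coherence_to_rates(co, session$input$total_rate)
        mu_l <- if (dir == "left") mus$mu_high else mus$mu_low
        mu_r <- if (dir == "right") mus$mu_high else mus$mu_low
        fr_l <- sample_rate_trace(mu_l, session$input$sigma,
                                  session$input$refresh_hz, session$input_duration)
        fr_r <- sample_rate_trace(mu_r, session$input$sigma,
                                  session$input$refresh_hz, session$input_duration)
        idx <- ((k - 1) * trial_steps + onset_step + 1):((k - 1) * trial_steps + offset_step)
        rate_l[idx] <- expand_frames(fr_l, dt, length(idx)) * session$input$task_fan_in
        rate_r[idx] <- expand_frames(fr_r, dt, length(idx)) * session$input$task_fan_in
      }
    })
  }

  sim <- simulate_network(
    network, n_steps = n_steps,
    background_rate = subject$background_rate *
      background_fan_for(session$input, subject$architecture),
    task_rate_left = rate_l, task_rate_right = rate_r,
    stim = session$stimulation,
    trial_start_steps = (seq_len(n_trials) - 1L) * trial_steps,
    reinitialize = session$continuity == "reinitialized",
    seed = session_seed,
    init_state = init_state
  )

  n_sel <- config$n_selective
  if (n_steps > 0) {
    tr_left <- smooth_rate(sim$counts[, 1] / (n_sel * dt / 1000), dt)
    tr_right <- smooth_rate(sim$counts[, 2] / (n_sel * dt / 1000), dt)
  } else {
    tr_left <- tr_right <- numeric(0)
  }

  records <- vector("list", n_trials)
  prev_choice <- "none"
  for (k in seq_len(n_trials)) {
    i0 <- (k - 1) * trial_steps
    seg <- (i0 + 1):(i0 + trial_steps)
    dec <- detect_decision(
      trace_left = tr_left[seg], trace_right = tr_right[seg],
      times = (seq_len(trial_steps) - 0.5) * dt / 1000,
      threshold = subject$response_threshold,
      window = c(session$pre_input, session$trial_duration),
      tie_seed = derive_seed(session_seed, "tie", k)
    )
    pre_idx <- (i0 + onset_step - round(0.5 * steps_per_s) + 1):(i0 + onset_step)
    pre_l <- mean(tr_left[pre_idx])
    pre_r <- mean(tr_right[pre_idx])
    chosen_rate <- switch(dec$choice, left = pre_l, right = pre_r, none = NA_real_)
    unchosen_rate <- switch(dec$choice, left = pre_r, right = pre_l, none = NA_real_)
    co <- session$trials$coherence[k]
    dir <- session$trials$direction[k]
    records[[k]] <- data.frame(
      subject_id = subject$subject_id,
      block = block,
      condition = cond_name,
      trial_index = k,
      coherence_signed = if (dir == "left") -co else co,
      direction = dir,
      choice = dec$choice,
      responded = as.integer(dec$choice != "none"),
      decision_time_s = dec$time,  # already measured from input onset
      prestim_rate_chosen_hz = chosen_rate,
      prestim_rate_unchosen_hz = unchosen_rate,
      previous_choice = prev_choice,
      stringsAsFactors = FALSE
    )
    prev_choice <- dec$choice
  }
  records <- if (n_trials) do.call(rbind, records) else empty_trial_records()
  records$correct <- with(records, ifelse(
    choice == "none" | coherence_signed == 0, NA,
    (coherence_signed > 0 & choice == "right") |
      (coherence_signed < 0 & choice == "left")))

  out <- list(
    records = records,
    traces = if (return_traces)
      list(time_ms = (seq_len(n_steps) - 0.5) * dt,
           left = tr_left, right = tr_right) else NULL,
    state = sim$state,
    onset_step = onset_step,
    trial_steps = trial_steps,
    dt = dt,
    task_events_selective = sim$task_events_selective,
    task_events_other = sim$task_events_other,
    session_seed = session_seed,
    threshold = subject$response_threshold
  )
  class(out) <- c("session_result", "list")
  out
}

empty_trial_records <- function() {
  data.frame(subject_id = integer(0), block = integer(0),
             condition = character(0), trial_index = integer(0),
             coherence_signed = numeric(0), direction = character(0),
             choice = character(0), responded = integer(0),
             decision_time_s = numeric(0),
             prestim_rate_chosen_hz = numeric(0),
             prestim_rate_unchosen_hz = numeric(0),
             previous_choice = character(0), stringsAsFactors = FALSE)
}
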
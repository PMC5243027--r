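#' Build the probabilistically wired network
#'
#' Draws every connection as an independent Bernoulli trial at the
#' probabilities in the configuration's [connectivity_spec()]. The attractor
#' architecture wires both selective pools to the common interneuron pool and
#' back; the accumulator architecture wires each interneuron half exclusively
#' to the matching selective pool, so no inhibition crosses between the two
#' decision channels. Identical `wiring_seed` gives identical wiring.
#'
#' @param config a [network_config()].
#' @param wiring_seed optional integer overriding `config$wiring_seed`.
#' @return An object of class `attractor_network`: the configuration plus a
#'   compressed adjacency (`offsets`, 0-based `targets`) over the combined
#'   index space (pyramidal cells first, then interneurons).
#' @examples
#' \donttest{
#' net <- build_network(network_preset("competitive", wiring_seed = 7))
#' net$n_edges
#' }
#' @export
build_network <- function(config, wiring_seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  seed <- if (is.null(wiring_seed)) config$wiring_seed else as.integer(wiring_seed)
  wiring <- cpp_wire_network(
    n_pyr = config$n_pyramidal, n_sel = config$n_selective,
    n_int = config$n_interneurons,
    architecture = if (config$architecture == "attractor") 0L else 1L,
    p_pyr_recurrent = config$connectivity$p_pyr_recurrent,
    p_int_recurrent = config$connectivity$p_int_recurrent,
    p_pyr_to_int = config$connectivity$p_pyr_to_int,
    p_int_to_pyr = config$connectivity$p_int_to_pyr,
    seed = seed
  )
  structure(list(config = config,
                 wiring_seed = seed,
                 offsets = wiring$offsets,
                 targets = wiring$targets,
                 n_pyr = wiring$n_pyr,
                 n_sel = wiring$n_sel,
                 n_int = wiring$n_int,
                 n_edges = length(wiring$targets)),
            class = c("attractor_network", "list"))
}

#' @export
print.attractor_network <- function(x, ...) {
  cat("<attractor_network>", x$config$architecture, "architecture,",
      x$n_pyr + x$n_int, "neurons,", x$n_edges, "connections\n")
  invisible(x)
}

#' Outgoing targets of one neuron
#'
#' @param network an `attractor_network`.
#' @param neuron 1-based neuron index (pyramidal cells first).
#' @return Integer vector of 1-based postsynaptic indices.
#' @export
network_targets <- function(network, neuron) {
  stopifnot(inherits(network, "attractor_network"))
  i <- as.integer(neuron)
  if (i < 1 || i > x_total(network)) stop("neuron index out of range", call. = FALSE)
  network$targets[(network$offsets[i] + 1):network$offsets[i + 1]] + 1L
}

x_total <- function(network) network$n_pyr + network$n_int

#' Count connections between cell groups
#'
#' Convenience for wiring diagnostics: number of edges from `from` indices to
#' `to` indices (1-based, combined index space).
#'
#' @param network an `attractor_network`.
#' @param from,to integer vectors of 1-based neuron indices.
#' @return Edge count.
#' @export
connection_count <- function(network, from, to) {
  stopifnot(inherits(network, "attractor_network"))
  to <- as.integer(to)
  keep <- logical(x_total(network))
  keep[to] <- TRUE
  total <- 0L
  for (i in as.integer(from)) {
    lo <- network$offsets[i] + 1L
    hi <- network$offsets[i + 1]
    if (hi >= lo) total <- total + sum(keep[network$targets[lo:hi] + 1L])
  }
  total
}

#' Population index helpers
#'
#' 1-based index ranges of the four populations of a network: the two
#' selective pyramidal pools, the non-selective pyramidal pool and the
#' interneurons.
#'
#' @param network an `attractor_network` (or a [network_config()]).
#' @return Named list of integer vectors `left`, `right`, `nonselective`,
#'   `interneurons`.
#' @export
population_indices <- function(network) {
  cfg <- if (inherits(network, "attractor_network")) network$config else network
  n_sel <- cfg$n_selective; n_pyr <- cfg$n_pyramidal; n_int <- cfg$n_interneurons
  list(
    left = seq_len(n_sel),
    right = seq_len(n_sel) + n_sel,
    nonselective = if (n_pyr > 2 * n_sel) (2 * n_sel + 1):n_pyr else integer(0),
    interneurons = if (n_int > 0) (n_pyr + 1):(n_pyr + n_int) else integer(0)
  )
}

# Flatten config into the parameter list the C++ core consumes.
sim_params <- function(config) {
  syn <- config$synapses
  p <- config$pyramidal; i <- config$interneuron
  nmda <- synapse_row(syn, "NMDA", "pyramidal")
  list(
    C = c(p$C, i$C), g_L = c(p$g_L, i$g_L), E_L = c(p$E_L, i$E_L),
    Delta_T = c(p$Delta_T, i$Delta_T), V_T = c(p$V_T, i$V_T),
    V_s = c(p$V_s, i$V_s), V_r = c(p$V_r, i$V_r),
    ref_steps = as.integer(round(c(p$tau_r, i$tau_r) / config$dt)),
    G_ext = c(synapse_row(syn, "AMPA_ext", "pyramidal")$G,
              synapse_row(syn, "AMPA_ext", "interneuron")$G),
    G_bg = c(synapse_row(syn, "AMPA_background", "pyramidal")$G,
             synapse_row(syn, "AMPA_background", "interneuron")$G),
    G_rec = c(synapse_row(syn, "AMPA_recurrent", "pyramidal")$G,
              synapse_row(syn, "AMPA_recurrent", "interneuron")$G),
    G_nmda = c(nmda$G, synapse_row(syn, "NMDA", "interneuron")$G),
    G_gaba = c(synapse_row(syn, "GABA_A", "pyramidal")$G,
               synapse_row(syn, "GABA_A", "interneuron")$G),
    tau_ampa = synapse_row(syn, "AMPA_ext", "pyramidal")$tau,
    tau_gaba = synapse_row(syn, "GABA_A", "pyramidal")$tau,
    tau_nmda_rise = nmda$tau_1, tau_nmda_decay = nmda$tau_2,
    Mg = nmda$Mg,
    E_gaba = synapse_row(syn, "GABA_A", "pyramidal")$E,
    dt = config$dt,
    w_plus = config$connectivity$w_plus,
    delay_steps = as.integer(round(config$connectivity$delay / config$dt)),
    saturating = if (config$synapse_update == "saturating") 1L else 0L
  )
}

#' Low-level network simulation
#'
#' Advances the network by forward Euler for a given number of steps.
#' [run_session()] builds on this; exposing it directly supports single-step
#' contracts, continuity checks and isolated-neuron integrations.
#'
#' @param network an `attractor_network` from [build_network()].
#' @param n_steps number of integration steps of length `config$dt`.
#' @param background_rate per-neuron background Poisson rate (Hz); scalar or
#'   `c(pyramidal, interneuron)`.
#' @param task_rate_left,task_rate_right per-step task input rate (Hz) for
#'   the two selective pools; scalars are recycled to `n_steps`.
#' @param stim a [stimulation_currents()] pair (injected convention,
#'   positive = depolarizing) or numeric `c(I_pyr, I_int)` in pA.
#' @param trial_start_steps 0-based step indices at which trials start (used
#'   only when `reinitialize = TRUE`).
#' @param reinitialize reset membrane and conductance state at trial starts.
#' @param seed integer seed for the simulation's Poisson inputs.
#' @param init_state a state list returned by a previous call, to continue
#'   the exact trajectory (the pending-spike queue and the input RNG resume).
#' @param return_spikes also return per-spike neuron ids and times.
#' @param ext_events optional data frame with columns `neuron` (1-based) and
#'   `step` (0-based) of externally scheduled input spikes delivered to the
#'   AMPA_ext synapse state; a deterministic test hook.
#' @return List with `counts` (steps x 4 spike counts: left, right,
#'   non-selective, interneurons), `state`, diagnostics, and optionally the
#'   spike list.
#' @export
simulate_network <- function(network, n_steps,
                             background_rate = 0,
                             task_rate_left = 0, task_rate_right = 0,
                             stim = c(0, 0),
                             trial_start_steps = integer(0),
                             reinitialize = FALSE,
                             seed = 1L,
                             init_state = NULL,
                             return_spikes = FALSE,
                             ext_events = NULL) {
  stopifnot(inherits(network, "attractor_network"))
  n_steps <- as.integer(n_steps)
  if (length(task_rate_left) == 1) task_rate_left <- rep(task_rate_left, n_steps)
  if (length(task_rate_right) == 1) task_rate_right <- rep(task_rate_right, n_steps)
  if (length(task_rate_left) != n_steps || length(task_rate_right) != n_steps)
    stop("task rate vectors must have length n_steps", call. = FALSE)
  stim <- as_stim_pair(stim)
  ev_n <- ev_s <- NULL
  if (!is.null(ext_events)) {
    ord <- order(ext_events$step)
    ev_n <- as.integer(ext_events$neuron[ord]) - 1L
    ev_s <- as.integer(ext_events$step[ord])
  }
  cpp_simulate_session(
    net = list(offsets = network$offsets, targets = network$targets,
               n_pyr = network$n_pyr, n_sel = network$n_sel,
               n_int = network$n_int,
               architecture = if (network$config$architecture == "attractor") 0L else 1L),
    params = sim_params(network$config),
    background_rate = as.numeric(rep_len(background_rate, 2)),
    task_rate_left = as.numeric(task_rate_left),
    task_rate_right = as.numeric(task_rate_right),
    I_stim_pyr = stim[1], I_stim_int = stim[2],
    trial_start_steps = as.integer(trial_start_steps),
    reinitialize = reinitialize,
    seed = as.integer(seed),
    init_state = init_state,
    return_spikes = return_spikes,
    ext_event_neuron = ev_n,
    ext_event_step = ev_s
  )
}

as_stim_pair <- function(stim) {
  if (inherits(stim, "stimulation_currents")) c(stim$I_pyr, stim$I_int)
  else if (is.numeric(stim) && length(stim) == 2) as.numeric(stim)
  else stop("stim must be stimulation_currents or a numeric pair", call. = FALSE)
}
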
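#' Neuron parameter presets
#'
#' Biophysical constants of the conductance-based exponential
#' integrate-and-fire neuron, in the units used throughout the package
#' (nF, nS, mV, ms). Two presets are shipped, one per cell class of the
#' competitive attractor circuit.
#'
#' @param class `"pyramidal"` or `"interneuron"`, or omit and supply every
#'   field explicitly.
#' @param C membrane capacitance (nF).
#' @param g_L leak conductance (nS).
#' @param E_L resting potential (mV).
#' @param Delta_T slope factor controlling spike-initiation sharpness (mV).
#' @param V_T threshold voltage of the exponential term (mV).
#' @param V_s spike-detection threshold (mV).
#' @param V_r post-spike reset potential (mV).
#' @param tau_r absolute refractory period (ms).
#'
#' @return An object of class `neuron_params` (a named list).
#' @examples
#' neuron_params("pyramidal")
#' @export
neuron_params <- function(class = c("pyramidal", "interneuron"),
                          C = NULL, g_L = NULL, E_L = -70, Delta_T = 3,
                          V_T = -55, V_s = -20, V_r = -53, tau_r = NULL) {
  class <- match.arg(class)
  defaults <- switch(class,
    pyramidal   = list(C = 0.5, g_L = 25, tau_r = 2),
    interneuron = list(C = 0.2, g_L = 20, tau_r = 1)
  )
  p <- list(
    class = class,
    C = if (is.null(C)) defaults$C else C,
    g_L = if (is.null(g_L)) defaults$g_L else g_L,
    E_L = E_L, Delta_T = Delta_T, V_T = V_T, V_s = V_s, V_r = V_r,
    tau_r = if (is.null(tau_r)) defaults$tau_r else tau_r
  )
  if (p$C <= 0) stop("membrane capacitance C must be positive", call. = FALSE)
  if (p$g_L <= 0) stop("leak conductance g_L must be positive", call. = FALSE)
  if (p$Delta_T <= 0) stop("slope factor Delta_T must be positive", call. = FALSE)
  if (p$V_r >= p$V_s) stop("reset V_r must lie below spike threshold V_s", call. = FALSE)
  if (p$tau_r < 0) stop("refractory period tau_r must be non-negative", call. = FALSE)
  structure(p, class = c("neuron_params", "list"))
}

#' Synapse parameter table
#'
#' Maximal conductances, kinetics and reversal potentials for the five
#' synapse kinds of the circuit. Conductances are target-class specific:
#' pyramidal cells and interneurons express different weights for the same
#' presynaptic kind.
#'
#' @return A data frame with one row per (kind, target class) combination and
#'   columns `kind`, `target`, `G` (nS), `tau` (ms; decay constant of
#'   mono-exponential kinds), `tau_1`, `tau_2` (ms; NMDA rise/decay),
#'   `E` (mV) and `Mg` (mM, NMDA only).
#' @examples
#' synapse_params()
#' @export
synapse_params <- function() {
  tab <- rbind(
    data.frame(kind = "AMPA_ext",        target = c("pyramidal", "interneuron"),
               G = c(1.6, 1.6),   tau = 2,  tau_1 = NA, tau_2 = NA,  E = 0,   Mg = NA),
    data.frame(kind = "AMPA_background", target = c("pyramidal", "interneuron"),
               G = c(2.1, 1.53),  tau = 2,  tau_1 = NA, tau_2 = NA,  E = 0,   Mg = NA),
    data.frame(kind = "AMPA_recurrent",  target = c("pyramidal", "interneuron"),
               G = c(0.05, 0.04), tau = 2,  tau_1 = NA, tau_2 = NA,  E = 0,   Mg = NA),
    data.frame(kind = "NMDA",            target = c("pyramidal", "interneuron"),
               G = c(0.145, 0.13), tau = NA, tau_1 = 2, tau_2 = 100, E = 0,   Mg = 1),
    data.frame(kind = "GABA_A",          target = c("pyramidal", "interneuron"),
               G = c(1.3, 1.0),   tau = 5,  tau_1 = NA, tau_2 = NA,  E = -70, Mg = NA)
  )
  rownames(tab) <- NULL
  validate_synapse_params(tab)
  tab
}

validate_synapse_params <- function(tab) {
  required <- c("kind", "target", "G", "tau", "tau_1", "tau_2", "E", "Mg")
  if (!all(required %in% names(tab)))
    stop("synapse table is missing columns: ",
         paste(setdiff(required, names(tab)), collapse = ", "), call. = FALSE)
  if (any(tab$G < 0)) stop("maximal conductances must be non-negative", call. = FALSE)
  nmda <- tab[tab$kind == "NMDA", ]
  if (nrow(nmda) && any(nmda$tau_1 >= nmda$tau_2))
    stop("NMDA rise constant tau_1 must be smaller than decay constant tau_2",
         call. = FALSE)
  mono <- tab[tab$kind != "NMDA", ]
  if (any(mono$tau <= 0)) stop("decay constants must be positive", call. = FALSE)
  invisible(tab)
}

#' Connection probabilities and conduction delay
#'
#' @param p_pyr_recurrent probability of a recurrent connection within a
#'   pyramidal population.
#' @param p_int_recurrent probability of a recurrent interneuron connection.
#' @param p_pyr_to_int probability of a pyramidal-to-interneuron connection.
#' @param p_int_to_pyr probability of an interneuron-to-pyramidal connection.
#' @param delay axonal conduction delay (ms); must be a multiple of the
#'   integration step.
#' @param w_plus Hebbian potentiation factor applied to recurrent synapses
#'   (AMPA and NMDA) between neurons of the same selective pool, the
#'   structured-weight feature of competitive attractor networks; 1 means
#'   unstructured weights. The default places the circuit in the regime with
#'   seconds-scale decaying tail activity after each decision.
#' @return An object of class `connectivity_spec`.
#' @export
connectivity_spec <- function(p_pyr_recurrent = 0.08, p_int_recurrent = 0.1,
                              p_pyr_to_int = 0.1, p_int_to_pyr = 0.2,
                              delay = 0.5, w_plus = 2.2) {
  ps <- c(p_pyr_recurrent, p_int_recurrent, p_pyr_to_int, p_int_to_pyr)
  if (any(ps < 0 | ps > 1))
    stop("connection probabilities must lie in [0, 1]", call. = FALSE)
  if (delay <= 0) stop("conduction delay must be positive", call. = FALSE)
  if (w_plus <= 0) stop("w_plus must be positive", call. = FALSE)
  structure(list(p_pyr_recurrent = p_pyr_recurrent,
                 p_int_recurrent = p_int_recurrent,
                 p_pyr_to_int = p_pyr_to_int,
                 p_int_to_pyr = p_int_to_pyr,
                 delay = delay,
                 w_plus = w_plus),
            class = c("connectivity_spec", "list"))
}

#' Network configuration
#'
#' Assembles populations, architecture, wiring probabilities and integration
#' settings into the configuration consumed by [build_network()] and
#' [run_session()].
#'
#' The `attractor` architecture wires both selective pyramidal pools to a
#' common interneuron pool and back, producing mutual inhibition and
#' winner-take-all competition. The `accumulator` control architecture splits
#' the interneurons into two equal halves wired exclusively to the
#' corresponding selective pool, so the pools integrate independently.
#'
#' @param architecture `"attractor"` or `"accumulator"`.
#' @param n_pyramidal total number of pyramidal cells.
#' @param n_selective neurons per selective subpopulation (two pools).
#' @param n_interneurons number of inhibitory interneurons.
#' @param connectivity a [connectivity_spec()].
#' @param pyramidal,interneuron [neuron_params()] per cell class.
#' @param synapses the synapse parameter table ([synapse_params()]).
#' @param dt Euler integration step (ms).
#' @param wiring_seed integer seed that fixes the probabilistic wiring.
#' @param synapse_update `"additive"` (default): presynaptic spikes increment
#'   the aggregated conductance state by one quantum `G`, the exact
#'   aggregation of per-synapse additive updates. `"saturating"`: the
#'   aggregated state is set to `G` on arrival, for sensitivity checks.
#' @return An object of class `network_config`.
#' @examples
#' cfg <- network_config(wiring_seed = 1)
#' cfg$n_pyramidal
#' @export
network_config <- function(architecture = c("attractor", "accumulator"),
                           n_pyramidal = 1600, n_selective = 240,
                           n_interneurons = 400,
                           connectivity = connectivity_spec(),
                           pyramidal = neuron_params("pyramidal"),
                           interneuron = neuron_params("interneuron"),
                           synapses = synapse_params(),
                           dt = 0.5, wiring_seed = 1L,
                           synapse_update = c("additive", "saturating")) {
  architecture <- match.arg(architecture)
  synapse_update <- match.arg(synapse_update)
  if (2 * n_selective > n_pyramidal)
    stop("two selective pools of ", n_selective,
         " neurons do not fit in ", n_pyramidal, " pyramidal cells", call. = FALSE)
  if (architecture == "accumulator" && n_interneurons %% 2 != 0)
    stop("accumulator architecture needs an even interneuron count", call. = FALSE)
  if (dt <= 0) stop("integration step dt must be positive", call. = FALSE)
  steps <- connectivity$delay / dt
  if (abs(steps - round(steps)) > 1e-9)
    stop("conduction delay must be a whole multiple of dt", call. = FALSE)
  validate_synapse_params(synapses)
  structure(list(architecture = architecture,
                 n_pyramidal = n_pyramidal,
                 n_selective = n_selective,
                 n_interneurons = n_interneurons,
                 connectivity = connectivity,
                 pyramidal = pyramidal,
                 interneuron = interneuron,
                 synapses = synapses,
                 dt = dt,
                 wiring_seed = as.integer(wiring_seed),
                 synapse_update = synapse_update),
            class = c("network_config", "list"))
}

#' Packaged network presets
#'
#' `"competitive"` is the standard winner-take-all circuit (1600 pyramidal
#' cells with two selective pools of 240, 400 interneurons, the published
#' parameter table); `"accumulator"` is the control architecture with split,
#' non-shared interneuron pools.
#'
#' @param name preset name.
#' @param wiring_seed integer seed for the probabilistic wiring.
#' @return A [network_config()].
#' @export
network_preset <- function(name = c("competitive", "accumulator"),
                           wiring_seed = 1L) {
  name <- match.arg(name)
  network_config(architecture = if (name == "competitive") "attractor" else "accumulator",
                 wiring_seed = wiring_seed)
}

#' Read or write a network configuration file
#'
#' Configurations serialize to YAML so experiment runs can log and reload the
#' exact network they used.
#'
#' @param path file path.
#' @return `read_network_config()` returns a [network_config()];
#'   `write_network_config()` returns `path` invisibly.
#' @export
read_network_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn <- do.call(rbind, lapply(raw$synapses, as.data.frame))
  syn[] <- lapply(syn, function(x) if (is.character(x)) x else as.numeric(x))
  network_config(
    architecture = raw$architecture,
    n_pyramidal = raw$n_pyramidal,
    n_selective = raw$n_selective,
    n_interneurons = raw$n_interneurons,
    connectivity = do.call(connectivity_spec, raw$connectivity),
    pyramidal = do.call(neuron_params, c(list(class = "pyramidal"),
                                         raw$pyramidal[setdiff(names(raw$pyramidal), "class")])),
    interneuron = do.call(neuron_params, c(list(class = "interneuron"),
                                           raw$interneuron[setdiff(names(raw$interneuron), "class")])),
    synapses = syn,
    dt = raw$dt,
    wiring_seed = raw$wiring_seed,
    synapse_update = raw$synapse_update
  )
}

#' @rdname read_network_config
#' @param config a [network_config()].
#' @export
write_network_config <- function(config, path) {
  stopifnot(inherits(config, "network_config"))
  out <- list(
    architecture = config$architecture,
    n_pyramidal = config$n_pyramidal,
    n_selective = config$n_selective,
    n_interneurons = config$n_interneurons,
    connectivity = unclass(config$connectivity),
    pyramidal = unclass(config$pyramidal),
    interneuron = unclass(config$interneuron),
    synapses = lapply(seq_len(nrow(config$synapses)),
                      function(i) as.list(config$synapses[i, ])),
    dt = config$dt,
    wiring_seed = config$wiring_seed,
    synapse_update = config$synapse_update
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config>", x$architecture, "architecture\n")
  cat("  pyramidal:", x$n_pyramidal,
      sprintf("(2 x %d selective, %d non-selective)",
              x$n_selective, x$n_pyramidal - 2 * x$n_selective), "\n")
  cat("  interneurons:", x$n_interneurons, "\n")
  cat("  dt:", x$dt, "ms; wiring seed:", x$wiring_seed,
      "; synapse update:", x$synapse_update, "\n")
  invisible(x)
}

# look up one synapse parameter row
synapse_row <- function(synapses, kind, target) {
  row <- synapses[synapses$kind == kind & synapses$target == target, ]
  if (nrow(row) != 1)
    stop("no unique synapse parameters for kind ", kind, " onto ", target,
         call. = FALSE)
  row
}
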
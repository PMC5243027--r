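#' Mono-exponential synaptic conductance
#'
#' Conductance of an AMPA or GABA_A synapse `t` milliseconds after a
#' presynaptic spike: `g(t) = G exp(-t / tau)`. On spike arrival the synapse
#' state takes its maximal value `G` and then decays.
#'
#' @param G maximal conductance (nS).
#' @param tau decay time constant (ms).
#' @param t time since the last presynaptic spike (ms); vectorized.
#' @return Conductance in nS.
#' @examples
#' exp_conductance(1.6, 2, c(0, 2))
#' @export
exp_conductance <- function(G, tau, t) {
  if (any(G < 0)) stop("maximal conductance G must be non-negative", call. = FALSE)
  if (any(tau <= 0)) stop("decay constant tau must be positive", call. = FALSE)
  if (any(t < 0)) stop("time since spike must be non-negative", call. = FALSE)
  G * exp(-t / tau)
}

#' Bi-exponential (NMDA) synaptic conductance
#'
#' Rising-then-decaying conductance waveform
#' `g(t) = G tau_2/(tau_2 - tau_1) (exp(-t/tau_2) - exp(-t/tau_1))`,
#' zero at the moment of the spike, peaking between the rise constant
#' `tau_1` and the decay constant `tau_2`. The normalization is the
#' slow-over-difference prefactor; the waveform is non-negative for all
#' `t >= 0`.
#'
#' @param G maximal conductance (nS).
#' @param tau_1 rise time constant (ms).
#' @param tau_2 decay time constant (ms); must exceed `tau_1`.
#' @param t time since the presynaptic spike (ms); vectorized.
#' @return Conductance in nS.
#' @examples
#' biexp_conductance(0.145, 2, 100, c(0, 8, 500))
#' @export
biexp_conductance <- function(G, tau_1, tau_2, t) {
  if (any(G < 0)) stop("maximal conductance G must be non-negative", call. = FALSE)
  if (any(tau_1 <= 0)) stop("rise constant tau_1 must be positive", call. = FALSE)
  if (any(tau_1 >= tau_2))
    stop("rise constant tau_1 must be smaller than decay constant tau_2",
         call. = FALSE)
  if (any(t < 0)) stop("time since spike must be non-negative", call. = FALSE)
  G * tau_2 / (tau_2 - tau_1) * (exp(-t / tau_2) - exp(-t / tau_1))
}

#' Peak time of the bi-exponential waveform
#'
#' Closed form `t* = tau_1 tau_2 / (tau_2 - tau_1) * log(tau_2 / tau_1)`.
#'
#' @inheritParams biexp_conductance
#' @return Peak time in ms.
#' @export
biexp_peak_time <- function(tau_1, tau_2) {
  if (any(tau_1 <= 0) || any(tau_1 >= tau_2))
    stop("need 0 < tau_1 < tau_2", call. = FALSE)
  tau_1 * tau_2 / (tau_2 - tau_1) * log(tau_2 / tau_1)
}

#' Synaptic current from conductance and driving force
#'
#' `I = g (V_m - E)`: outward-positive convention, so excitatory currents
#' (reversal 0 mV, membrane near rest) are negative.
#'
#' @param g conductance (nS).
#' @param V_m membrane potential (mV).
#' @param E reversal potential (mV).
#' @return Current in pA.
#' @examples
#' synaptic_current(1, -70, 0)    # excitatory drive at rest
#' synaptic_current(1, -70, -70)  # GABA_A at its reversal
#' @export
synaptic_current <- function(g, V_m, E) {
  if (any(g < 0)) stop("conductance must be non-negative", call. = FALSE)
  g * (V_m - E)
}

#' Voltage-dependent magnesium block of NMDA receptors
#'
#' Gating factor `1 / (1 + Mg exp(-0.062 V_m) / 3.57)`, strictly between 0
#' and 1 and monotonically increasing with depolarization.
#'
#' @param V_m membrane potential (mV); vectorized.
#' @param Mg extracellular magnesium concentration (mM).
#' @return Dimensionless gating factor.
#' @examples
#' nmda_gating(0, 1)
#' nmda_gating(-70, 1)
#' @export
nmda_gating <- function(V_m, Mg = 1) {
  if (any(Mg < 0)) stop("magnesium concentration must be non-negative", call. = FALSE)
  1 / (1 + Mg * exp(-0.062 * V_m) / 3.57)
}

#' Total transmembrane current
#'
#' Sum of the three synaptic currents plus the stimulation term, all on the
#' membrane equation's outward-positive scale. With `I_stim = 0` this reduces
#' exactly to the unstimulated synaptic sum. Injected depolarizing
#' stimulation enters this sum with a negative sign (see
#' [stimulation_currents()] for the interface convention).
#'
#' @param I_AMPA,I_NMDA,I_GABA,I_stim currents (pA).
#' @return Total current in pA.
#' @export
total_current <- function(I_AMPA, I_NMDA, I_GABA, I_stim = 0) {
  out <- I_AMPA + I_NMDA + I_GABA + I_stim
  if (any(!is.finite(out))) stop("non-finite current", call. = FALSE)
  out
}

#' Membrane potential derivative of the exponential integrate-and-fire neuron
#'
#' `dV/dt = (-g_L (V_m - E_L) + g_L Delta_T exp((V_m - V_T)/Delta_T) - I_total) / C`
#' in mV/ms. The leak term is restoring (stable fixed point slightly above
#' `E_L` for zero input) and the exponential term produces regenerative spike
#' initiation above `V_T`. `I_total` uses the outward-positive convention of
#' [synaptic_current()], so excitatory (negative) currents depolarize.
#'
#' @param V_m membrane potential (mV); vectorized.
#' @param I_total total transmembrane current (pA).
#' @param params a [neuron_params()] object.
#' @return dV/dt in mV/ms.
#' @examples
#' membrane_derivative(-70, 0, neuron_params("pyramidal"))
#' @export
membrane_derivative <- function(V_m, I_total, params) {
  stopifnot(inherits(params, "neuron_params"))
  I_ion <- -params$g_L * (V_m - params$E_L) +
    params$g_L * params$Delta_T * exp((V_m - params$V_T) / params$Delta_T) -
    I_total
  # pA / nF = mV/s; convert to mV/ms
  I_ion / params$C / 1000
}

#' Subthreshold fixed point of the membrane equation
#'
#' Root of [membrane_derivative()] nearest the resting potential, for a
#' constant input current. Exists only while the input is weak enough that
#' the leak still balances the exponential term.
#'
#' @param I_total constant current (pA).
#' @param params a [neuron_params()] object.
#' @return Fixed-point voltage (mV), or `NA` if no subthreshold root exists.
#' @export
membrane_fixed_point <- function(I_total, params) {
  stopifnot(inherits(params, "neuron_params"))
  f <- function(v) membrane_derivative(v, I_total, params)
  lo <- params$E_L - 40
  hi <- params$V_T  # search below the regenerative region's unstable root
  grid <- seq(lo, hi, by = 0.1)
  vals <- f(grid)
  sgn <- which(diff(sign(vals)) != 0)
  if (!length(sgn)) return(NA_real_)
  uniroot(f, c(grid[sgn[1]], grid[sgn[1] + 1]), tol = 1e-10)$root
}

#' Steady-state membrane polarization from an injected current
#'
#' Leak-dominated estimate `dV = I_stim / g_L` of the resting-potential shift
#' caused by a small constant injected current; used to sanity-check
#' stimulation magnitudes against in vitro polarization measurements.
#'
#' @param I_stim injected current (pA), positive = depolarizing.
#' @param g_L leak conductance (nS).
#' @return Polarization in mV.
#' @examples
#' steady_state_polarization(0.375, 20)
#' @export
steady_state_polarization <- function(I_stim, g_L) {
  if (any(g_L <= 0)) stop("leak conductance must be positive", call. = FALSE)
  I_stim / g_L
}
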
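---
title: "Choice hysteresis in a competitive attractor network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choice hysteresis in a competitive attractor network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

When decisions follow each other closely, humans and animals tend to repeat
their previous choice — *choice hysteresis* — and the tendency is strongest
when the current evidence is weak. `attractorchoice` implements a
biophysical account of this bias: a spiking winner-take-all attractor
network performs a two-alternative motion-discrimination task in
*continuous* sessions, so that decaying activity from the previous
decision is still present when the next stimulus arrives and biases the
competition toward repetition. Weak polarizing currents (a model of
transcranial direct current stimulation) amplify or suppress that residual
activity and thereby steer the bias. The package contains the simulator,
the complete behavioral analysis pipeline, a synthetic behavioral
generator for validating the analyses, and experiment runners that
reproduce the study designs at configurable scale.

## The circuit

The network has 2000 conductance-based exponential integrate-and-fire
neurons: 1600 pyramidal cells — two *selective* pools of 240 coding the
"left" and "right" response options, plus 1120 non-selective cells — and
400 inhibitory interneurons. Within a selective pool, pyramidal cells
recur onto AMPA and NMDA synapses; both pools excite a *common* pool of
interneurons which inhibits all pyramidal cells (GABA\_A), producing
winner-take-all competition. Wiring is Bernoulli: 0.08 for pyramidal
recurrence, 0.1 for pyramidal-to-interneuron and interneuron recurrence,
0.2 for interneuron-to-pyramidal, all with 0.5 ms conduction delays. The
non-selective pool exchanges connections with the whole pyramidal
population at the recurrent probability and projects to the interneurons;
it receives no task input. In the *accumulator* control architecture the
interneurons are split into two halves wired exclusively to the matching
selective pool, removing mutual inhibition while keeping integration.

Membrane dynamics follow the exponential leaky integrate-and-fire
equation,

$$C \frac{dV_m}{dt} = -g_L (V_m - E_L) + g_L \Delta_T
  e^{(V_m - V_T)/\Delta_T} - I_{\mathrm{total}},$$

with synaptic currents $I = g (V_m - E)$ (outward-positive, so excitatory
currents are negative), mono-exponential AMPA/GABA\_A conductances,
bi-exponential NMDA conductances with the voltage-dependent magnesium
block $1/(1 + [\mathrm{Mg}^{2+}] e^{-0.062 V_m} / 3.57)$, and the standard
parameter table of this model family (`synapse_params()`,
`neuron_params()`). Integration is forward Euler at a fixed 0.5 ms step;
spikes register when $V_m \ge V_s$ at the end of a step, reset to $V_r$,
and are held refractory with the membrane clamped at $V_r$. All
quantities are kept in the table's own units (mV, nS, pA, nF, ms), with
the single pA/nF = mV/s conversion applied in one place; this avoids the
scale-factor bugs that creep in when converting a published parameter
table to SI.

Two modeling conventions deserve comment, because the model family admits
both readings:

* **Synaptic update.** The package aggregates one conductance state per
  neuron and synapse kind and, by default, *adds* one quantum $G$ per
  presynaptic spike — the exact aggregation of per-synapse additive
  updates and the convention of the simulators this model family is built
  on. A `saturating` option (the state is *set* to $G$ on arrival) is
  provided for sensitivity checks; with aggregated states it caps the
  entire recurrent NMDA drive at a single quantum and silences the
  network, which is why it is not the default.
* **Stimulation sign.** Stimulation currents are expressed in the
  injected convention (positive = depolarizing) at every interface;
  internally the injected current enters the outward-positive total with
  a negative sign. The standard depolarizing condition injects +0.75 pA
  into pyramidal cells and −0.375 pA into interneurons (the sign
  difference reflecting cellular orientation under an external field);
  hyperpolarizing stimulation reverses both. The implied steady-state
  polarizations, $I/g_L \approx$ 0.038 and 0.019 mV, are far below
  threshold — stimulation biases the dynamics without eliciting spikes.

## Input realization and calibration

The task protocol specifies input *pool rates*: two task channels whose
mean rates vary linearly with motion coherence and always sum to 80 Hz
(`coherence_to_rates()`), resampled every monitor frame (60 Hz) with 4 Hz
jitter, and a background channel at a subject-specific rate (880–950 Hz
for the attractor). How many independent Poisson generators from each
pool converge on a neuron is not specified by the rates themselves, and
the delivered drive depends on the product. A single 900 Hz train through
a 2.1 nS AMPA quantum leaves the network essentially silent (< 0.1 Hz),
which contradicts the regime the model is described to operate in:
selective pools at roughly 3–15 Hz before stimulus onset, winners
crossing response thresholds of 18–22 Hz, losers suppressed toward zero.
The package therefore models each channel as a pool sampled with a
per-neuron *fan-in* (delivered rate = pool rate × fan-in, quanta
unchanged), and fixes the fan-ins once, by calibration against that
described regime:

* background fan-in 1.3 (pyramidal) and 1.1 (interneurons) for the
  attractor; 1.2 / 1.1 for the accumulator, whose uninhibited pools sit
  close to a self-sustaining transition and need less drive — consistent
  with the observation that this architecture is much more sensitive to
  the background level;
* task fan-in 2, which makes the task input a small (~10%) perturbation
  on the background drive, so decisions are resolved by the recurrent
  competition over hundreds of milliseconds rather than relayed
  feed-forward.

A second calibrated constant is structural. With the printed recurrent
conductances and 0.08 connection probability the within-pool
self-excitation loop gain saturates near 0.5–0.6, giving the
winner-minus-loser mode a memory of only ~0.2 s — far too short for
hysteresis that is strong at inter-stimulus intervals (ISIs) of 1.5–2 s
and gone by 5 s. Structured competitive attractor models classically
solve this with Hebbian-potentiated within-pool weights, $w^+ > 1$. The
package exposes this as `connectivity_spec(w_plus = )`, default 2.2:
recurrent AMPA and NMDA synapses between neurons of the same selective
pool are scaled by $w^+$. At the default the differential mode relaxes
with a ~0.8 s time constant — decaying tails that are clearly visible at
a 2 s ISI and have vanished by 5 s — without crossing into persistent
(working-memory-like) bistability. These four constants (three fan-ins
and $w^+$) were calibrated once against the described firing regimes and
then frozen; they are deliberately not part of the subject-level
variability.

## Task protocol

A trial is 1 s of pre-input time, 1 s of task input, and post-input
padding; the ISI is defined from input offset to the next input onset, so
the default 2 s ISI gives the 3 s trial. Shorter or longer ISIs adjust
the post-input padding only, keeping the 1 s pre-input window (which must
contain the 500 ms prestimulus analysis window). Sessions run either
*continuously* — the full network state, including the pending-spike
queue and the input RNG, carries across trials — or *reinitialized*, with
membrane potentials and conductances reset at each trial start (the
falsification control: no state, no hysteresis).

A *virtual subject* is one instantiation of the model: a wiring seed
(quenched connectivity), a background rate drawn uniformly from the
architecture's range, and a response threshold (uniform 18–22 Hz for the
attractor; for the accumulator, an affine map of the background rate onto
19–36 Hz, since the published description ties the threshold to the rate
without giving the form — the affine map through the two range endpoints
is the minimal choice). Blocks use the balanced design: five coherences
(3.2–51.2%) × two directions × a configurable number of repetitions,
randomly ordered. A decision is made when the smoothed rate of a
selective pool first reaches the subject's threshold inside the response
window (input onset to trial end); the crossing time minus onset is the
decision time. Simultaneous crossings break by the higher rate, then by a
seeded coin flip.

## Analysis pipeline

All analyses operate on plain trial tables, identically for simulated and
human-format data:

* **Filtering** (`filter_trials()`): non-response trials are invalid;
  within each subject × condition group, decision times deviating from
  the group median by more than 3 × 1.4826 × MAD are outliers. A floor on
  the MAD keeps degenerate groups (identical times) intact, and the
  median-based rule structurally cannot discard more than half a group.
* **Accuracy threshold** (`weibull_accuracy_threshold()`): per-coherence
  accuracy is fitted to the two-alternative Weibull curve
  $P(c) = 1 - 0.5 e^{-(c/\alpha)^\beta}$ by weighted least squares and
  inverted at 80%.
* **Decision-time regression** (`dt_difference_regression()`): per
  subject × coherence cell means of the stimulation-minus-control
  decision-time difference, pooled and fitted by ordinary least squares
  against coherence.
* **Indecision points** (`indecision_points()`): trials split by the
  previous choice; a two-parameter logistic psychometric curve per group;
  the shift of the 50%-rightward coherence (after-left minus after-right)
  is positive under repetition bias.
* **Sequential logistic model** (`hysteresis_logistic()`): maximum
  likelihood fit of
  $P(\mathrm{right}) = 1/(1 + e^{-(a_0 + a_1 c + a_2 (\delta_R - \delta_L))})$
  with $c$ the signed coherence as a proportion (so $a_1$ is of order 10)
  and the previous-choice regressor ±1. Hysteresis is $a_2 > 0$; the
  normalized effect is $a_2 / a_1$ (defined only for $a_1 > 0$). First
  trials of a block have no defined previous choice and are excluded.
  Under perfect separation the fit is retried with a weak L2 penalty
  (λ = 10⁻³) on the slope terms and flagged `regularized`.
* **Nonparametric tests**: paired Wilcoxon signed-rank (reported as
  $W = \min(W^+, W^-)$, exact for n ≤ 12 without ties), Mann-Whitney U,
  and one-way ANOVA, wrapping the standard R implementations. All tests
  are two-sided; no multiple-comparison correction is applied.

The prestimulus neural measure mirrors the behavioral one: population
rates are spike counts per 0.5 ms bin, normalized and convolved with a
unit-area Gaussian truncated at ±5 ms (σ = 5/3 ms, which puts the kernel
at about 1% of its peak at the cutoff; the published description fixes
only the total width, so σ is configurable). The per-trial *bias* is the
chosen-minus-unchosen pool rate averaged over the 500 ms before input
onset; on repeated-choice trials it is positive — the residual trace that
causes the repetition.

## The synthetic behavioral generator

`generate_session()` draws trial tables with exactly the statistical
structure the analyses assume: sequential logistic choices with a
previous-choice term, response times linear in |coherence| with Gaussian
noise and a 50 ms floor, and non-response and inflated-outlier trials
injected at stated probabilities. It exists so that every analysis stage
can be validated against known ground truth without running the network
(`recovery_experiment()` quantifies coefficient bias and RMSE). The RT
model is deliberately plumbing, not a cognitive model; the generator also
makes no attempt to emulate quenched wiring asymmetries, non-stationary
learning, or the heavy RT tails of real data, so passing recovery tests
certifies the pipeline's correctness, not realism of the RT process.

## What the experiment runners compute

`run_stimulation_experiment()` runs, per subject, one block per
stimulation condition with identical wiring (a within-subject design) and
reports per-subject accuracy thresholds, indecision-point shifts,
hysteresis coefficients, the paired Wilcoxon comparisons against no
stimulation, and the decision-time difference regressions.
`run_isi_experiment()` uses independent subject groups per ISI level (a
between-group design) and a one-way ANOVA across levels.
`run_control_experiments()` re-runs the stimulation design under the
falsification variants: 60 Hz total input, 30/120 Hz refresh,
pyramidal-only / interneuron-only / uniform stimulation, reinitialized
sessions, and the accumulator architecture.

Expected signatures, at any scale: positive $a_2$ across subjects in
continuous sessions; the $a_2/a_1$ ratio increased by depolarizing and
decreased by hyperpolarizing stimulation with no accuracy-threshold
change; decision-time differences largest at low coherence (positive
regression slope under depolarizing, negative under hyperpolarizing);
hysteresis decaying with ISI; and no hysteresis under reinitialization or
the accumulator.

## Numerical choices and accuracy

* Euler at the fixed 0.5 ms step: halving the step changes a 1 s
  subthreshold trace by well under 0.1 mV. Spike timing is coarser: the
  reset potential (−53 mV) lies above the exponential threshold
  (−55 mV), so inter-spike intervals are dominated by the regenerative
  upswing, where the coarse step costs about 2 ms per spike; single-neuron
  firing periods agree with a 0.01 ms reference integration to within
  about 7–9%. Network-level quantities (smoothed rates, decision times at
  the 18–22 Hz thresholds) are insensitive at this level.
* The exponential in the spike term is clamped at argument 20; a step
  ending at or above $V_s$ registers a spike, so the clamp only prevents
  overflow on the step where the spike is already inevitable. Non-finite
  membrane potentials abort with the neuron index and time.
* Conduction delays are quantized to whole steps (0.5 ms = 1 step);
  monitor frames are quantized to whole steps (60 Hz → 33 steps).
* The simulator uses its own small, seedable PCG32 generator for all
  Poisson inputs, so a session is reproducible from integer seeds alone
  and sessions can be resumed bit-identically from a saved state.
  Frame-rate jitter and trial ordering use R's RNG under locally derived
  seeds; experiment-level seeds derive deterministically from one master
  seed.

## Scales used by the shipped tests

The packaged test suite exercises the full designs at desk scale: the
stimulation experiment with 8 subjects (a 100-trial no-stimulation block
and 60-trial stimulation blocks), the
ISI comparison with 5 subjects per level at 1.5 s and 5 s × 40 trials,
and the reinitialization and accumulator controls with 6 subjects × 40
trials. These sizes keep a complete run of the biophysical pipeline in
the tens of minutes on one core while leaving the qualitative signatures
well resolved; the experiment runners default to the full design (20
subjects, 100 trials per block) for standalone use.

## Known limitations

* The input fan-ins and $w^+$ are calibrated constants, not fitted
  quantities; other combinations reproducing the same operating regime
  would serve equally well, and conclusions should not hinge on their
  exact values.
* Neurons are point-like and polarization is uniform within a class; no
  spatial morphology, no heterogeneous field, no plasticity, and no
  hemodynamic signal generation.
* Quenched wiring asymmetry at 240-neuron pool size produces per-subject
  static side biases (absorbed by $a_0$ and the per-subject indecision
  points, as in the analyses), which are larger than what averaging over
  biological heterogeneity would give.
* Model decision times are threshold crossings of smoothed rates; they
  lack the sensory and motor latencies of human response times and are
  comparable to them only through differences and trends, never
  absolutely.
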
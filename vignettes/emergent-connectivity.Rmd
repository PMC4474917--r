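---
title: "Emergent feature-specific connectivity in balanced plastic networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent feature-specific connectivity in balanced plastic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balnet)
```

## The scientific question

In rodent visual cortex, neurons respond selectively to stimulus orientation
already at eye opening, but synaptic connections between similarly tuned
neurons become *functionally specific* — stronger and more often
bidirectional — only later, presumably through experience-dependent
plasticity. `balnet` simulates this developmental scenario in an
inhibition-dominated balanced random network of spiking neurons: recurrent
dynamics alone produce sharp orientation selectivity from weakly tuned
feedforward input, and Hebbian voltage-based plasticity then converts that
selectivity into orientation-specific, reciprocally biased excitatory
connectivity, while inhibitory plasticity keeps the network stable.

## Network model

The network holds $N = 500$ leaky integrate-and-fire neurons, $f = 80\%$
excitatory. The membrane potential obeys
$\tau_m \dot u_k + u_k = R I_k(t)$ with $\tau_m = 20$ ms; at
$u \ge u_{\mathrm{th}} = 20$ mV a spike is emitted and $u$ resets to
$u_0 = 0$ mV. Synaptic currents are $\delta$-pulses, so every presynaptic
spike simply deflects the postsynaptic potential by the PSP amplitude $J$
(in mV): the current formulation with $R$ and the charge $Q$ never needs to
be materialised, as $J = QR/\tau_m$ absorbs them. Excitatory synapses have
$J_{\mathrm{exc}} = 0.5$ mV; inhibitory synapses are $g$ times stronger and
of opposite sign, $J_{\mathrm{inh}} = -g J_{\mathrm{exc}}$ with $g = 8$ by
default (inhibition dominance). Each excitatory neuron contacts a random
30% of all targets (independent Bernoulli draws per target, no autapses);
inhibitory neurons contact everything.

Feedforward drive is one lumped Poisson channel per neuron with rate

$$s(\theta, \theta^*) = s_b\,[1 + \mu \cos 2(\theta - \theta^*)],$$

baseline $s_b = 2$ kHz, PSP $J_{\mathrm{ffw}} = 1$ mV, modulation
$\mu_{\mathrm{exc}} = 20\%$ for excitatory and $\mu_{\mathrm{inh}} = 2\%$
for inhibitory targets. $\theta^*$ is the neuron's input preferred
orientation (PO).

Two modelling choices the source description leaves open:

* **PO assignment.** POs are uniformly spaced on $[0°, 180°)$ within each
  population and neurons are indexed in ascending PO order. This gives
  deterministic uniform coverage and makes weight matrices directly
  comparable across seeds.
* **Population rounding.** $N_{\mathrm{exc}} = \mathrm{round}(fN)$,
  $N_{\mathrm{inh}} = N - N_{\mathrm{exc}}$.

## Integration scheme

Dynamics are advanced with exact integration at a fixed step
$dt = 1$ ms (0.1 ms available for verification): between events the
membrane decays by the exact factor $e^{-dt/\tau_m}$, and all PSPs arriving
in a step are added as instantaneous jumps. Discrete-time conventions,
fixed for reproducibility:

* Recurrent spikes emitted at step $t$ are delivered at step $t+1$ (one
  effective step of delay); feedforward Poisson counts drawn at step $t$
  act within step $t$. This removes within-step event-ordering ambiguity
  that the continuous "no delay" formulation leaves open.
* Synaptic input is accumulated in ascending presynaptic index order, so
  runs are bitwise reproducible for a given seed.
* With rates up to 2.4 kHz, multi-spike bins are common at $dt = 1$ ms;
  feedforward input is therefore injected as (Poisson count) ×
  $J_{\mathrm{ffw}}$.
* The refractory machinery exists but $t_{\mathrm{ref}} = 0$ by default.

Halving the step to 0.1 ms changes population rates by only a few percent
(verified in the test suite), confirming the discretisation is benign.

## Plasticity model

E→E, E→I and I→E synapses evolve under the voltage-based rule

$$\dot w_i = -A_{\mathrm{LTD}}(\bar{\bar u})\,X_i(t)\,
  [\bar u_-(t) - \theta_-]_+ \;+\;
  A_{\mathrm{LTP}}\,\bar x_i(t)\,[u(t) - \theta_+]_+\,
  [\bar u_+(t) - \theta_-]_+ ,$$

with hard bounds ($[0, 2]$ mV for excitatory weights, magnitudes in
$[0, 5]$ mV for inhibitory ones). I→I synapses are never plastic, and no
synapses are created or deleted: entries absent at construction stay zero
forever. $\bar u_-$ and $\bar u_+$ are exponential low-pass filters of the
postsynaptic voltage ($\tau_- = 10$ ms, $\tau_+ = 7$ ms), $\bar x_i$ is a
low-pass filter of the presynaptic spike train ($\tau_x = 15$ ms), and the
depression amplitude is controlled homeostatically,
$A_{\mathrm{LTD}}(\bar{\bar u}) = A_{\mathrm{LTD}}\,\bar{\bar u}^2 /
u_{\mathrm{ref}}^2$, where $\bar{\bar u}$ is the mean depolarization over a
trailing 0.1 s window. Default amplitudes are
$A_{\mathrm{LTD}} = 14 \times 10^{-5}$,
$A_{\mathrm{LTP}} = 8 \times 10^{-5}$, thresholds $\theta_- = -20$ mV,
$\theta_+ = 7.5$ mV, $u_{\mathrm{ref}}^2 = 70\ \mathrm{mV}^2$.

Discretisation and conventions (each verified against an independent scalar
reference implementation in the tests):

* **Depression is event-triggered**: the $\delta$-train $X_i$ integrates to
  one jump of $-A_{\mathrm{LTD}}(\bar{\bar u})[\bar u_- - \theta_-]_+$ per
  presynaptic spike. **Potentiation is integrated** with forward Euler at
  $dt$. This avoids $dt$-dependent double counting.
* **Trace normalisation**: a presynaptic spike increments $\bar x$ by
  $1/\tau_x$ (the unit-area impulse response), giving the trace units of
  rate. The source description says only that the trace increases "by some
  fixed value"; this convention also makes the inhibitory rate rule below
  land on its stated target rate, which corroborates it.
* **Voltage at spike steps**: the LIF has no spike waveform, so at a spike
  step the voltage entering the filters and the rectified terms is clamped
  to $u_{\mathrm{th}}$; the reset applies afterwards. This preserves the
  rule's sensitivity to pre–post coincidence.
* **Homeostatic mean**: $\bar{\bar u}$ is a boxcar average over the
  trailing 100 ms; an exponential variant with the same time constant is
  available (`homeo_filter = "exponential"`) for sensitivity checks.
* **Sign convention for I→E**: nothing in the source specifies how the rule
  maps onto inhibitory weights. We evolve the *magnitude*: "potentiation"
  strengthens inhibition (stored weight more negative), consistent with the
  observed unspecific amplitude increase of inhibitory synapses during
  learning.
* **Event timing**: plasticity events (trace increments, depression
  triggers) use spike *emission* steps, the standard convention; only PSP
  delivery carries the one-step delay.

### Alternative inhibitory rule

For the homeostatic-inhibition variant (`"homeostatic_ie"`), I→E synapses instead follow a rate-homeostatic
pre/post trace rule: on a presynaptic (inhibitory) spike the magnitude
changes by $\eta(\bar x_{\mathrm{post}} - \alpha)$, on a postsynaptic
(excitatory) spike by $\eta \bar x_{\mathrm{pre}}$, with $\eta = 0.1$ and
$\alpha = 0.01$. With the unit-area trace normalisation, the mean-field
fixed point of this rule sits at an excitatory rate of $\alpha/2 =
0.005$ spikes/ms $= 5$ Hz, the stated design target of the variant; the
simulated networks settle slightly below it (≈ 4.4 Hz) because inhibitory
spikes and the postsynaptic trace are positively correlated rather than
independent.

## Stimulation protocols

* **Learning**: batches of 20 stimuli, 100 ms each, drawn from 20
  orientations spaced 9° apart (the source states only "20 different
  orientations"; even spacing is the natural choice). Under uniform
  statistics each batch is a random permutation; under the cardinally
  biased statistics stimuli are i.i.d. with $P(0°) = P(90°) = 0.25$ and
  the rest uniform, matching "half of all stimuli cardinal" without
  imposing further structure. Filters and traces are never reset between
  segments — stimulation is continuous.
* **Default batch count 40** (80 s of "visual experience"). The source
  material is internally inconsistent here: one caption says 40 batches
  while computing $20 \times 20 \times 0.1\,\mathrm{s} = 40$ s, and the
  accompanying text says 80 s with spontaneous activity starting at batch
  41. We follow the 40-batch reading for the default and use each
  variant's stated count (20) for the g-sweep, perturbation and
  supplementary presets; every count is a parameter.
* **Tuning probes**: 8 orientations (0°, 22.5°, …, 157.5°), 10 trials of
  2 s each, orientation-major order, weights frozen.
* **Spontaneous drive**: untuned input at $s_b/2$ ($\mu = 0$) with
  plasticity on, in 2 s "batches" so snapshots stay comparable; the
  homeostatic-inhibition variant uses the full $s_b$ as its description
  states.
* **Connectivity-factor rescaling** ($C = 1, 2, 4$): $s_b \to C s_b$,
  $\mu_{\mathrm{exc}} \to \mu_{\mathrm{exc}}/C$,
  $J_{\mathrm{ffw}} \to J_{\mathrm{ffw}}/C$, $\mu_{\mathrm{inh}}$
  unchanged. This keeps the absolute rate modulation
  $s_b\mu_{\mathrm{exc}}$ and the untuned drive $s_b J_{\mathrm{ffw}}$
  fixed while the *relative* input tuning weakens — the point of the
  manipulation is that output selectivity survives it. (Note the
  triple product $s_b \mu_{\mathrm{exc}} J_{\mathrm{ffw}}$ is *not*
  invariant under these scalings.)

## Analysis metrics

* **Tuning curves**: per neuron and orientation, mean and SD over the 10
  trials of spike count / 2 s.
* **OSI** $= 1 -$ circular variance
  $= |\sum_k r_k e^{2i\theta_k}| / \sum_k r_k$: 0 for flat, 1 for a
  single-orientation response; for $r \propto 1 + \mu\cos 2\theta$ it
  converges to $\mu/2$. All-zero curves are undefined, reported as `NA`,
  excluded from population summaries and counted (some neurons fall silent
  in the sparse post-learning regime).
* **Population-aligned tuning**: curves shifted so each neuron's input PO
  maps to 90°, binned into 180 bins, averaged; the OSI of the binned mean
  curve summarises population selectivity.
* **Membrane-potential tuning**: $\langle u \rangle$ per orientation plus
  the reset-corrected free potential
  $u_{\mathrm{free}} = \langle u \rangle + \tau_m u_{\mathrm{th}} r$.
  The free-potential E/I decomposition disables the threshold of the
  probed neuron *only* (network activity elsewhere unchanged) and
  integrates excitatory- and inhibitory-source input separately; both runs
  share the identical Poisson realisation, which the fixed
  one-draw-per-neuron-per-step RNG layout guarantees.
* **Weight vs. dPO**: circular PO difference in $[0°, 90°]$, group means
  over similar (< 30°), indifferent (30–60°) and dissimilar (> 60°) pairs.
  The **weight-tuning OSI** treats the binned mean-magnitude profile as a
  tuning curve by mirroring the dPO axis onto $[0°, 180°)$, so the
  circular-variance formula applies unchanged; this is one consistent
  reading of an index the source does not define operationally.
* **WBI**: mean over unordered in-scope pairs (all pairs, connected or
  not) of $|w_{ij}||w_{ji}|$; scope defaults to E→E pairs, where the
  bidirectionality question lives. **WBI$_\mathrm{norm}$** divides by the
  mean WBI of 100 surrogates in which the non-zero entries of the scoped
  block are permuted uniformly over its off-diagonal positions (the weight
  multiset is preserved; the source says only "shuffle the elements of the
  weight matrix"). Chance level is 1 in expectation over wiring draws;
  a single network fluctuates around it with pair-sampling noise that
  shrinks with $N$.

## What the generator emulates — and what it does not

The synthetic input reproduces the study conditions: batched random
oriented stimuli, biased statistics, untuned spontaneous drive, and
connectivity-factor rescaling, all as stationary Poisson rate
abstractions. It does not implement image-computable stimuli, receptive
fields, an LGN stage, orientation maps, conductance synapses, synaptic
delays or structural plasticity. Passing tests therefore validate the
network-and-plasticity mechanism under the model's idealisations, not a
fit to any biological recording.

## Problem sizes, tolerances and degenerate inputs

Simulations run at the study's native scale ($N = 500$, 40 learning
batches ≈ 80 s simulated, 160 s probes); replicate counts are 3 seeds for
stochastic summaries. The compiled core is validated against a plain-R
scalar reference implementation to $10^{-10}$ mV on small networks, and
against closed forms for leak decay (exact exponential to $10^{-12}$
relative) and the constant-drive inter-spike interval (within one step). A
deterministic-input mode (each step injects the expected Poisson count)
exists solely for such diagnostics. Degenerate inputs have defined
behaviour: all-zero tuning curves give `NA` selectivity, empty synapse
classes give `NA` group means, a single probe trial flags the trial spread
as undefined, and non-finite membrane potentials abort with a diagnostic
pointing at parameter blow-up.

## Known limitations

* The one-step PSP delay and threshold-clamped filter voltage are
  discretisation conventions; quantitative weight trajectories shift
  slightly under $dt$ refinement even though all qualitative outcomes and
  the headline indices are stable.
* The absolute scale pairing of the trace increment with
  $A_{\mathrm{LTP}}$ is a convention (see above); selectivity and
  bidirectionality outcomes proved robust to it, but this robustness is
  established here only empirically.
* WBI averages over all in-scope pairs, including never-connected ones;
  restricting to pairs with at least one synapse would rescale WBI and
  WBI$_\mathrm{norm}$ identically under the shuffle null, so the
  normalised index is insensitive to this choice.

## A worked example

```{r example, eval = FALSE}
net <- build_network(network_config(), seed = 1)
proto <- make_learning_protocol(n_batches = 40, seed = 2)
sim <- simulate_network(net, proto, plasticity_params(), seed = 3)

wbi_norm(net$W, net)        # ~1: chance-level bidirectionality
wbi_norm(sim$W_final, net)  # elevated after learning
weight_vs_dpo(sim$W_final, net)  # similar-PO synapses strengthened
```

The `run_experiment()` wrapper executes the full phase sequence
(probe → learn → probe → spontaneous → probe) for any preset and returns
the summary metrics; `compare_runs()` tabulates differences between two
bundles.
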
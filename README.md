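# balnet

Simulation and analysis of **emergent feature-specific connectivity in
balanced spiking networks with synaptic plasticity**.

## The problem

In rodent visual cortex, neurons are orientation-selective already at eye
opening, but connections between similarly tuned neurons become stronger —
and disproportionately bidirectional — only later, through visual
experience. `balnet` is for computational neuroscientists who want to study
this two-stage process in a network that is *recurrently* realistic: an
inhibition-dominated balanced random network of leaky integrate-and-fire
(LIF) neurons, where selectivity is created by the recurrent dynamics from
weakly tuned input, and where a voltage-based Hebbian rule then reshapes
recurrent E→E, E→I and I→E synapses.

## The model in brief

- **Network**: N = 500 LIF neurons (80% excitatory), δ-synapses specified by
  PSP amplitude; τ_m = 20 ms, threshold 20 mV, reset 0 mV. Excitatory
  out-connectivity 30% at J_exc = 0.5 mV; inhibitory neurons project
  everywhere at J_inh = −g·J_exc, inhibition dominance g = 8.
- **Input**: one lumped Poisson channel per neuron with rate
  s(θ, θ\*) = s_b·[1 + μ·cos 2(θ − θ\*)], s_b = 2 kHz, J_ffw = 1 mV,
  μ = 20% (E) / 2% (I); θ\* is the neuron's input preferred orientation.
- **Plasticity** (E→E, E→I, I→E; I→I frozen):

  dw/dt = −A_LTD(ū̄)·X(t)·[ū₋ − θ₋]₊ + A_LTP·x̄(t)·[u − θ₊]₊·[ū₊ − θ₋]₊

  with homeostatic depression amplitude A_LTD(ū̄) = A_LTD·ū̄²/u_ref², hard
  bounds, and an optional rate-homeostatic pre/post trace rule for I→E.
- **Metrics**: orientation selectivity index (OSI = 1 − circular variance),
  population-aligned tuning, membrane-potential tuning with free-potential
  correction, weight-versus-ΔPO structure, and a weighted bidirectionality
  index (WBI) normalised by a weight-shuffle null.

Simulation is exact-integration at a fixed 1 ms step with a compiled core;
runs are bitwise reproducible for a given seed.

## Worked example

```r
library(balnet)
b <- run_experiment("default", seed = 1)
b
#> Experiment bundle: preset 'default', seed 1
#>   WBI_norm (E->E): 1.010 before -> 1.394 after learning
#>   E->E group means after (mV): 1.524 / 0.854 / 0.331
#>   mean excitatory OSI: 0.668 before -> 0.836 after
```

Reading the numbers: before learning, reciprocal E→E weight products sit at
chance level (WBI_norm ≈ 1); 40 batches of randomly ordered oriented
stimuli (80 s of "visual experience") raise the normalised bidirectionality
to ≈ 1.4 — a ~40% surplus of bidirectional weight over the shuffle null.
The mean E→E weight between neurons with similar preferred orientations
(ΔPO < 30°) roughly triples from its initial 0.5 mV while dissimilar pairs
(ΔPO > 60°) weaken, i.e. connectivity has become feature-specific; and the
mean single-neuron OSI of the excitatory population increases, with sparser
responses overall.

Other entry points:

```r
net  <- build_network(network_config(g = 4), seed = 1)   # custom network
sw   <- run_sweep("g_sweep", seed = 1)   # inhibition-dominance sweep
pre  <- preset("homeostatic_ie")                  # rate-homeostatic I->E variant
```

The vignette (`vignettes/emergent-connectivity.Rmd`) documents the model,
every numerical convention, the stimulation protocols and the analysis
metrics.

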
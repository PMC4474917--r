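Package: balnet
Title: Plasticity and Feature-Specific Connectivity in Balanced Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of balanced random networks of excitatory
    and inhibitory leaky integrate-and-fire neurons with orientation-tuned
    Poisson input and voltage-based Hebbian plasticity. Constructs sparse
    random networks, simulates their spiking dynamics with exact integration
    at a fixed time step, applies a voltage-dependent potentiation/depression
    rule (with a homeostatic depression amplitude and hard weight bounds) to
    recurrent excitatory and inhibitory synapses, and provides the analysis
    toolkit for the emergent structure: orientation tuning curves, circular
    variance selectivity indices, membrane-potential tuning, weight tuning
    versus preferred-orientation difference, and a weighted bidirectionality
    index with a shuffle-based null. Includes stimulation protocols (batched
    oriented stimuli, tuning probes, untuned spontaneous drive, biased
    stimulus statistics, connectivity-factor rescaling) and presets for full
    experiment variants, including an alternative rate-homeostatic inhibitory
    plasticity rule.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, knitr, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
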
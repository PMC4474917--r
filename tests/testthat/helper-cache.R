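# Heavy simulation runs shared across test files, computed once per session.

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .run_cache, inherits = FALSE))
    assign(name, expr, envir = .run_cache)
  get(name, envir = .run_cache, inherits = FALSE)
}

# Default inhibition-dominated network, 40 batches of oriented-stimulus
# learning. Wiring, stimulus order and input spikes get distinct sub-seeds.
default_run <- function(seed, snapshots = FALSE) {
  cached(sprintf("default_%d_%d", seed, snapshots), {
    net <- build_network(network_config(), seed = seed)
    proto <- make_learning_protocol(40, seed = seed + 100)
    sim <- simulate_network(net, proto, plasticity_params(),
                            seed = seed + 200, record_spikes = FALSE,
                            record_snapshots = snapshots)
    list(net = net, sim = sim)
  })
}

# Tuning probe (8 orientations x 10 x 2 s) on a frozen weight matrix.
probe_run <- function(net, W, seed, params = input_params()) {
  n2 <- net
  n2$W <- W
  sim <- simulate_network(n2, make_tuning_probe(params = params), NULL,
                          seed = seed, record_spikes = FALSE,
                          record_snapshots = FALSE)
  tuning_curves(sim)
}

probe_default <- function(seed, when = c("before", "after")) {
  when <- match.arg(when)
  cached(sprintf("probe_%d_%s", seed, when), {
    run <- default_run(seed, snapshots = (seed == 1))
    W <- if (when == "before") run$net$W else run$sim$W_final
    probe_run(run$net, W, seed = seed + 300)
  })
}

# Spontaneous continuation: untuned drive at s_b / 2, plasticity still on.
spontaneous_default <- function(seed = 1) {
  cached(sprintf("spont_%d", seed), {
    run <- default_run(seed, snapshots = TRUE)
    n2 <- run$net
    n2$W <- run$sim$W_final
    simulate_network(n2, make_spontaneous_protocol(10), plasticity_params(),
                     seed = seed + 400, record_spikes = FALSE,
                     record_snapshots = TRUE)
  })
}

# Homeostatic-inhibition variant: denser E->I wiring, weak Gaussian E->E weights, g = 2,
# rate-homeostatic I->E rule, 40 batches.
homeostatic_ie_run <- function(seed) {
  cached(sprintf("hie_%d", seed), {
    p <- preset("homeostatic_ie")
    net <- build_network(p$network, seed = seed)
    proto <- make_learning_protocol(40, params = p$input, seed = seed + 100)
    sim <- simulate_network(net, proto, p$plasticity, seed = seed + 200,
                            record_spikes = FALSE, record_snapshots = FALSE)
    list(net = net, sim = sim)
  })
}

# g-sweep point: 20 learning batches at inhibition dominance g, with the
# stimulus sequence held fixed across g.
gsweep_run <- function(g) {
  cached(sprintf("g_%d", g), {
    net <- build_network(network_config(g = g), seed = 1)
    proto <- make_learning_protocol(20, seed = 101)
    sim <- simulate_network(net, proto, plasticity_params(), seed = 201,
                            record_spikes = FALSE, record_snapshots = FALSE)
    list(net = net, sim = sim)
  })
}
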
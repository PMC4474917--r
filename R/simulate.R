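#' Simulate network dynamics
#'
#' Runs the leaky integrate-and-fire dynamics of a network under a
#' stimulation protocol, with optional synaptic plasticity. Integration uses
#' exact (exponential) propagation of the membrane potential between PSP
#' jumps at a fixed step `dt`; recurrent spikes emitted at one step are
#' delivered at the next, feedforward Poisson counts act within their step.
#'
#' @param network a [build_network()] object.
#' @param protocol a `balnet_protocol` object.
#' @param plasticity a [plasticity_params()] object, or `NULL` to freeze all
#'   weights.
#' @param seed integer seed for the feedforward Poisson realisation.
#' @param record_v integer vector of neuron ids whose membrane trace is
#'   recorded (end-of-step state, after reset).
#' @param record_spikes record the full spike list (time, neuron id).
#' @param record_snapshots store the weight matrix at every batch boundary
#'   (plus the initial matrix); disable to save memory in sweeps.
#' @param dt override of the integration step (ms); segment durations must
#'   be integer multiples of `dt`.
#' @param u0 initial membrane potential (scalar or per neuron, mV).
#' @param input `"poisson"` (stochastic feedforward counts, the model) or
#'   `"deterministic"` (each step injects the expected count; a mean-drive
#'   diagnostic used e.g. to compare spike times against closed-form LIF
#'   results).
#' @return an object of class `balnet_sim` with elements `spikes`
#'   (data.frame `time_ms`, `neuron`), `rates` (n_segments x N matrix of
#'   mean rates in Hz per segment), `W_final`, `snapshots` (list of weight
#'   matrices, `batch count + 1` entries when recorded), `v` (matrix of
#'   recorded traces), and bookkeeping (`protocol`, `network`, `seed`, `dt`).
#' @export
simulate_network <- function(network, protocol, plasticity = NULL, seed = 1,
                             record_v = integer(0), record_spikes = TRUE,
                             record_snapshots = TRUE, dt = NULL,
                             u0 = NULL, input = c("poisson", "deterministic")) {
  input <- match.arg(input)
  dt <- if (is.null(dt)) network$config$dt else dt
  segs <- protocol$segments
  steps <- segs$duration_ms / dt
  if (any(abs(steps - round(steps)) > 1e-9))
    stop("segment durations must be integer multiples of dt")
  steps <- as.integer(round(steps))
  N <- network$config$N
  if (is.null(u0)) u0 <- rep(network$config$u_rest, N)
  if (length(u0) == 1L) u0 <- rep(u0, N)

  rates <- protocol_rates(protocol, network)
  snap_after <- integer(nrow(segs))
  snap_after[protocol$batch_ends] <- 1L

  set.seed(as.integer(seed))
  res <- sim_core(network$W, network$mask,
                  as.integer(network$pop == "I"), u0,
                  rates, steps, snap_after,
                  dt, network$config$tau_m, network$config$u_th,
                  network$config$u_rest,
                  as.integer(round(network$config$t_ref / dt)),
                  protocol$params$J_ffw,
                  plasticity_to_core(plasticity),
                  as.integer(record_v - 1L), integer(0),
                  record_spikes, record_snapshots,
                  input == "poisson")

  out <- list(
    spikes = data.frame(time_ms = res$spike_t, neuron = res$spike_id),
    rates = res$seg_counts / (segs$duration_ms / 1000),  # Hz
    W_final = res$W_final,
    snapshots = res$snapshots,
    v = res$v,
    record_v = record_v,
    protocol = protocol, network = network,
    plasticity = plasticity, seed = as.integer(seed), dt = dt)
  class(out) <- "balnet_sim"
  out
}

#' @export
print.balnet_sim <- function(x, ...) {
  cat(sprintf("Network simulation: %.1f s at dt = %g ms, %d spikes\n",
              protocol_duration_ms(x$protocol) / 1000, x$dt, nrow(x$spikes)))
  is_e <- x$network$pop == "E"
  cat(sprintf("  mean rate: %.2f Hz (exc), %.2f Hz (inh)\n",
              mean(x$rates[, is_e]), mean(x$rates[, !is_e])))
  cat(sprintf("  plasticity: %s\n",
              if (is.null(x$plasticity)) "off (frozen weights)" else "on"))
  invisible(x)
}

#' Mean population rate of a simulation
#'
#' @param sim a `balnet_sim` object.
#' @param population `"E"`, `"I"` or `"all"`.
#' @param segments optional subset of segment indices (e.g. the final
#'   batches of a learning run).
#' @return mean firing rate in Hz.
#' @export
mean_rate <- function(sim, population = "E", segments = NULL) {
  sel <- switch(population,
                E = sim$network$pop == "E",
                I = sim$network$pop == "I",
                all = rep(TRUE, length(sim$network$pop)))
  r <- sim$rates[, sel, drop = FALSE]
  if (!is.null(segments)) r <- r[segments, , drop = FALSE]
  mean(r)
}

#' Free membrane-potential decomposition
#'
#' Re-simulates the (frozen-weight) network with the spike threshold
#' disabled for the designated neurons only, so their membrane potential
#' integrates freely while network activity elsewhere is unchanged, and
#' records separately the leaky integrals of their excitatory-source input
#' (feedforward plus recurrent excitatory) and inhibitory-source input. A
#' companion run with identical input realisation (same seed, hence the
#' same Poisson draws) provides the actual spiking trace.
#'
#' @param network a [build_network()] object.
#' @param protocol a `balnet_protocol` object.
#' @param neuron_ids neurons whose threshold is disabled and decomposed.
#' @param seed integer seed shared by both runs.
#' @return a list with matrices `u_actual`, `u_free`, `u_free_exc`,
#'   `u_free_inh` (steps x neurons) and the step size `dt`.
#' @export
free_potential_decomposition <- function(network, protocol, neuron_ids,
                                         seed = 1) {
  N <- network$config$N
  if (any(neuron_ids < 1L | neuron_ids > N)) stop("neuron id out of range")
  dt <- network$config$dt
  segs <- protocol$segments
  steps <- as.integer(round(segs$duration_ms / dt))
  rates <- protocol_rates(protocol, network)
  u0 <- rep(network$config$u_rest, N)
  snap_after <- integer(nrow(segs))

  run <- function(free_ids, rec_ids) {
    set.seed(as.integer(seed))
    sim_core(network$W, network$mask, as.integer(network$pop == "I"), u0,
             rates, steps, snap_after,
             dt, network$config$tau_m, network$config$u_th,
             network$config$u_rest,
             as.integer(round(network$config$t_ref / dt)),
             protocol$params$J_ffw, NULL,
             as.integer(rec_ids - 1L), as.integer(free_ids - 1L),
             FALSE, FALSE, TRUE)
  }
  actual <- run(integer(0), neuron_ids)
  free <- run(neuron_ids, integer(0))
  list(u_actual = actual$v, u_free = free$free_u,
       u_free_exc = free$free_exc, u_free_inh = free$free_inh, dt = dt)
}
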
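#' Run a full experiment from a preset
#'
#' Executes the standard phase sequence of the study: tuning probe on the
#' initial frozen network, batched oriented-stimulus learning with plastic
#' synapses, probe on the frozen learned network, untuned spontaneous drive
#' with plasticity still on, and a final probe. Weight state is carried
#' across phases; probe phases always freeze the weights. Sub-seeds for
#' wiring, stimulus order and input spikes are fanned out deterministically
#' from the master seed, so stimulus randomness can be held fixed across
#' parameter sweeps.
#'
#' @param spec a preset name (see [preset()]) or a preset list.
#' @param seed master seed.
#' @param probes run the tuning probes (before/after learning).
#' @param spontaneous run the spontaneous phase.
#' @param record_snapshots store per-batch weight snapshots of the learning
#'   and spontaneous phases.
#' @param probe_trials trials per orientation in the probes.
#' @return an object of class `balnet_bundle`: the network, the learning /
#'   spontaneous simulations, tuning curves before and after, and summary
#'   connectivity metrics (`wbi_norm_before`, `wbi_norm_after`,
#'   [weight_vs_dpo()] reports).
#' @export
run_experiment <- function(spec = "default", seed = 1, probes = TRUE,
                           spontaneous = TRUE, record_snapshots = TRUE,
                           probe_trials = 10) {
  if (is.character(spec)) spec <- preset(spec)
  seeds <- fan_out_seeds(seed, 4)
  net <- build_network(spec$network, seeds[1])

  learn_proto <- make_learning_protocol(
    spec$n_learning_batches,
    orientation_weights = spec$orientation_weights,
    params = spec$input, seed = seeds[2])
  probe_proto <- make_tuning_probe(n_trials = probe_trials,
                                   params = spec$input)

  tuning_before <- tuning_after <- NULL
  if (probes) {
    sim0 <- simulate_network(net, probe_proto, plasticity = NULL,
                             seed = seeds[3], record_spikes = FALSE,
                             record_snapshots = FALSE)
    tuning_before <- tuning_curves(sim0)
  }

  learn_sim <- simulate_network(net, learn_proto, plasticity = spec$plasticity,
                                seed = seeds[4], record_spikes = FALSE,
                                record_snapshots = record_snapshots)
  net_after <- net
  net_after$W <- learn_sim$W_final

  spont_sim <- NULL
  if (spontaneous) {
    spont_proto <- make_spontaneous_protocol(spec$n_spont_batches,
                                             params = spec$input,
                                             baseline_frac = spec$spont_frac)
    spont_sim <- simulate_network(net_after, spont_proto,
                                  plasticity = spec$plasticity,
                                  seed = seeds[4] + 1L,
                                  record_spikes = FALSE,
                                  record_snapshots = record_snapshots)
    net_after$W <- spont_sim$W_final
  }

  if (probes) {
    sim1 <- simulate_network(net_after, probe_proto, plasticity = NULL,
                             seed = seeds[3], record_spikes = FALSE,
                             record_snapshots = FALSE)
    tuning_after <- tuning_curves(sim1)
  }

  out <- list(
    spec = spec, seed = seed, network = net,
    W_before = net$W, W_after = learn_sim$W_final,
    learn_sim = learn_sim, spont_sim = spont_sim,
    tuning_before = tuning_before, tuning_after = tuning_after,
    wbi_norm_before = wbi_norm(net$W, net, seed = seed),
    wbi_norm_after = wbi_norm(learn_sim$W_final, net, seed = seed),
    dpo_before = weight_vs_dpo(net$W, net),
    dpo_after = weight_vs_dpo(learn_sim$W_final, net))
  class(out) <- "balnet_bundle"
  out
}

fan_out_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max %/% 2L, n)
}

#' @export
print.balnet_bundle <- function(x, ...) {
  cat(sprintf("Experiment bundle: preset '%s', seed %d\n",
              x$spec$name, x$seed))
  cat(sprintf("  WBI_norm (E->E): %.3f before -> %.3f after learning\n",
              x$wbi_norm_before, x$wbi_norm_after))
  gm <- x$dpo_after$group_means
  cat(sprintf("  E->E group means after (mV): %.3f / %.3f / %.3f\n",
              gm[1], gm[2], gm[3]))
  if (!is.null(x$tuning_before)) {
    cat(sprintf("  mean excitatory OSI: %.3f before -> %.3f after\n",
                osi_distribution(x$tuning_before)$mean,
                osi_distribution(x$tuning_after)$mean))
  }
  invisible(x)
}

#' Run a sweep preset
#'
#' Executes the parameter sweeps of the sweep presets: `"factor_sweep"` probes one
#' learned network under connectivity-factor-rescaled input (C = 1, 2, 4);
#' `"g_sweep"` learns separate networks across the inhibition-dominance values
#' `g`; `"perturbation"` perturbs each principal plasticity parameter by the given
#' fractions. Stimulus randomness is held fixed across sweep points (shared
#' sub-seeds), so differences reflect the swept parameter.
#'
#' @param spec a sweep preset name or preset list (must carry a `sweep`
#'   component).
#' @param seed master seed.
#' @param probes,probe_trials passed to [run_experiment()] where applicable.
#' @return a list with per-point results and a `summary` data.frame of the
#'   headline metrics per sweep point.
#' @export
run_sweep <- function(spec, seed = 1, probes = FALSE, probe_trials = 10) {
  if (is.character(spec)) spec <- preset(spec)
  if (is.null(spec$sweep)) stop("spec has no sweep component; use run_experiment()")
  if (!is.null(spec$sweep$C)) {
    # probe a single learned network under rescaled input
    base <- run_experiment(spec, seed = seed, probes = FALSE,
                           spontaneous = FALSE, record_snapshots = FALSE)
    pts <- lapply(spec$sweep$C, function(C) {
      ip <- apply_connectivity_factor(spec$input, C)
      pr <- make_tuning_probe(n_trials = probe_trials, params = ip)
      before <- tuning_curves(simulate_network(
        base$network, pr, NULL, seed = seed + 300L,
        record_spikes = FALSE, record_snapshots = FALSE))
      net_after <- base$network
      net_after$W <- base$W_after
      after <- tuning_curves(simulate_network(
        net_after, pr, NULL, seed = seed + 300L,
        record_spikes = FALSE, record_snapshots = FALSE))
      list(C = C, tuning_before = before, tuning_after = after)
    })
    summary <- data.frame(
      C = spec$sweep$C,
      osi_before = vapply(pts, function(p)
        population_average_tuning(p$tuning_before)$osi, numeric(1)),
      osi_after = vapply(pts, function(p)
        population_average_tuning(p$tuning_after)$osi, numeric(1)))
    return(list(points = pts, summary = summary, base = base))
  }
  if (!is.null(spec$sweep$g)) {
    pts <- lapply(spec$sweep$g, function(g) {
      sp <- spec
      sp$network$g <- g
      sp$network$J_inh <- -g * sp$network$J_exc
      sp$sweep <- NULL
      run_experiment(sp, seed = seed, probes = probes,
                     spontaneous = FALSE, record_snapshots = FALSE,
                     probe_trials = probe_trials)
    })
    summary <- data.frame(
      g = spec$sweep$g,
      weight_tuning_osi = vapply(pts, function(b)
        b$dpo_after$weight_tuning_osi, numeric(1)),
      wbi_norm_after = vapply(pts, function(b) b$wbi_norm_after, numeric(1)))
    return(list(points = pts, summary = summary))
  }
  if (!is.null(spec$sweep$perturb)) {
    params <- c("A_LTD", "A_LTP", "theta_minus", "theta_plus", "u_ref_sq")
    grid <- expand.grid(param = params, frac = spec$sweep$perturb,
                        stringsAsFactors = FALSE)
    pts <- lapply(seq_len(nrow(grid)), function(k) {
      sp <- spec
      sp$plasticity <- perturb_plasticity(grid$param[k], grid$frac[k],
                                          spec$plasticity)
      sp$sweep <- NULL
      run_experiment(sp, seed = seed, probes = probes,
                     spontaneous = FALSE, record_snapshots = FALSE,
                     probe_trials = probe_trials)
    })
    summary <- cbind(grid, weight_tuning_osi = vapply(pts, function(b)
      b$dpo_after$weight_tuning_osi, numeric(1)))
    return(list(points = pts, summary = summary))
  }
  stop("unrecognised sweep component")
}

#' Compare the summary metrics of two experiment bundles
#'
#' @param a,b `balnet_bundle` objects with compatible metric sets.
#' @return a data.frame of metric values in `a`, in `b` and their
#'   difference (`b - a`).
#' @export
compare_runs <- function(a, b) {
  grab <- function(x) {
    v <- c(wbi_norm_before = x$wbi_norm_before,
           wbi_norm_after = x$wbi_norm_after,
           weight_tuning_osi = x$dpo_after$weight_tuning_osi,
           group_similar = x$dpo_after$group_means[1],
           group_indifferent = x$dpo_after$group_means[2],
           group_dissimilar = x$dpo_after$group_means[3])
    if (!is.null(x$tuning_before)) {
      v <- c(v, mean_osi_before = osi_distribution(x$tuning_before)$mean,
             mean_osi_after = osi_distribution(x$tuning_after)$mean)
    }
    v
  }
  va <- grab(a); vb <- grab(b)
  common <- intersect(names(va), names(vb))
  if (length(common) == 0L) stop("bundles share no metrics")
  data.frame(metric = common, a = va[common], b = vb[common],
             delta = vb[common] - va[common], row.names = NULL)
}
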
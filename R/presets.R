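#' Experiment presets
#'
#' Named parameter sets for the study variants. Each preset bundles a
#' network configuration, plasticity parameters, input parameters and the
#' learning-protocol settings; sweep presets (`"factor_sweep"`, `"g_sweep"`,
#' `"perturbation"`) additionally carry the swept values.
#'
#' Available presets:
#' * `"default"`: inhibition-dominated network, g = 8, 40 learning batches.
#' * `"factor_sweep"`: connectivity-factor probes (C = 1, 2, 4).
#' * `"cardinal_bias"`: cardinally biased stimulus statistics.
#' * `"weak_inhibition"`: g = 4, 20 batches.
#' * `"g_sweep"`: sweep of the inhibition dominance g, 20 batches each.
#' * `"perturbation"`: each principal plasticity parameter perturbed by
#'   +/-10%, 20 batches.
#' * `"dense_ei_static_ie"`: denser E->I wiring (80%), weak weights
#'   (0.1 mV), g = 4, I->E frozen, 20 batches.
#' * `"gaussian_init"`: Gaussian initial excitatory weights.
#' * `"fast_exc_ltp"` / `"fast_inh_ltp"`: potentiation amplitude +20% for
#'   excitatory / inhibitory synapses, 20 batches.
#' * `"homeostatic_ie"`: denser E->I wiring, Gaussian E->E weights around
#'   0.1 mV, g = 2, rate-homeostatic I->E rule, spontaneous drive at the
#'   full baseline.
#'
#' @param name preset name.
#' @return a list with components `network` ([network_config()]),
#'   `plasticity` ([plasticity_params()]), `input` ([input_params()]),
#'   `n_learning_batches`, `orientation_weights`, `spont_frac`,
#'   `n_spont_batches` and optionally `sweep`.
#' @export
preset <- function(name = c("default", "factor_sweep", "cardinal_bias", "weak_inhibition", "g_sweep",
                            "perturbation", "dense_ei_static_ie", "gaussian_init", "fast_exc_ltp", "fast_inh_ltp", "homeostatic_ie")) {
  name <- match.arg(name)
  base <- list(network = network_config(),
               plasticity = plasticity_params(),
               input = input_params(),
               n_learning_batches = 40L,
               orientation_weights = NULL,
               spont_frac = 0.5,
               n_spont_batches = 10L,
               name = name)
  switch(name,
    default = base,
    factor_sweep = within_list(base, sweep = list(C = c(1, 2, 4))),
    cardinal_bias = within_list(base,
                                orientation_weights = cardinal_weights()),
    weak_inhibition = within_list(base, network = network_config(g = 4),
                                  n_learning_batches = 20L),
    g_sweep = within_list(base, sweep = list(g = 1:8),
                          n_learning_batches = 20L),
    perturbation = within_list(base, sweep = list(perturb = c(-0.1, 0.1)),
                               n_learning_batches = 20L),
    dense_ei_static_ie = within_list(
      base,
      network = network_config(eps_EI = 0.8, J_exc = 0.1, g = 4),
      plasticity = plasticity_params(rule_IE = "frozen"),
      n_learning_batches = 20L),
    gaussian_init = within_list(
      base, network = network_config(init_weight_mode = "gaussian")),
    fast_exc_ltp = within_list(
      base, plasticity = plasticity_params(A_LTP_exc = 9.6e-5),
      n_learning_batches = 20L),
    fast_inh_ltp = within_list(
      base, plasticity = plasticity_params(A_LTP_inh = 9.6e-5),
      n_learning_batches = 20L),
    homeostatic_ie = within_list(
      base,
      network = network_config(eps_EI = 0.8, J_exc = 0.1, g = 2,
                               init_weight_mode = "gaussian",
                               gaussian_classes = "EE"),
      plasticity = plasticity_params(rule_IE = "vogels"),
      spont_frac = 1))
}

within_list <- function(x, ...) {
  mods <- list(...)
  x[names(mods)] <- mods
  x
}

#' Perturbed plasticity parameters for robustness sweeps
#'
#' Scales one of the five principal plasticity parameters (`A_LTD`,
#' `A_LTP`, `theta_minus`, `theta_plus`, `u_ref_sq`) by `1 + frac`.
#'
#' @param which parameter name.
#' @param frac relative perturbation (e.g. `0.1` or `-0.1`).
#' @param base baseline [plasticity_params()].
#' @return a perturbed [plasticity_params()] object.
#' @export
perturb_plasticity <- function(which = c("A_LTD", "A_LTP", "theta_minus",
                                         "theta_plus", "u_ref_sq"),
                               frac, base = plasticity_params()) {
  which <- match.arg(which)
  args <- list(A_LTD = base$A_LTD, A_LTP = base$A_LTP,
               theta_minus = base$theta_minus, theta_plus = base$theta_plus,
               u_ref_sq = base$u_ref_sq, rule_IE = base$rule_IE)
  args[[which]] <- args[[which]] * (1 + frac)
  do.call(plasticity_params, args)
}
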
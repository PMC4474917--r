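#' Voltage-based plasticity parameters
#'
#' Parameters of the voltage-dependent potentiation/depression rule applied
#' to recurrent E->E, E->I and I->E synapses (I->I synapses are never
#' plastic). Depression is triggered by presynaptic spikes when a slow
#' low-pass filter of the postsynaptic voltage exceeds `theta_minus`, with an
#' amplitude scaled homeostatically by the squared mean depolarization over a
#' trailing 100 ms window relative to `u_ref_sq`. Potentiation accrues
#' continuously when the momentary voltage exceeds `theta_plus` while a
#' faster voltage filter is above `theta_minus`, gated by a presynaptic
#' spike trace. Weights are clipped to hard bounds: excitatory synapses to
#' `[0, w_max_exc]` mV, inhibitory magnitudes to `[0, w_max_inh]` mV.
#'
#' For inhibitory (I->E) synapses the rule acts on the weight magnitude:
#' "potentiation" strengthens inhibition (the stored weight becomes more
#' negative).
#'
#' @param A_LTD depression amplitude.
#' @param A_LTP potentiation amplitude.
#' @param A_LTP_exc,A_LTP_inh optional per-class overrides of `A_LTP` for
#'   excitatory (E->E and E->I) and inhibitory (I->E) synapses.
#' @param theta_minus,theta_plus voltage thresholds (mV).
#' @param tau_minus,tau_plus time constants (ms) of the slow and fast
#'   postsynaptic voltage filters.
#' @param tau_x presynaptic spike-trace time constant (ms); each presynaptic
#'   spike increments the trace by `1 / tau_x` (unit-area impulse), so the
#'   trace has units of rate.
#' @param u_ref_sq homeostatic reference depolarization squared (mV^2).
#' @param homeo_ms averaging window (ms) of the homeostatic mean
#'   depolarization.
#' @param homeo_filter `"boxcar"` (trailing moving average, the default) or
#'   `"exponential"` (same time constant) for sensitivity checks.
#' @param w_max_exc,w_max_inh hard upper bounds (mV) for excitatory weights
#'   and inhibitory magnitudes.
#' @param rule_IE rule governing I->E synapses: the same `"voltage"` rule,
#'   the `"vogels"` rate-homeostatic rule (see [vogels_params()]), or
#'   `"frozen"`.
#' @param vogels parameters for `rule_IE = "vogels"`.
#' @return an object of class `balnet_plasticity`.
#' @export
plasticity_params <- function(A_LTD = 14e-5, A_LTP = 8e-5,
                              A_LTP_exc = NULL, A_LTP_inh = NULL,
                              theta_minus = -20, theta_plus = 7.5,
                              tau_minus = 10, tau_plus = 7, tau_x = 15,
                              u_ref_sq = 70, homeo_ms = 100,
                              homeo_filter = c("boxcar", "exponential"),
                              w_max_exc = 2, w_max_inh = 5,
                              rule_IE = c("voltage", "vogels", "frozen"),
                              vogels = vogels_params()) {
  homeo_filter <- match.arg(homeo_filter)
  rule_IE <- match.arg(rule_IE)
  stopifnot(A_LTD >= 0, A_LTP >= 0, tau_minus > 0, tau_plus > 0, tau_x > 0,
            u_ref_sq > 0, homeo_ms > 0, w_max_exc > 0, w_max_inh > 0)
  p <- list(A_LTD = A_LTD, A_LTP = A_LTP,
            A_LTP_exc = if (is.null(A_LTP_exc)) A_LTP else A_LTP_exc,
            A_LTP_inh = if (is.null(A_LTP_inh)) A_LTP else A_LTP_inh,
            theta_minus = theta_minus, theta_plus = theta_plus,
            tau_minus = tau_minus, tau_plus = tau_plus, tau_x = tau_x,
            u_ref_sq = u_ref_sq, homeo_ms = homeo_ms,
            homeo_filter = homeo_filter,
            w_max_exc = w_max_exc, w_max_inh = w_max_inh,
            rule_IE = rule_IE, vogels = vogels)
  class(p) <- "balnet_plasticity"
  p
}

#' Rate-homeostatic inhibitory plasticity parameters
#'
#' Parameters of the alternative pre/post spike-trace rule for I->E
#' synapses: on a presynaptic (inhibitory) spike the weight magnitude
#' changes by `eta * (xbar_post - alpha)`; on a postsynaptic (excitatory)
#' spike it changes by `eta * xbar_pre`. Traces are low-pass filtered spike
#' trains with the shared time constant `tau_x` and unit-area increments,
#' which places the stable excitatory firing rate at `alpha / 2`
#' (5 Hz for the default `alpha`).
#'
#' @param eta learning rate.
#' @param alpha depression factor (units of rate, spikes/ms).
#' @return an object of class `balnet_vogels`.
#' @export
vogels_params <- function(eta = 0.1, alpha = 0.01) {
  stopifnot(eta > 0, alpha >= 0)
  p <- list(eta = eta, alpha = alpha)
  class(p) <- "balnet_vogels"
  p
}

#' Homeostatic depression amplitude
#'
#' The depression amplitude scaled by the squared homeostatic mean
#' depolarization: `A_LTD * u_dblbar^2 / u_ref_sq`.
#'
#' @param u_dblbar mean depolarization over the homeostatic window (mV).
#' @param params a [plasticity_params()] object.
#' @return the effective depression amplitude (vectorised over `u_dblbar`).
#' @export
homeostatic_amplitude <- function(u_dblbar, params = plasticity_params()) {
  stopifnot(all(is.finite(u_dblbar)))
  params$A_LTD * u_dblbar^2 / params$u_ref_sq
}

#' One step of the voltage-based rule for a single synapse
#'
#' Scalar/vector form of the update applied inside the simulator, useful for
#' scripted single-synapse analyses: depression is a discrete jump
#' `-A_LTD(u_dblbar) * [u_minus - theta_minus]+` per presynaptic spike;
#' potentiation accrues as
#' `dt * A_LTP * x_pre * [u_post - theta_plus]+ * [u_plus - theta_minus]+`.
#' The result is clipped to the class bounds. For inhibitory synapses the
#' update acts on the magnitude and the returned weight is `-magnitude`.
#'
#' @param w current weight (mV; negative for inhibitory synapses).
#' @param pre_spike 0/1 presynaptic spike indicator for this step.
#' @param u_post momentary postsynaptic voltage (mV, threshold-clamped).
#' @param u_minus,u_plus low-pass filtered postsynaptic voltages (mV).
#' @param x_pre presynaptic spike trace.
#' @param u_dblbar homeostatic mean depolarization (mV).
#' @param params a [plasticity_params()] object.
#' @param dt step size (ms).
#' @param class `"exc"` (E->E / E->I) or `"inh"` (I->E).
#' @return the updated weight.
#' @export
voltage_rule_step <- function(w, pre_spike, u_post, u_minus, u_plus, x_pre,
                              u_dblbar, params = plasticity_params(),
                              dt = 1, class = c("exc", "inh")) {
  class <- match.arg(class)
  ltd <- pre_spike * homeostatic_amplitude(u_dblbar, params) *
    pmax(u_minus - params$theta_minus, 0)
  a_ltp <- if (class == "exc") params$A_LTP_exc else params$A_LTP_inh
  ltp <- dt * a_ltp * x_pre * pmax(u_post - params$theta_plus, 0) *
    pmax(u_plus - params$theta_minus, 0)
  if (!all(is.finite(ltd)) || !all(is.finite(ltp)))
    stop("non-finite weight update")
  if (class == "exc") {
    pmin(pmax(w - ltd + ltp, 0), params$w_max_exc)
  } else {
    -pmin(pmax(-w - ltd + ltp, 0), params$w_max_inh)
  }
}

#' One step of the rate-homeostatic inhibitory rule
#'
#' @param w_mag current weight magnitude (mV, >= 0).
#' @param pre_spike,post_spike 0/1 spike indicators for the inhibitory
#'   presynaptic and excitatory postsynaptic neuron.
#' @param x_pre,x_post spike traces of pre- and postsynaptic neuron.
#' @param params_v a [vogels_params()] object.
#' @param w_max magnitude bound (mV).
#' @return the updated magnitude, clipped to `[0, w_max]`.
#' @export
vogels_rule_step <- function(w_mag, pre_spike, post_spike, x_pre, x_post,
                             params_v = vogels_params(), w_max = 5) {
  d <- pre_spike * params_v$eta * (x_post - params_v$alpha) +
    post_spike * params_v$eta * x_pre
  pmin(pmax(w_mag + d, 0), w_max)
}

# flatten to the list consumed by the C++ core
plasticity_to_core <- function(p) {
  if (is.null(p)) return(NULL)
  list(a_ltd = p$A_LTD, a_ltp_exc = p$A_LTP_exc, a_ltp_inh = p$A_LTP_inh,
       theta_minus = p$theta_minus, theta_plus = p$theta_plus,
       tau_minus = p$tau_minus, tau_plus = p$tau_plus, tau_x = p$tau_x,
       u_ref_sq = p$u_ref_sq, homeo_ms = p$homeo_ms,
       wmax_e = p$w_max_exc, wmax_i = p$w_max_inh,
       rule_ie = match(p$rule_IE, c("voltage", "vogels", "frozen")) - 1L,
       homeo_mode = match(p$homeo_filter, c("boxcar", "exponential")) - 1L,
       eta = p$vogels$eta, alpha = p$vogels$alpha)
}
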
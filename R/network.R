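#' Network configuration
#'
#' Parameters of the balanced random network: population sizes, wiring
#' probabilities, synaptic amplitudes and single-neuron constants. Defaults
#' reproduce the standard parameter set of the model: an inhibition-dominated
#' network of 500 leaky integrate-and-fire neurons (80% excitatory) with
#' sparse excitatory (30%) and dense inhibitory (100%) out-connectivity,
#' excitatory PSP amplitude 0.5 mV and inhibitory amplitude `-g * J_exc` with
#' `g = 8`.
#'
#' @param N total number of neurons.
#' @param f excitatory fraction; `N_exc = round(f * N)`, `N_inh = N - N_exc`.
#' @param eps_EE,eps_EI out-connection probability of an excitatory neuron to
#'   excitatory / inhibitory targets (independent Bernoulli draws per target).
#' @param eps_IE,eps_II out-connection probability of an inhibitory neuron.
#' @param J_exc excitatory PSP amplitude (mV).
#' @param g inhibition-dominance ratio; inhibitory amplitude is `-g * J_exc`.
#' @param J_ffw feedforward PSP amplitude (mV).
#' @param tau_m membrane time constant (ms).
#' @param u_th spike threshold (mV).
#' @param u_rest resting/reset potential (mV).
#' @param t_ref absolute refractory period (ms).
#' @param dt integration step (ms); 0.1 ms available for verification runs.
#' @param init_weight_mode `"fixed"` sets every existing excitatory synapse to
#'   `J_exc`; `"gaussian"` draws amplitudes from N(`J_exc`, `J_exc`) with
#'   negative draws clipped to zero (the synapse still exists and may regrow).
#' @param gaussian_classes synapse classes the Gaussian initialisation applies
#'   to, subset of `c("EE", "EI")`.
#' @return an object of class `balnet_config` (a validated list).
#' @export
network_config <- function(N = 500, f = 0.8,
                           eps_EE = 0.30, eps_EI = 0.30,
                           eps_IE = 1.0, eps_II = 1.0,
                           J_exc = 0.5, g = 8, J_ffw = 1.0,
                           tau_m = 20, u_th = 20, u_rest = 0,
                           t_ref = 0, dt = 1.0,
                           init_weight_mode = c("fixed", "gaussian"),
                           gaussian_classes = c("EE", "EI")) {
  init_weight_mode <- match.arg(init_weight_mode)
  cfg <- list(N = as.integer(N), f = f,
              eps_EE = eps_EE, eps_EI = eps_EI,
              eps_IE = eps_IE, eps_II = eps_II,
              J_exc = J_exc, g = g, J_inh = -g * J_exc, J_ffw = J_ffw,
              tau_m = tau_m, u_th = u_th, u_rest = u_rest,
              t_ref = t_ref, dt = dt,
              init_weight_mode = init_weight_mode,
              gaussian_classes = gaussian_classes)
  class(cfg) <- "balnet_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$N >= 2, cfg$f > 0, cfg$f < 1,
            cfg$J_exc > 0, cfg$J_inh < 0,
            cfg$tau_m > 0, cfg$dt > 0, cfg$t_ref >= 0)
  eps <- c(cfg$eps_EE, cfg$eps_EI, cfg$eps_IE, cfg$eps_II)
  if (any(eps < 0 | eps > 1))
    stop("connection probabilities must lie in [0, 1]")
  invisible(cfg)
}

#' Build a balanced random network
#'
#' Draws the random wiring and initial weights, assigns population labels and
#' input preferred orientations (POs). POs are uniformly spaced on
#' \[0, 180) degrees within each population and neurons are indexed in
#' ascending PO order, so connectivity matrices are directly comparable
#' across runs.
#'
#' @param config a [network_config()] object.
#' @param seed integer seed; the same seed yields bitwise-identical wiring.
#' @return an object of class `balnet_network` with elements `W` (N x N signed
#'   weight matrix in mV, entry `[j, i]` = synapse from presynaptic `j` to
#'   postsynaptic `i`), `mask` (0/1 existence matrix), `pop` (factor `"E"` /
#'   `"I"`), `PO` (degrees), and the originating `config`.
#' @export
build_network <- function(config, seed) {
  validate_config(config)
  set.seed(as.integer(seed))
  N <- config$N
  n_exc <- as.integer(round(config$f * N))
  n_inh <- N - n_exc
  if (n_exc < 1L || n_inh < 1L)
    stop("both populations must contain at least one neuron")
  pop <- c(rep("E", n_exc), rep("I", n_inh))
  PO <- c(seq(0, 180, length.out = n_exc + 1L)[seq_len(n_exc)],
          seq(0, 180, length.out = n_inh + 1L)[seq_len(n_inh)])

  is_e <- pop == "E"
  # out-connection probability by (presynaptic pop, postsynaptic pop)
  p_out <- matrix(c(config$eps_EE, config$eps_EI,
                    config$eps_IE, config$eps_II),
                  2, 2, byrow = TRUE)
  pre_idx <- ifelse(is_e, 1L, 2L)
  pmat <- p_out[pre_idx, pre_idx, drop = FALSE]  # N x N probabilities
  mask <- matrix(as.integer(matrix(stats::runif(N * N), N, N) < pmat), N, N)
  diag(mask) <- 0L

  W <- matrix(0, N, N)
  W[mask == 1L] <- ifelse(rep(is_e, times = N)[mask == 1L],
                          config$J_exc, config$J_inh)
  if (config$init_weight_mode == "gaussian") {
    post_e <- matrix(rep(is_e, each = N), N, N)
    cls_ok <- matrix(FALSE, N, N)
    if ("EE" %in% config$gaussian_classes) cls_ok <- cls_ok | post_e
    if ("EI" %in% config$gaussian_classes) cls_ok <- cls_ok | !post_e
    sel <- mask == 1L & rep(is_e, times = N) & cls_ok
    W[sel] <- pmax(0, stats::rnorm(sum(sel), config$J_exc, config$J_exc))
  }

  net <- list(W = W, mask = mask, pop = pop, PO = PO,
              n_exc = n_exc, n_inh = n_inh,
              config = config, seed = as.integer(seed))
  class(net) <- "balnet_network"
  net
}

#' @export
print.balnet_network <- function(x, ...) {
  cat("Balanced random network\n")
  cat(sprintf("  %d neurons (%d excitatory, %d inhibitory)\n",
              x$config$N, x$n_exc, x$n_inh))
  cat(sprintf("  %d synapses; J_exc = %g mV, J_inh = %g mV (g = %g)\n",
              sum(x$mask), x$config$J_exc, x$config$J_inh, x$config$g))
  cat(sprintf("  built with seed %d\n", x$seed))
  invisible(x)
}

# logical index matrices for a synapse class such as "EE", "IE" (pre, post)
class_mask <- function(net, pre, post) {
  is_e <- net$pop == "E"
  pre_ok <- if (pre == "E") is_e else !is_e
  post_ok <- if (post == "E") is_e else !is_e
  outer(pre_ok, post_ok) & net$mask == 1L
}
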
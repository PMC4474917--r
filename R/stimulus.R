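#' Feedforward input parameters
#'
#' The feedforward drive to every neuron is a single lumped Poisson channel
#' whose rate depends on the stimulus orientation `theta` and the neuron's
#' input preferred orientation `theta_star` as
#' `s(theta, theta_star) = s_b * (1 + mu * cos(2 * (theta - theta_star)))`,
#' with modulation depth `mu` set per target population (excitatory neurons
#' receive more sharply tuned input than inhibitory ones).
#'
#' @param s_b untuned baseline rate (kHz).
#' @param mu_exc relative modulation for excitatory targets.
#' @param mu_inh relative modulation for inhibitory targets.
#' @param J_ffw feedforward PSP amplitude (mV).
#' @return an object of class `balnet_input`.
#' @export
input_params <- function(s_b = 2.0, mu_exc = 0.20, mu_inh = 0.02,
                         J_ffw = 1.0) {
  stopifnot(s_b >= 0, mu_exc >= 0, mu_exc <= 1, mu_inh >= 0, mu_inh <= 1)
  p <- list(s_b = s_b, mu_exc = mu_exc, mu_inh = mu_inh, J_ffw = J_ffw)
  class(p) <- "balnet_input"
  p
}

#' Orientation-tuned input rate
#'
#' @param theta_deg stimulus orientation (degrees); `NA` denotes an untuned
#'   stimulus, for which the baseline is returned.
#' @param theta_star_deg preferred orientation of the target neuron (degrees).
#' @param params an [input_params()] object.
#' @param population `"E"` or `"I"`, selecting `mu_exc` or `mu_inh`.
#' @param baseline optional baseline override (kHz), e.g. `s_b / 2` for the
#'   spontaneous condition.
#' @return input rate in kHz (vectorised over `theta_star_deg`).
#' @export
input_rate <- function(theta_deg, theta_star_deg, params,
                       population = "E", baseline = NULL) {
  sb <- if (is.null(baseline)) params$s_b else baseline
  if (is.na(theta_deg)) return(rep(sb, length(theta_star_deg)))
  mu <- if (population == "E") params$mu_exc else params$mu_inh
  d <- (theta_deg - theta_star_deg) * pi / 180
  sb * (1 + mu * cos(2 * d))
}

#' Rescale input for an effective connectivity factor
#'
#' Emulates a `C`-fold denser feedforward convergence: the baseline rate is
#' scaled by `C`, the excitatory modulation depth by `1 / C` and the
#' feedforward PSP by `1 / C`, so the absolute modulation
#' `s_b * mu_exc * J_ffw` is invariant while the untuned component grows.
#' The inhibitory modulation depth is left unchanged.
#'
#' @param params an [input_params()] object.
#' @param C connectivity factor (>= 1).
#' @return a rescaled [input_params()] object.
#' @export
apply_connectivity_factor <- function(params, C) {
  stopifnot(C >= 1)
  input_params(s_b = params$s_b * C, mu_exc = params$mu_exc / C,
               mu_inh = params$mu_inh, J_ffw = params$J_ffw / C)
}

new_protocol <- function(segments, batch_ends, params) {
  stopifnot(all(segments$duration_ms > 0))
  proto <- list(segments = segments, batch_ends = as.integer(batch_ends),
                params = params)
  class(proto) <- "balnet_protocol"
  proto
}

#' Batched oriented-stimulus learning protocol
#'
#' Each batch is a random sequence of `n_orientations` stimuli (default 20
#' orientations equally spaced at 9 degrees), each shown for `stim_ms`.
#' Under uniform weights every batch is a random permutation of the
#' orientation set; under biased `orientation_weights` stimuli are drawn
#' i.i.d. from those weights.
#'
#' @param n_batches number of batches.
#' @param n_orientations number of distinct orientations (must divide 180).
#' @param stim_ms duration of each stimulus (ms).
#' @param orientation_weights optional probability per orientation, summing
#'   to 1; `NULL` for uniform permutations.
#' @param params an [input_params()] object.
#' @param seed integer seed for the stimulus sequence.
#' @return a `balnet_protocol` object.
#' @seealso [cardinal_weights()] for the cardinally biased statistics.
#' @export
make_learning_protocol <- function(n_batches, n_orientations = 20,
                                   stim_ms = 100, orientation_weights = NULL,
                                   params = input_params(), seed = 1) {
  thetas <- seq(0, 180, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  set.seed(as.integer(seed))
  seqs <- lapply(seq_len(n_batches), function(b) {
    if (is.null(orientation_weights)) {
      sample(thetas)
    } else {
      if (length(orientation_weights) != n_orientations ||
          abs(sum(orientation_weights) - 1) > 1e-8)
        stop("orientation_weights must be one probability per orientation, summing to 1")
      sample(thetas, n_orientations, replace = TRUE, prob = orientation_weights)
    }
  })
  theta <- unlist(seqs)
  segments <- data.frame(theta = theta,
                         duration_ms = stim_ms,
                         baseline = params$s_b,
                         tuned = TRUE)
  new_protocol(segments, seq_len(n_batches) * n_orientations, params)
}

#' Cardinally biased orientation weights
#'
#' Stimulus statistics in which the cardinal orientations 0 and 90 degrees
#' together make up 50% of all stimuli (25% each), the remaining probability
#' spread uniformly over the other orientations.
#'
#' @param n_orientations number of orientations (equally spaced at
#'   `180 / n_orientations` degrees; must include 0 and 90).
#' @return a probability vector usable as `orientation_weights`.
#' @export
cardinal_weights <- function(n_orientations = 20) {
  thetas <- seq(0, 180, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  cardinal <- thetas %in% c(0, 90)
  if (sum(cardinal) != 2L)
    stop("orientation grid must contain both 0 and 90 degrees")
  w <- rep(0.5 / (n_orientations - 2), n_orientations)
  w[cardinal] <- 0.25
  w
}

#' Tuning-curve probe protocol
#'
#' Probes the (frozen-weight) network with `n_orientations` orientations,
#' `n_trials` trials of `trial_ms` each, in orientation-major order (all
#' trials of the first orientation, then the second, ...).
#'
#' @param n_orientations number of probe orientations (default 8: 0, 22.5,
#'   ..., 157.5 degrees).
#' @param trial_ms trial duration (ms).
#' @param n_trials trials per orientation; with a single trial the
#'   trial-to-trial spread of the tuning curve is undefined.
#' @param params an [input_params()] object.
#' @return a `balnet_protocol` object with no batch boundaries.
#' @export
make_tuning_probe <- function(n_orientations = 8, trial_ms = 2000,
                              n_trials = 10, params = input_params()) {
  thetas <- seq(0, 180, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  segments <- data.frame(theta = rep(thetas, each = n_trials),
                         duration_ms = trial_ms,
                         baseline = params$s_b,
                         tuned = TRUE)
  new_protocol(segments, integer(0), params)
}

#' Untuned spontaneous-drive protocol
#'
#' Untuned background input at a reduced baseline (default `s_b / 2`,
#' `mu = 0`) for both populations; the batch structure (one 2 s segment per
#' batch, matching the duration of a learning batch) is preserved so weight
#' snapshots remain comparable.
#'
#' @param n_batches number of spontaneous batches.
#' @param params an [input_params()] object.
#' @param baseline_frac fraction of `s_b` used as the untuned rate; the
#'   default halves the baseline, use `1` for the variant driven at the full
#'   baseline.
#' @param batch_ms duration of one batch (ms).
#' @return a `balnet_protocol` object.
#' @export
make_spontaneous_protocol <- function(n_batches, params = input_params(),
                                      baseline_frac = 0.5, batch_ms = 2000) {
  segments <- data.frame(theta = NA_real_,
                         duration_ms = batch_ms,
                         baseline = params$s_b * baseline_frac,
                         tuned = FALSE)
  segments <- segments[rep(1L, n_batches), , drop = FALSE]
  rownames(segments) <- NULL
  new_protocol(segments, seq_len(n_batches), params)
}

#' @export
print.balnet_protocol <- function(x, ...) {
  n <- nrow(x$segments)
  cat(sprintf("Stimulation protocol: %d segments, %.1f s total, %d batch boundaries\n",
              n, sum(x$segments$duration_ms) / 1000, length(x$batch_ends)))
  invisible(x)
}

#' @export
as.data.frame.balnet_protocol <- function(x, ...) {
  data.frame(segment = seq_len(nrow(x$segments)), x$segments)
}

#' Total duration of a protocol in milliseconds
#' @param protocol a `balnet_protocol` object.
#' @export
protocol_duration_ms <- function(protocol) sum(protocol$segments$duration_ms)

# n_seg x N matrix of per-neuron feedforward rates (kHz)
protocol_rates <- function(protocol, network) {
  segs <- protocol$segments
  p <- protocol$params
  t(vapply(seq_len(nrow(segs)), function(s) {
    th <- segs$theta[s]
    if (!segs$tuned[s] || is.na(th)) {
      rep(segs$baseline[s], network$config$N)
    } else {
      mu <- ifelse(network$pop == "E", p$mu_exc, p$mu_inh)
      segs$baseline[s] *
        (1 + mu * cos(2 * (th - network$PO) * pi / 180))
    }
  }, numeric(network$config$N)))
}
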
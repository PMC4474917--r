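#' Orientation tuning curves from a probe simulation
#'
#' Per neuron and probed orientation, the mean and standard deviation over
#' trials of the firing rate (spike count divided by trial duration).
#'
#' @param sim a `balnet_sim` run under a [make_tuning_probe()] protocol.
#' @param probe the probe protocol (defaults to the protocol stored in
#'   `sim`).
#' @return an object of class `balnet_tuning`: list with `orientations`
#'   (degrees), `mean` and `sd` (orientation x neuron matrices, Hz), and
#'   `PO` (the input preferred orientation per neuron).
#' @export
tuning_curves <- function(sim, probe = sim$protocol) {
  segs <- probe$segments
  if (any(is.na(segs$theta))) stop("probe protocol must be fully tuned")
  thetas <- sort(unique(segs$theta))
  mean_m <- vapply(thetas, function(th) {
    colMeans(sim$rates[segs$theta == th, , drop = FALSE])
  }, numeric(ncol(sim$rates)))
  sd_m <- vapply(thetas, function(th) {
    r <- sim$rates[segs$theta == th, , drop = FALSE]
    if (nrow(r) < 2L) rep(NA_real_, ncol(r)) else apply(r, 2, stats::sd)
  }, numeric(ncol(sim$rates)))
  out <- list(orientations = thetas, mean = t(mean_m), sd = t(sd_m),
              PO = sim$network$PO, pop = sim$network$pop)
  class(out) <- "balnet_tuning"
  out
}

#' Orientation selectivity index (1 - circular variance)
#'
#' `OSI = |sum_k r_k exp(2 i theta_k)| / sum_k r_k` with orientations in
#' radians; 0 for a flat curve, 1 for a response confined to a single
#' orientation. For a curve `r(theta) = 1 + mu * cos(2(theta - PO))` sampled
#' densely, the OSI converges to `mu / 2`.
#'
#' @param rates non-negative response vector (or matrix, orientations in
#'   rows handled per column).
#' @param orientations_deg orientations in degrees.
#' @return the OSI in `[0, 1]`; `NA` for an all-zero curve.
#' @export
osi <- function(rates, orientations_deg) {
  f <- function(r) {
    s <- sum(r)
    if (!is.finite(s) || s <= 0) return(NA_real_)
    Mod(sum(r * exp(2i * orientations_deg * pi / 180))) / s
  }
  if (is.matrix(rates)) apply(rates, 2, f) else f(rates)
}

#' Per-neuron OSI distribution of a tuning set
#'
#' @param curves a [tuning_curves()] object.
#' @param population `"E"`, `"I"` or `"all"`.
#' @return named list with the OSI vector (`NA` for silent neurons,
#'   which are excluded from summaries) and the count of silent neurons.
#' @export
osi_distribution <- function(curves, population = "E") {
  sel <- switch(population, E = curves$pop == "E", I = curves$pop == "I",
                all = rep(TRUE, length(curves$pop)))
  v <- osi(curves$mean[, sel, drop = FALSE], curves$orientations)
  list(osi = v, n_silent = sum(is.na(v)), mean = mean(v, na.rm = TRUE))
}

#' Population-average tuning curve aligned to the input PO
#'
#' Shifts every neuron's tuning curve so that its input preferred
#' orientation maps to the centre (90 degrees) of a common axis, bins the
#' aligned samples (180 bins over \[0, 180)), and averages within bins.
#'
#' @param curves a [tuning_curves()] object.
#' @param population `"E"`, `"I"` or `"all"`.
#' @param n_bins number of bins over the aligned axis.
#' @return list with `bin_deg` (bin centres), `mean`, `sd` per bin, and the
#'   `osi` of the binned mean curve.
#' @export
population_average_tuning <- function(curves, population = "E",
                                      n_bins = 180) {
  sel <- which(switch(population, E = curves$pop == "E",
                      I = curves$pop == "I",
                      all = rep(TRUE, length(curves$pop))))
  aligned_th <- c(outer(curves$orientations, curves$PO[sel],
                        function(th, po) (th - po + 90) %% 180))
  vals <- c(curves$mean[, sel, drop = FALSE])
  bin <- pmin(floor(aligned_th / (180 / n_bins)) + 1L, n_bins)
  m <- tapply(vals, factor(bin, levels = seq_len(n_bins)), mean)
  s <- tapply(vals, factor(bin, levels = seq_len(n_bins)), stats::sd)
  centers <- (seq_len(n_bins) - 0.5) * 180 / n_bins
  ok <- !is.na(m)
  list(bin_deg = centers, mean = as.numeric(m), sd = as.numeric(s),
       osi = osi(as.numeric(m[ok]), centers[ok]))
}

#' Membrane-potential tuning with free-potential correction
#'
#' Per probed orientation, the time-averaged membrane potential of a
#' recorded neuron and its reset-corrected free value
#' `u_free = <u> + tau_m * u_th * r` (`tau_m` in seconds, `r` the mean rate
#' in Hz), which adds back the average potential removed by spike resets.
#'
#' @param sim a `balnet_sim` run with `record_v` set.
#' @param neuron id of the neuron (must be among `sim$record_v`).
#' @return list with `orientations`, `u_mean` and `u_free` (mV per
#'   orientation).
#' @export
membrane_tuning <- function(sim, neuron) {
  k <- match(neuron, sim$record_v)
  if (is.na(k)) stop("neuron was not recorded; pass it via record_v")
  segs <- sim$protocol$segments
  thetas <- sort(unique(segs$theta))
  steps <- as.integer(round(segs$duration_ms / sim$dt))
  seg_of_step <- rep(seq_len(nrow(segs)), steps)
  u_seg <- tapply(sim$v[, k], seg_of_step, mean)
  u_mean <- vapply(thetas, function(th) mean(u_seg[segs$theta == th]),
                   numeric(1))
  r <- vapply(thetas, function(th) mean(sim$rates[segs$theta == th, neuron]),
              numeric(1))
  cfg <- sim$network$config
  list(orientations = thetas, u_mean = u_mean,
       u_free = u_mean + (cfg$tau_m / 1000) * cfg$u_th * r, rate = r)
}

circ_dpo <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Weight tuning versus preferred-orientation difference
#'
#' Collects the existing synapses of one class, computes the circular
#' difference in preferred orientation (dPO, in \[0, 90\] degrees) of each
#' pre/post pair, the mean weight magnitude in the three canonical groups
#' (similar dPO < 30, indifferent 30-60, dissimilar > 60 degrees), and the
#' selectivity (OSI) of the binned mean-magnitude-versus-dPO profile, with
#' the dPO axis mirrored onto \[0, 180) so the circular-variance formula
#' applies unchanged.
#'
#' @param W weight matrix (`[j, i]` = presynaptic j to postsynaptic i).
#' @param network the `balnet_network` the matrix belongs to (supplies POs,
#'   population labels and the existence mask).
#' @param pre,post presynaptic and postsynaptic population (`"E"` or `"I"`).
#' @param n_bins number of dPO bins for the tuning profile.
#' @return an object of class `balnet_dpo`: list with the per-synapse table
#'   (`dpo`, `weight`), `group_means` (length 3), the binned profile
#'   (`bin_deg`, `bin_mean`) and `weight_tuning_osi`.
#' @export
weight_vs_dpo <- function(W, network, pre = "E", post = "E", n_bins = 18) {
  cm <- class_mask(network, pre, post)
  idx <- which(cm, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(structure(list(synapses = NULL, group_means = rep(NA_real_, 3),
                          weight_tuning_osi = NA_real_),
                     class = "balnet_dpo"))
  }
  dpo <- circ_dpo(network$PO[idx[, 1]], network$PO[idx[, 2]])
  w <- abs(W[cm])
  groups <- cut(dpo, breaks = c(-1, 30, 60, 91),
                labels = c("similar", "indifferent", "dissimilar"))
  gm <- tapply(w, groups, mean)
  bin <- pmin(floor(dpo / (90 / n_bins)) + 1L, n_bins)
  bm <- tapply(w, factor(bin, levels = seq_len(n_bins)), mean)
  centers <- (seq_len(n_bins) - 0.5) * 90 / n_bins
  ok <- !is.na(bm)
  # mirror the [0, 90] profile to [0, 180): m(180 - x) = m(x)
  prof_th <- c(centers[ok], 180 - centers[ok])
  prof_w <- c(bm[ok], bm[ok])
  out <- list(synapses = data.frame(dpo = dpo, weight = w),
              group_means = as.numeric(gm),
              bin_deg = centers, bin_mean = as.numeric(bm),
              weight_tuning_osi = osi(prof_w, prof_th))
  class(out) <- "balnet_dpo"
  out
}

#' @export
print.balnet_dpo <- function(x, ...) {
  cat("Weight vs. dPO report\n")
  cat(sprintf("  group means (mV): similar %.4f | indifferent %.4f | dissimilar %.4f\n",
              x$group_means[1], x$group_means[2], x$group_means[3]))
  cat(sprintf("  weight-tuning OSI: %.4f\n", x$weight_tuning_osi))
  invisible(x)
}

#' Weighted bidirectionality index
#'
#' Mean over unordered neuron pairs of the product of reciprocal weight
#' magnitudes `|w_ij| * |w_ji|`. A purely unidirectional network scores 0;
#' the more weight sits on reciprocal pairs, the larger the index.
#'
#' @param W weight matrix.
#' @param network the owning `balnet_network` (for the pair scope).
#' @param scope `"EE"` restricts to excitatory-excitatory pairs (the
#'   default); `"all"` uses every pair.
#' @return the WBI (mean reciprocal product over all in-scope unordered
#'   pairs, connected or not).
#' @export
wbi <- function(W, network = NULL, scope = c("EE", "all")) {
  scope <- match.arg(scope)
  M <- abs(W)
  if (scope == "EE") {
    stopifnot(!is.null(network))
    e <- network$pop == "E"
    M <- M[e, e, drop = FALSE]
  }
  n <- nrow(M)
  if (n < 2L) return(0)
  P <- M * t(M)
  (sum(P) - sum(diag(P))) / (n * (n - 1))
}

#' Shuffle-normalised weighted bidirectionality index
#'
#' Divides the WBI of the weight matrix by the average WBI of surrogate
#' matrices in which the non-zero entries of the in-scope block are
#' permuted uniformly over all off-diagonal positions (preserving the
#' weight multiset). A value of 1 indicates chance-level bidirectionality.
#'
#' @inheritParams wbi
#' @param n_shuffles number of surrogates.
#' @param seed integer seed for the shuffles.
#' @return `WBI / mean(WBI_shuffled)`; `NA` if the block carries no weight.
#' @export
wbi_norm <- function(W, network = NULL, scope = c("EE", "all"),
                     n_shuffles = 100, seed = 1) {
  scope <- match.arg(scope)
  M <- abs(W)
  if (scope == "EE") {
    stopifnot(!is.null(network))
    e <- network$pop == "E"
    M <- M[e, e, drop = FALSE]
  }
  n <- nrow(M)
  off <- which(row(M) != col(M))
  vals <- M[off]
  nz <- vals[vals > 0]
  if (length(nz) == 0L) return(NA_real_)
  pair_mean <- function(A) {
    P <- A * t(A)
    (sum(P) - sum(diag(P))) / (n * (n - 1))
  }
  w0 <- pair_mean(M)
  set.seed(as.integer(seed))
  ws <- vapply(seq_len(n_shuffles), function(s) {
    A <- matrix(0, n, n)
    A[sample(off, length(nz))] <- nz
    pair_mean(A)
  }, numeric(1))
  w0 / mean(ws)
}

#' Weight evolution across batch snapshots
#'
#' Per batch and synapse class, the mean absolute weight change of existing
#' synapses between consecutive snapshots, plus per-batch weight histograms
#' over fixed bin edges.
#'
#' @param sim a `balnet_sim` with recorded snapshots (or a list of weight
#'   matrices via `snapshots`).
#' @param network owning network (defaults to `sim$network`).
#' @param snapshots list of weight matrices; defaults to `sim$snapshots`.
#' @param classes synapse classes to report, as pre/post pairs.
#' @param breaks histogram bin edges (mV, applied to weight magnitudes).
#' @return list with `delta` (batch x class matrix of mean |dw|) and
#'   `histograms` (class-named list of bins x batch count matrices).
#' @export
weight_evolution <- function(sim, network = sim$network,
                             snapshots = sim$snapshots,
                             classes = list(c("E", "E"), c("E", "I"),
                                            c("I", "E")),
                             breaks = seq(0, 5, by = 0.1)) {
  if (length(snapshots) < 2L) stop("need at least two snapshots")
  cls_names <- vapply(classes, paste0, character(1), collapse = "")
  masks <- lapply(classes, function(cl) class_mask(network, cl[1], cl[2]))
  n_b <- length(snapshots) - 1L
  delta <- matrix(NA_real_, n_b, length(classes),
                  dimnames = list(NULL, cls_names))
  hists <- lapply(masks, function(m) {
    matrix(0L, length(breaks) - 1L, length(snapshots))
  })
  names(hists) <- cls_names
  for (k in seq_along(snapshots)) {
    for (c in seq_along(classes)) {
      w <- pmin(abs(snapshots[[k]][masks[[c]]]), max(breaks))
      hists[[c]][, k] <- hist(w, breaks = breaks, plot = FALSE)$counts
      if (k > 1L) {
        dw <- abs(snapshots[[k]][masks[[c]]] - snapshots[[k - 1L]][masks[[c]]])
        delta[k - 1L, c] <- mean(dw)
      }
    }
  }
  list(delta = delta, histograms = hists, breaks = breaks)
}
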
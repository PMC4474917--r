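#' Spike raster of a simulation
#'
#' Excitatory spikes in red, inhibitory in blue; neurons are already sorted
#' by preferred orientation within each population.
#'
#' @param x a `balnet_sim` with recorded spikes.
#' @param t_range optional time window (ms).
#' @param ... passed to [plot()].
#' @export
plot.balnet_sim <- function(x, t_range = NULL, ...) {
  sp <- x$spikes
  if (nrow(sp) == 0L) stop("no recorded spikes")
  if (!is.null(t_range))
    sp <- sp[sp$time_ms >= t_range[1] & sp$time_ms <= t_range[2], ]
  col <- ifelse(x$network$pop[sp$neuron] == "E", "firebrick", "royalblue")
  plot(sp$time_ms, sp$neuron, pch = ".", col = col,
       xlab = "time (ms)", ylab = "neuron (sorted by PO)", ...)
  invisible(x)
}

#' Tuning curve of a single neuron
#'
#' @param x a `balnet_tuning` object.
#' @param neuron neuron id.
#' @param add overlay on an existing plot.
#' @param col line colour.
#' @param ... passed to [plot()].
#' @export
plot.balnet_tuning <- function(x, neuron = 1, add = FALSE,
                               col = "black", ...) {
  th <- x$orientations
  m <- x$mean[, neuron]
  if (!add) {
    plot(th, m, type = "o", col = col, xlab = "orientation (deg)",
         ylab = "rate (Hz)", ...)
  } else {
    lines(th, m, type = "o", col = col)
  }
  invisible(x)
}

#' Weight-versus-dPO scatter with group means
#'
#' @param x a `balnet_dpo` report.
#' @param ... passed to [plot()].
#' @export
plot.balnet_dpo <- function(x, ...) {
  if (is.null(x$synapses)) stop("empty synapse class")
  plot(x$synapses$dpo, x$synapses$weight, pch = ".",
       xlab = "dPO (deg)", ylab = "|weight| (mV)", ...)
  lines(x$bin_deg, x$bin_mean, col = "firebrick", lwd = 2)
  invisible(x)
}
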
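# Plain-text artifact writers. All artifacts embed the seed and a cheap
# configuration checksum so runs can be diffed and audited.

config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Write spike events as delimited text
#'
#' Two columns (`time_ms`, `neuron`), preceded by comment lines carrying the
#' seed and a configuration checksum.
#'
#' @param sim a `balnet_sim` with recorded spikes.
#' @param path output file.
#' @export
write_spikes <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed: %d", sim$seed),
               sprintf("# config: %s", config_hash(sim$network$config))),
             con)
  utils::write.table(sim$spikes, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a protocol schedule as delimited text
#'
#' @param protocol a `balnet_protocol`.
#' @param path output file.
#' @export
write_protocol <- function(protocol, path) {
  df <- as.data.frame(protocol)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write weight snapshots to an array container
#'
#' Stores the snapshots as a named list (`W_init`, `W_batch_1`, ...) in an
#' RDS container.
#'
#' @param sim a `balnet_sim` with recorded snapshots.
#' @param path output file (`.rds`).
#' @export
write_snapshots <- function(sim, path) {
  snaps <- sim$snapshots
  names(snaps) <- c("W_init",
                    if (length(snaps) > 1L)
                      paste0("W_batch_", seq_len(length(snaps) - 1L)))
  saveRDS(snaps, path)
  invisible(path)
}

#' Write or read an experiment configuration as structured text
#'
#' Serialises a preset (network, plasticity and input parameters plus
#' protocol settings) to YAML, field for field, so runs can be configured
#' and audited outside R.
#'
#' @param spec a preset list (see [preset()]).
#' @param path output file.
#' @export
write_config <- function(spec, path) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (inherits(v, c("balnet_vogels"))) unclass(v)
           else v)
  }
  out <- list(name = spec$name,
              network = unclass(spec$network),
              plasticity = strip(spec$plasticity),
              input = unclass(spec$input),
              protocol = list(
                n_learning_batches = spec$n_learning_batches,
                n_spont_batches = spec$n_spont_batches,
                spont_frac = spec$spont_frac,
                orientation_weights = spec$orientation_weights),
              sweep = spec$sweep)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @return `read_config()` returns a preset list reconstructed from the
#'   file, with validated parameter objects.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  net <- raw$network
  plast <- raw$plasticity
  spec <- list(
    network = do.call(network_config, net[setdiff(names(net), "J_inh")]),
    plasticity = do.call(plasticity_params, c(
      plast[setdiff(names(plast), c("A_LTP_exc", "A_LTP_inh", "vogels"))],
      list(A_LTP_exc = plast$A_LTP_exc, A_LTP_inh = plast$A_LTP_inh,
           vogels = do.call(vogels_params, plast$vogels)))),
    input = do.call(input_params, raw$input),
    n_learning_batches = raw$protocol$n_learning_batches,
    n_spont_batches = raw$protocol$n_spont_batches,
    spont_frac = raw$protocol$spont_frac,
    orientation_weights = raw$protocol$orientation_weights,
    sweep = raw$sweep,
    name = raw$name)
  spec
}

#' Write a flat key-value metric report
#'
#' @param metrics named numeric vector or list.
#' @param path output file.
#' @param seed seed to embed in the header.
#' @export
write_report <- function(metrics, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  m <- unlist(metrics)
  writeLines(sprintf("%s\t%.10g", names(m), m), con)
  invisible(path)
}
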
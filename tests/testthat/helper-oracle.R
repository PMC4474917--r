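# Independent reference implementations used as oracles. The scalar
# simulator below re-implements the documented update scheme in plain R
# loops, entirely separately from the compiled core, and is only ever run
# on tiny networks.

lif_interval <- function(u_inf, u_th, tau_m) {
  # closed-form inter-spike interval of a LIF neuron under constant current
  if (u_inf <= u_th) return(Inf)
  tau_m * log(u_inf / (u_inf - u_th))
}

reference_sim <- function(net, protocol, plasticity = NULL, seed,
                          dt = net$config$dt, poisson = TRUE) {
  cfg <- net$config
  N <- cfg$N
  W <- net$W
  mask <- net$mask
  pop_i <- net$pop == "I"
  rates <- balnet:::protocol_rates(protocol, net)
  segs <- protocol$segments
  steps <- as.integer(round(segs$duration_ms / dt))
  p <- balnet:::plasticity_to_core(plasticity)
  plastic <- !is.null(p)

  dm <- exp(-dt / cfg$tau_m)
  if (plastic) {
    dum <- exp(-dt / p$tau_minus); dup <- exp(-dt / p$tau_plus)
    dx <- exp(-dt / p$tau_x); xi <- 1 / p$tau_x
    L <- max(1L, as.integer(round(p$homeo_ms / dt)))
    buf <- matrix(0, N, L); hsum <- numeric(N); pos <- 1L
    # plastic adjacency
    plast_cls <- outer(!pop_i, !pop_i | pop_i) & mask == 1L  # E -> anything
    ie_cls <- outer(pop_i, !pop_i) & mask == 1L              # I -> E
    diag(plast_cls) <- FALSE; diag(ie_cls) <- FALSE
    volt_cls <- plast_cls | (if (p$rule_ie == 0L) ie_cls else
                             matrix(FALSE, N, N))
  }
  u <- rep(cfg$u_rest, N)
  um <- up <- xbar <- ubb <- numeric(N)
  pending <- numeric(N)
  refrac <- integer(N)
  ref_steps <- as.integer(round(cfg$t_ref / dt))
  spk_t <- numeric(0); spk_id <- integer(0)
  counts <- matrix(0L, nrow(segs), N)

  set.seed(as.integer(seed))
  step <- 0L
  for (s in seq_len(nrow(segs))) {
    lam <- rates[s, ] * dt
    for (tt in seq_len(steps[s])) {
      step <- step + 1L
      for (k in seq_len(N)) {
        ff <- 0
        if (lam[k] > 0)
          ff <- (if (poisson) stats::rpois(1, lam[k]) else lam[k]) * cfg$J_ffw
        if (refrac[k] > 0L) {
          u[k] <- cfg$u_rest; refrac[k] <- refrac[k] - 1L
        } else {
          u[k] <- u[k] * dm + pending[k] + ff
        }
      }
      spikers <- which(refrac == 0L & u >= cfg$u_th)
      if (plastic) {
        ue <- pmin(u, cfg$u_th)
        um <- ue + (um - ue) * dum
        up <- ue + (up - ue) * dup
        if (p$homeo_mode == 0L) {
          hsum <- hsum + ue - buf[, pos]; buf[, pos] <- ue
          ubb <- hsum / L
          pos <- pos %% L + 1L
        } else {
          ubb <- ue + (ubb - ue) * exp(-dt / p$homeo_ms)
        }
        xbar <- xbar * dx
        xbar[spikers] <- xbar[spikers] + xi
        for (j in spikers) {   # depression jumps
          for (i in which(volt_cls[j, ])) {
            d <- um[i] - p$theta_minus
            if (d <= 0) next
            amp <- p$a_ltd * (ubb[i]^2 / p$u_ref_sq) * d
            W[j, i] <- if (!pop_i[j]) max(W[j, i] - amp, 0)
                       else min(W[j, i] + amp, 0)
          }
        }
        for (i in seq_len(N)) {  # potentiation
          g1 <- ue[i] - p$theta_plus
          if (g1 <= 0) next
          g2 <- up[i] - p$theta_minus
          if (g2 <= 0) next
          base <- dt * g1 * g2
          be <- p$a_ltp_exc * base; bi <- p$a_ltp_inh * base
          for (j in which(volt_cls[, i])) {
            if (!pop_i[j]) W[j, i] <- min(W[j, i] + be * xbar[j], p$wmax_e)
            else W[j, i] <- max(W[j, i] - bi * xbar[j], -p$wmax_i)
          }
        }
        if (p$rule_ie == 1L) {
          for (k in spikers) {
            if (pop_i[k]) {
              for (i in which(ie_cls[k, ])) {
                m <- -W[k, i] + p$eta * (xbar[i] - p$alpha)
                W[k, i] <- -min(max(m, 0), p$wmax_i)
              }
            } else {
              for (j in which(ie_cls[, k])) {
                m <- -W[j, k] + p$eta * xbar[j]
                W[j, k] <- -min(max(m, 0), p$wmax_i)
              }
            }
          }
        }
      }
      pend_next <- numeric(N)
      for (j in spikers) pend_next <- pend_next + W[j, ]
      pending <- pend_next
      for (j in spikers) {
        spk_t <- c(spk_t, step * dt); spk_id <- c(spk_id, j)
        counts[s, j] <- counts[s, j] + 1L
        u[j] <- cfg$u_rest
        refrac[j] <- ref_steps
      }
    }
  }
  list(W = W, spikes = data.frame(time_ms = spk_t, neuron = spk_id),
       counts = counts)
}

# small fully-specified network for scripted tests
tiny_network <- function(N = 6, f = 2 / 3, seed = 1, g = 8, J_exc = 0.5,
                         eps = 1) {
  build_network(network_config(N = N, f = f, eps_EE = eps, eps_EI = eps,
                               eps_IE = eps, eps_II = eps,
                               J_exc = J_exc, g = g), seed = seed)
}
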
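# helpers to fabricate sim/tuning objects for metric tests

fake_probe_sim <- function(rate_fun, n_trials = 10, trial_s = 2,
                           thetas = seq(0, 157.5, by = 22.5), seed = 1,
                           N = 30) {
  net <- build_network(network_config(N = N), seed = 1)
  proto <- make_tuning_probe(n_orientations = length(thetas),
                             trial_ms = trial_s * 1000, n_trials = n_trials)
  set.seed(seed)
  segs <- proto$segments
  counts <- t(vapply(seq_len(nrow(segs)), function(s) {
    stats::rpois(N, rate_fun(segs$theta[s], net$PO) * trial_s)
  }, numeric(N)))
  sim <- list(rates = counts / trial_s, network = net, protocol = proto,
              dt = 1)
  class(sim) <- "balnet_sim"
  sim
}

test_that("tuning curves recover Poisson rates and are trial-order invariant", {
  lam <- function(th, po) 10 + 5 * cos(2 * (th - po) * pi / 180)
  sim <- fake_probe_sim(lam, n_trials = 50)
  tc <- tuning_curves(sim)
  truth <- outer(tc$orientations, sim$network$PO, lam)
  # CLT error for 50 trials of Poisson(lambda * 2s)
  se <- sqrt(truth / 2 / 50)
  expect_true(all(abs(tc$mean - truth) < 5 * se))
  # permuting trials leaves mean and sd unchanged
  sim2 <- sim
  perm <- as.vector(matrix(seq_len(nrow(sim$rates)), nrow = 50)[sample(50), ])
  stopifnot(all(sim$protocol$segments$theta ==
                  sim$protocol$segments$theta[perm]))
  sim2$rates <- sim$rates[perm, ]
  tc2 <- tuning_curves(sim2)
  expect_equal(tc2$mean, tc$mean)
  expect_equal(tc2$sd, tc$sd)
})

test_that("a flat curve has zero trial spread and the right mean", {
  sim <- fake_probe_sim(function(th, po) rep(10, length(po)))
  sim$rates[] <- 10
  tc <- tuning_curves(sim)
  expect_true(all(tc$mean == 10))
  expect_true(all(tc$sd == 0))
})

test_that("the selectivity index matches its closed forms", {
  th8 <- seq(0, 157.5, by = 22.5)
  expect_equal(osi(rep(3, 8), th8), 0)
  one <- rep(0, 8); one[3] <- 7
  expect_equal(osi(one, th8), 1)
  # dense cosine curve: OSI converges to mu / 2
  thd <- seq(0, 179.9, by = 0.1)
  for (mu in c(0.2, 0.6, 1)) {
    r <- 1 + mu * cos(2 * (thd - 35) * pi / 180)
    expect_equal(osi(r, thd), mu / 2, tolerance = 1e-6)
  }
  expect_true(is.na(osi(rep(0, 8), th8)))
  # range and scale invariance over random curves
  set.seed(1)
  for (k in 1:25) {
    r <- stats::runif(8)
    v <- osi(r, th8)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(osi(10 * r, th8), v)
  }
})

test_that("population-aligned averaging is PO-shift equivariant", {
  lam <- function(th, po) 8 + 4 * cos(2 * (th - po) * pi / 180)
  sim <- fake_probe_sim(lam, n_trials = 20)
  tc <- tuning_curves(sim)
  pa <- population_average_tuning(tc)
  # identical tuning shapes aligned: spread within a bin is zero
  tc0 <- tc
  tc0$mean <- outer(tc$orientations, tc$PO, lam)
  pa0 <- population_average_tuning(tc0)
  expect_true(all(pa0$sd[!is.na(pa0$sd)] < 1e-9))
  peak <- pa0$bin_deg[which.max(pa0$mean)]
  expect_lt(abs(peak - 90), 3)
  # shifting all POs and stimulus labels together changes nothing
  tc_shift <- tc0
  tc_shift$PO <- (tc0$PO + 45) %% 180
  tc_shift$mean <- outer(tc0$orientations, tc_shift$PO, lam)
  pa_shift <- population_average_tuning(tc_shift)
  expect_equal(pa_shift$osi, pa0$osi, tolerance = 1e-6)
  # flat curves give a flat average with zero OSI
  tcf <- tc0
  tcf$mean[] <- 5
  paf <- population_average_tuning(tcf)
  expect_true(all(abs(paf$mean - 5) < 1e-9, na.rm = TRUE))
  expect_equal(paf$osi, 0, tolerance = 1e-12)
})

test_that("membrane tuning applies the reset correction", {
  net <- build_network(network_config(N = 20), seed = 1)
  proto <- make_tuning_probe(n_orientations = 4, trial_ms = 100, n_trials = 2)
  sim <- list(v = matrix(6, 800, 1), rates = matrix(10, 8, 20),
              network = net, protocol = proto, record_v = 5L, dt = 1)
  class(sim) <- "balnet_sim"
  mt <- membrane_tuning(sim, 5L)
  expect_equal(mt$u_mean, rep(6, 4))
  # correction tau_m * u_th * r = 0.020 s * 20 mV * 10 Hz = 4 mV
  expect_equal(mt$u_free, rep(10, 4))
  # no spiking: free equals actual
  sim$rates[] <- 0
  expect_equal(membrane_tuning(sim, 5L)$u_free, rep(6, 4))
  # correction increases with rate
  sim$rates[] <- 20
  expect_equal(membrane_tuning(sim, 5L)$u_free, rep(14, 4))
  expect_error(membrane_tuning(sim, 6L), "not recorded")
})

test_that("weight-vs-dPO groups separate structured from unstructured weights", {
  net <- build_network(network_config(N = 200), seed = 6)
  rep0 <- weight_vs_dpo(net$W, net)
  expect_equal(rep0$group_means, rep(0.5, 3))
  expect_lt(rep0$weight_tuning_osi, 0.02)  # flat profile
  # cosine-squared weight structure: strictly decreasing group means
  Wc <- net$W
  ee <- balnet:::class_mask(net, "E", "E")
  idx <- which(ee, arr.ind = TRUE)
  d <- (net$PO[idx[, 1]] - net$PO[idx[, 2]]) * pi / 180
  Wc[ee] <- cos(d)^2
  repc <- weight_vs_dpo(Wc, net)
  expect_gt(repc$group_means[1], repc$group_means[2])
  expect_gt(repc$group_means[2], repc$group_means[3])
  expect_gt(repc$weight_tuning_osi, 0.2)
  # dPO is symmetric in pre/post
  expect_equal(balnet:::circ_dpo(10, 170), balnet:::circ_dpo(170, 10))
  expect_equal(balnet:::circ_dpo(10, 170), 20)
  expect_true(all(rep0$synapses$dpo >= 0 & rep0$synapses$dpo <= 90))
})

test_that("the bidirectionality index behaves per its definition", {
  net <- build_network(network_config(N = 100), seed = 3)
  is_e <- net$pop == "E"
  ne <- sum(is_e)
  # strictly unidirectional: upper-triangular weights only
  Wu <- net$W
  Wu[lower.tri(Wu)] <- 0
  expect_equal(wbi(Wu, net), 0)
  # fully symmetric unit weights on existing reciprocal pairs
  Ws <- matrix(0, net$config$N, net$config$N)
  sym <- net$mask == 1L & t(net$mask) == 1L
  Ws[sym] <- 1
  frac <- (sum(sym[is_e, is_e]) / 2) / (ne * (ne - 1) / 2)
  expect_equal(wbi(Ws, net), frac)
  # chance level: over random wiring draws at full size the normalised
  # index averages 1 (individual draws fluctuate with pair-sampling noise)
  vals <- vapply(1:3, function(s) {
    netf <- build_network(network_config(), seed = s)
    wbi_norm(netf$W, netf, n_shuffles = 100, seed = s)
  }, numeric(1))
  expect_gt(mean(vals), 0.95)
  expect_lt(mean(vals), 1.05)
  expect_true(is.na(wbi_norm(matrix(0, 10, 10), scope = "all")))
})

test_that("weight evolution reports per-class mean changes and histograms", {
  net <- build_network(network_config(N = 60), seed = 2)
  ee <- balnet:::class_mask(net, "E", "E")
  W2 <- net$W
  pos <- which(ee)[1]
  W2[pos] <- W2[pos] + 0.1
  ev <- weight_evolution(snapshots = list(net$W, net$W, W2), network = net)
  expect_equal(unname(ev$delta[1, ]), c(0, 0, 0))
  expect_equal(unname(ev$delta[2, ]), c(0.1 / sum(ee), 0, 0))
  expect_equal(colSums(ev$histograms$EE), rep(sum(ee), 3),
               ignore_attr = TRUE)
  expect_error(weight_evolution(snapshots = list(net$W), network = net),
               "two snapshots")
  # consistent relabeling leaves the class means unchanged
  perm <- c(sample(which(net$pop == "E")), sample(which(net$pop == "I")))
  netp <- net
  netp$W <- net$W[perm, perm]
  netp$mask <- net$mask[perm, perm]
  W2p <- W2[perm, perm]
  evp <- weight_evolution(snapshots = list(netp$W, W2p), network = netp)
  expect_equal(evp$delta[1, ], ev$delta[2, ])
})
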
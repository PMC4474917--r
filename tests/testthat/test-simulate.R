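# closed-form and contract tests of the integrator

quiet_protocol <- function(ms) {
  make_spontaneous_protocol(1, input_params(s_b = 0), batch_ms = ms)
}

test_that("membrane decay follows the exact exponential", {
  net <- build_network(network_config(N = 10, eps_EE = 0, eps_EI = 0,
                                      eps_IE = 0, eps_II = 0), seed = 1)
  sim <- simulate_network(net, quiet_protocol(20), NULL, seed = 1,
                          record_v = 1L, u0 = 10)
  expect_equal(sim$v[1, 1], 10 * exp(-1 / 20), tolerance = 1e-12)
  # after one membrane time constant: u = 10 / e
  expect_equal(sim$v[20, 1], 10 * exp(-1), tolerance = 1e-12)
  expect_equal(nrow(sim$spikes), 0L)
})

test_that("inter-spike interval under constant drive matches the LIF closed form", {
  cfg <- network_config(N = 10, eps_EE = 0, eps_EI = 0, eps_IE = 0,
                        eps_II = 0, dt = 0.1)
  net <- build_network(cfg, seed = 1)
  proto <- make_spontaneous_protocol(1, input_params(s_b = 2),
                                     baseline_frac = 1, batch_ms = 200)
  sim <- simulate_network(net, proto, NULL, seed = 1,
                          input = "deterministic")
  u_inf <- 2 * 1 * cfg$tau_m  # rate (kHz) x J_ffw (mV) x tau_m (ms)
  T_ref <- lif_interval(u_inf, cfg$u_th, cfg$tau_m)
  isi <- diff(sim$spikes$time_ms[sim$spikes$neuron == 1])
  expect_gt(length(isi), 5)
  expect_true(all(abs(isi - T_ref) <= cfg$dt + 1e-9))
})

test_that("without plasticity the weights are frozen", {
  net <- build_network(network_config(N = 80), seed = 2)
  proto <- make_learning_protocol(2, seed = 3)
  sim <- simulate_network(net, proto, NULL, seed = 4)
  expect_identical(sim$W_final, net$W)
  expect_length(sim$snapshots, 3L)  # batches + 1
  for (s in sim$snapshots) expect_identical(s, net$W)
})

test_that("identical seeds reproduce spike lists exactly", {
  net <- build_network(network_config(N = 100), seed = 5)
  proto <- make_learning_protocol(1, seed = 6)
  a <- simulate_network(net, proto, plasticity_params(), seed = 11)
  b <- simulate_network(net, proto, plasticity_params(), seed = 11)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$W_final, b$W_final)
  c <- simulate_network(net, proto, plasticity_params(), seed = 12)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("zero-amplitude plasticity is bitwise identical to frozen weights", {
  net <- build_network(network_config(N = 100), seed = 5)
  proto <- make_learning_protocol(1, seed = 6)
  p0 <- plasticity_params(A_LTD = 0, A_LTP = 0, rule_IE = "frozen")
  a <- simulate_network(net, proto, p0, seed = 11)
  b <- simulate_network(net, proto, NULL, seed = 11)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$W_final, b$W_final)
})

test_that("halving the time step changes population rates by less than 10%", {
  net <- build_network(network_config(), seed = 42)
  proto <- make_learning_protocol(1, seed = 7)
  r1 <- mean_rate(simulate_network(net, proto, NULL, seed = 1,
                                   record_spikes = FALSE), "E")
  r01 <- mean_rate(simulate_network(net, proto, NULL, seed = 1, dt = 0.1,
                                    record_spikes = FALSE), "E")
  expect_lt(abs(r1 - r01) / r1, 0.10)
})

test_that("evoked excitatory neurons stay on average below threshold", {
  net <- build_network(network_config(), seed = 42)
  proto <- make_learning_protocol(1, seed = 7)
  ids <- c(10L, 100L, 200L, 300L)
  sim <- simulate_network(net, proto, NULL, seed = 1, record_v = ids,
                          record_spikes = FALSE)
  expect_true(all(colMeans(sim$v) < net$config$u_th))
  expect_true(all(colMeans(sim$v) > net$config$u_rest))
})

test_that("plasticity respects structure: absent synapses stay absent, bounds hold", {
  net <- build_network(network_config(N = 120), seed = 9)
  # adversarially strong drive
  proto <- make_spontaneous_protocol(2, input_params(s_b = 10))
  sim <- simulate_network(net, proto, plasticity_params(), seed = 10,
                          record_spikes = FALSE)
  W <- sim$W_final
  is_e <- net$pop == "E"
  expect_true(all(W[net$mask == 0L] == 0))
  expect_true(all(W[is_e, ] >= 0 & W[is_e, ] <= 2))
  expect_true(all(W[!is_e, ] <= 0 & W[!is_e, ] >= -5))
  # I->I untouched
  ii <- balnet:::class_mask(net, "I", "I")
  expect_identical(W[ii], net$W[ii])
})

test_that("segment durations must be integer multiples of the step", {
  net <- build_network(network_config(N = 20), seed = 1)
  proto <- make_spontaneous_protocol(1, batch_ms = 100.5)
  expect_error(simulate_network(net, proto, NULL, seed = 1), "multiples")
})

test_that("compiled core agrees with the scalar reference implementation", {
  net <- tiny_network(N = 6, seed = 3)
  proto <- make_learning_protocol(1, n_orientations = 4, stim_ms = 80,
                                  seed = 5)
  for (rule in c("voltage", "vogels", "frozen")) {
    p <- plasticity_params(rule_IE = rule)
    fast <- simulate_network(net, proto, p, seed = 21)
    slow <- reference_sim(net, proto, p, seed = 21)
    expect_identical(fast$spikes$neuron, slow$spikes$neuron)
    expect_lt(max(abs(fast$W_final - slow$W)), 1e-10)
  }
})

test_that("the reference agreement also holds at a finer step with strong drive", {
  net <- tiny_network(N = 6, seed = 8, J_exc = 1, g = 2)
  proto <- make_learning_protocol(1, n_orientations = 3, stim_ms = 50,
                                  params = input_params(s_b = 4), seed = 2)
  p <- plasticity_params()
  fast <- simulate_network(net, proto, p, seed = 33, dt = 0.5)
  slow <- reference_sim(net, proto, p, seed = 33, dt = 0.5)
  expect_lt(max(abs(fast$W_final - slow$W)), 1e-10)
  expect_identical(fast$spikes$time_ms, slow$spikes$time_ms)
})

test_that("free-potential decomposition is exact and component-consistent", {
  net <- build_network(network_config(N = 60), seed = 4)
  proto <- make_learning_protocol(1, n_orientations = 5, seed = 5)
  ids <- c(3L, 20L)
  expect_error(free_potential_decomposition(net, proto, 999L, seed = 1),
               "out of range")
  fp <- free_potential_decomposition(net, proto, ids, seed = 6)
  # linearity: the free trace is exactly the sum of its E and I components
  expect_lt(max(abs(fp$u_free - (fp$u_free_exc + fp$u_free_inh))), 1e-9)
  # the excitatory component is non-negative, inhibitory non-positive
  expect_true(all(fp$u_free_exc >= 0))
  expect_true(all(fp$u_free_inh <= 0))

  # with silenced inhibitory weights the inhibitory component vanishes
  net0 <- net
  net0$W[net$pop == "I", ] <- 0
  fp0 <- free_potential_decomposition(net0, proto, ids, seed = 6)
  expect_true(all(fp0$u_free_inh == 0))

  # the excitatory component grows with the feedforward amplitude
  net_iso <- build_network(network_config(N = 60, eps_EE = 0, eps_EI = 0,
                                          eps_IE = 0, eps_II = 0), seed = 4)
  mk <- function(jf) make_learning_protocol(1, n_orientations = 5,
                                            params = input_params(J_ffw = jf),
                                            seed = 5)
  lo <- free_potential_decomposition(net_iso, mk(0.5), ids, seed = 6)
  hi <- free_potential_decomposition(net_iso, mk(1.5), ids, seed = 6)
  expect_true(all(hi$u_free_exc - lo$u_free_exc >= 0))
  expect_gt(max(hi$u_free_exc - lo$u_free_exc), 0)
})
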
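test_that("hazard rate follows the capped exponential escape function", {
  p <- neuron_params(r0 = 0.01, V_T = -55, dV = 2, r_max = 1)
  expect_equal(hazard_rate(p$V_T, p), p$r0)
  expect_equal(hazard_rate(-1e3, p), 0, tolerance = 1e-12)
  # monotone nondecreasing
  V <- seq(-90, 0, by = 0.5)
  expect_true(all(diff(hazard_rate(V, p)) >= 0))
  # cap binds far above threshold: r0 * exp(ln(1e6)) = 1e4 >> r_max
  p2 <- neuron_params(r0 = 0.01, V_T = -55, dV = 2, r_max = 1)
  expect_equal(hazard_rate(p2$V_T + 2 * log(1e6), p2), p2$r_max)
  # threshold offset shifts the curve
  expect_equal(hazard_rate(p$V_T + 3, p, threshold_offset = 3), p$r0)
  expect_error(hazard_rate(NaN, p), "finite")
})

test_that("neuron and synapse parameter invariants are enforced", {
  expect_error(neuron_params(r0 = 0), "r0")
  expect_error(neuron_params(dV = -1), "dV")
  expect_error(neuron_params(r_max = 0.001, r0 = 0.01), "r_max")
  expect_error(neuron_params(E_inh = -60, E_rest = -70), "reversal")
  expect_error(synapse_params(1, 2, weight = -1), "weight")
  expect_error(synapse_params(1, 2, 1, kind = "current-rect"), "pulse_length")
  expect_error(synapse_params(1, 2, 1, U = 1.5, D = 100, F = 100), "U")
  expect_error(stp_amplitudes(1, U = 0, D = 10, F = 10), "U")
})

test_that("STP amplitudes follow the dynamic-synapse recurrences", {
  # first response is w * U regardless of the other parameters
  expect_equal(stp_amplitudes(2, U = 0.3, D = 500, F = 50)[1], 2 * 0.3)
  # infinitely separated spikes fully recover: every amplitude w * U
  A <- stp_amplitudes(1.5, U = 0.4, D = 200, F = 30,
                      intervals = rep(1e9, 4))
  expect_equal(A, rep(1.5 * 0.4, 5), tolerance = 1e-12)
  # hand-iterated depression-only case: u fixed at U = 0.5 (F -> 0),
  # exp(-delta/D) = 0.5 per step
  d <- log(2) * 100
  A <- stp_amplitudes(1, U = 0.5, D = 100, F = 1e-9, intervals = c(d, d))
  expect_equal(A, c(0.5, 0.375, 0.34375), tolerance = 1e-9)
  # agreement with an independent oracle on random draws
  set.seed(42)
  for (i in 1:10) {
    w <- runif(1, 0.5, 3); U <- runif(1, 0.05, 1)
    D <- runif(1, 50, 1500); F <- runif(1, 5, 1500)
    iv <- rexp(8, 1 / 50)
    expect_equal(stp_amplitudes(w, U, D, F, iv),
                 stp_oracle(w, U, D, F, iv), tolerance = 1e-12)
  }
})

test_that("simulation is deterministic given the seed", {
  net <- driven_pair()
  a <- simulate_network(net, 2000, seed = 7)
  b <- simulate_network(net, 2000, seed = 7)
  expect_identical(a$time_ms, b$time_ms)
  expect_identical(a$neuron_id, b$neuron_id)
  c <- simulate_network(net, 2000, seed = 8)
  expect_false(identical(a$time_ms, c$time_ms))
})

test_that("zero-hazard network with no input stays silent", {
  p <- neuron_params(r0 = 1e-12, V_T = 100, dV = 2, r_max = 1)
  net <- network_model(list(p, p))
  rec <- simulate_network(net, 1000, seed = 1)
  expect_equal(nrow(rec), 0L)
})

test_that("refractoriness separates consecutive spikes on every record", {
  net <- network_model(list(flat_neuron(r0 = 0.2, refr = 3)))
  rec <- simulate_network(net, 20000, seed = 3)
  expect_gt(nrow(rec), 100)
  expect_true(all(diff(rec$time_ms) >= 3))
})

test_that("per-step spike probability never exceeds the rate cap", {
  dt <- 0.1
  net <- network_model(list(flat_neuron(r0 = 0.5, refr = 0, r_max = 0.5)))
  rec <- simulate_network(net, 20000, seed = 5)
  p_cap <- 1 - exp(-0.5 * dt)
  n_steps <- 20000 / dt
  phat <- nrow(rec) / n_steps
  tol <- 3 * sqrt(p_cap * (1 - p_cap) / n_steps)
  expect_lte(phat, p_cap + tol)
})

test_that("clamped-voltage neuron is Poisson with dead time (KS test)", {
  refr <- 2; r0 <- 0.05; dt <- 0.1
  net <- network_model(list(flat_neuron(r0 = r0, refr = refr)))
  rec <- simulate_network(net, 120000, seed = 11)
  isi <- diff(rec$time_ms)
  isi <- isi[seq_len(min(5000, length(isi)))]
  expect_gte(length(isi), 4000)
  # ISI - dead time is (discretized) exponential with the per-step rate
  r_eff <- -log(1 - (1 - exp(-r0 * dt))) / dt
  ks <- suppressWarnings(
    stats::ks.test(isi - refr - dt, stats::pexp, rate = r_eff))
  expect_gt(ks$p.value, 0.01)
})

test_that("spike counts match the Poisson-with-dead-time oracle", {
  r0 <- 0.05; refr <- 2; dt <- 0.1; L <- 50000
  net <- network_model(list(flat_neuron(r0 = r0, refr = refr)))
  rec <- simulate_network(net, L, dt = dt, seed = 2)
  # expected ISI: dead time (refr + dt) plus geometric wait with mean dt/p
  p <- 1 - exp(-r0 * dt)
  expected <- L / (refr + dt / p)
  expect_lt(abs(nrow(rec) - expected), 4 * sqrt(expected))
})

test_that("halving dt changes a reference 2-neuron circuit's rate by < 5%", {
  net <- network_model(
    list(neuron_params(bias_current = 120),
         neuron_params(refractory_abs = 0)),
    synapses = list(synapse_params(2, 1, weight = 4, delay = 1)),
    inputs = input_process(2, "constant", rate = 0.1))
  r1 <- mean_rate(simulate_network(net, 100000, dt = 0.1, seed = 4), ids = 1)
  r2 <- mean_rate(simulate_network(net, 100000, dt = 0.05, seed = 4), ids = 1)
  expect_lt(abs(r2 - r1) / r1, 0.05)
})

test_that("single excitatory delivery depolarizes by the closed-form step", {
  # passive membrane, no hazard: follow the potential trace for one EPSP
  p <- neuron_params(r0 = 1e-12, V_T = 1e3, dV = 2, g_leak = 10, C_m = 200)
  pin <- neuron_params(refractory_abs = 0)
  net <- network_model(list(p, pin),
                       synapses = list(synapse_params(2, 1, weight = 5,
                                                      delay = 1)),
                       inputs = input_process(2, "constant", rate = 1e-12))
  # silent: V stays at rest (equilibrium of the leak)
  rec <- simulate_network(net, 100, dt = 0.1, seed = 1,
                          record = "spikes+potentials",
                          init_uniform = FALSE)
  V <- attr(rec, "potentials")[, 1]
  expect_equal(max(abs(V - (-70))), 0, tolerance = 1e-10)
  # now force one presynaptic spike via a high-rate single step is awkward;
  # instead verify the one-step exponential-Euler update analytically
  g_e <- 5; dt <- 0.1
  g_tot <- 10 + g_e
  V_inf <- (10 * -70 + g_e * 0) / g_tot
  V1 <- V_inf + (-70 - V_inf) * exp(-dt * g_tot / 200)
  # a neuron holding that conductance for one step must land on V1:
  # emulate with a net whose neuron starts at rest and receives the
  # conductance via an input spike at t ~ 0 (rate so high it fires at once)
  net2 <- network_model(list(p, neuron_params(refractory_abs = 1e6)),
                        synapses = list(synapse_params(2, 1, weight = 5,
                                                       delay = 0.1)),
                        inputs = input_process(2, "constant", rate = 1e6))
  rec2 <- simulate_network(net2, 5, dt = 0.1, seed = 1,
                           record = "spikes+potentials",
                           init_uniform = FALSE)
  V2 <- attr(rec2, "potentials")[, 1]
  # input fires in step 1 (t=0.1), delivered at step 2; V after that step
  expect_equal(V2[2], V1, tolerance = 1e-9)
})

test_that("preparatory phase fixes the initial state across main seeds", {
  net <- driven_pair(rate = 0.02)
  prep <- prepare_initial_state(net, input_process(2, "constant",
                                                   rate = 0.05),
                                prep_duration = 300, prep_seed = 9,
                                state_window = 100)
  a <- simulate_network(net, 1000, seed = 1, prep = prep)
  b <- simulate_network(net, 1000, seed = 2, prep = prep)
  expect_identical(a$time_ms[a$time_ms <= 0], b$time_ms[b$time_ms <= 0])
  expect_false(identical(a$time_ms[a$time_ms > 0], b$time_ms[b$time_ms > 0]))
  # zero-rate preparatory input yields the resting initial state
  net0 <- driven_pair(rate = 0)
  prep0 <- prepare_initial_state(net0, input_process(2, "constant", rate = 0),
                                 prep_duration = 200, prep_seed = 1)
  r0 <- simulate_network(net0, 500, seed = 1, prep = prep0)
  expect_true(is_resting_state(
    markov_state(r0, 100, state_config(T = 100, tau = 20))))
  # too-short preparatory phase is rejected
  expect_error(prepare_initial_state(net, list(), 50, 1,
                                     state_window = 100), ">=")
})

test_that("dt exceeding the smallest delay is rejected", {
  net <- driven_pair()
  expect_error(simulate_network(net, 100, dt = 2, seed = 1), "delay")
})

test_that("markov-modulated input switches between rate regimes", {
  net <- network_model(
    list(neuron_params(), neuron_params(refractory_abs = 0)),
    synapses = list(synapse_params(2, 1, weight = 1, delay = 1)),
    inputs = input_process(2, "markov-modulated",
                           modulator = list(rates = c(0.002, 0.08),
                                            Q_dwell = c(1000, 1000))))
  rec <- simulate_network(net, 30000, seed = 12)
  rec2 <- simulate_network(net, 30000, seed = 12)
  expect_identical(rec$time_ms, rec2$time_ms)
  counts <- tabulate(findInterval(rec$time_ms[rec$neuron_id == 2],
                                  seq(0, 30000, by = 1000)), nbins = 30)
  # rate switching produces clearly bimodal window counts: overdispersed
  # relative to a constant-rate Poisson train of the same mean
  expect_gt(var(counts) / mean(counts), 3)
})
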
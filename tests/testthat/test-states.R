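cfg_small <- state_config(T = 20, tau = 10, dt_sample = 1)

test_that("simple states use the half-open window convention", {
  rec <- spike_record(c(1L, 3L), c(5, 9.5), duration = 40, n_neurons = 3)
  expect_equal(simple_state(rec, 10, cfg_small), c(1L, 0L, 1L))
  # spike exactly at t - tau is excluded, at t included
  rec2 <- spike_record(c(1L, 2L), c(10, 20), duration = 40, n_neurons = 2)
  expect_equal(simple_state(rec2, 20, cfg_small), c(0L, 1L))
  # brute-force interval scan agrees on random records
  set.seed(1)
  for (i in 1:25) {
    n <- 4
    tt <- sort(runif(30, 0, 100))
    id <- sample.int(n, 30, replace = TRUE)
    rec3 <- spike_record(id, tt, duration = 100, n_neurons = n)
    t <- runif(1, 10, 100)
    brute <- vapply(1:n, function(j)
      as.integer(any(tt[id == j] > t - 10 & tt[id == j] <= t)), 1L)
    expect_equal(simple_state(rec3, t, cfg_small), brute)
  }
  expect_error(simple_state(rec, 5, cfg_small), "tau")
  # all-zero on an empty record
  empty <- spike_record(integer(0), numeric(0), duration = 50, n_neurons = 2)
  expect_equal(simple_state(empty, 30, cfg_small), c(0L, 0L))
})

test_that("markov states restrict and binarize to simple states", {
  empty <- spike_record(integer(0), numeric(0), duration = 50, n_neurons = 2)
  expect_true(is_resting_state(markov_state(empty, 30, cfg_small)))
  rec <- spike_record(c(1L, 1L, 2L), c(10, 15, 30), duration = 50,
                      n_neurons = 2)
  ms <- markov_state(rec, 30, cfg_small)
  # offsets relative to the window start t - T = 10; spike at 10 excluded
  expect_equal(ms[[1]], 5)
  expect_equal(ms[[2]], 20)
  expect_error(markov_state(rec, 10, cfg_small), "T")
  # consistency with simple_state on random records
  set.seed(2)
  for (i in 1:100) {
    tt <- sort(runif(40, 0, 200))
    id <- sample.int(3, 40, replace = TRUE)
    r <- spike_record(id, tt, duration = 200, n_neurons = 3)
    t <- runif(1, 20, 200)
    ms <- markov_state(r, t, cfg_small)
    bin <- vapply(ms, function(off) as.integer(any(off > 20 - 10)), 1L)
    expect_equal(unname(bin), simple_state(r, t, cfg_small))
  }
})

test_that("empirical distributions are normalized and match counts", {
  fx <- generate_fixture(fixture_spec("poisson-chains",
                                      rates = c(0.02, 0.01, 0.03),
                                      duration = 3000, seed = 4))
  d <- empirical_distribution(fx, cfg_small, 10, 3000)
  expect_equal(sum(d$freq), 1, tolerance = 1e-12)
  expect_true(all(d$freq >= 0))
  # constant all-ones activity concentrates on the all-ones state
  dense <- spike_record(rep(1:2, each = 200),
                        rep(seq(5, 1000, by = 5), 2), duration = 1000,
                        n_neurons = 2)
  dd <- empirical_distribution(dense, cfg_small, 10, 1000)
  expect_equal(map_readout(dd), "11")
  expect_equal(dd$freq[dd$states == "11"], 1)
  expect_error(empirical_distribution(fx, cfg_small, 10, 10.5), "grid")
})

test_that("two-state occupancy fixture reproduces its target fraction", {
  fx <- generate_fixture(fixture_spec("two-state-occupancy",
                                      occupancy = 0.3, duration = 30000,
                                      tau = 20))
  cfg <- state_config(T = 100, tau = 20, dt_sample = 1)
  est <- estimate_marginal(fx, 1, 1, cfg, c(20, 30000))
  expect_lt(abs(est - 0.3), 0.02)
})

test_that("marginals are complements and marginalization-consistent", {
  fx <- generate_fixture(fixture_spec("poisson-chains",
                                      rates = c(0.02, 0.015, 0.01),
                                      duration = 4000, seed = 9))
  cfg <- cfg_small
  m1 <- estimate_marginal(fx, 1, 1, cfg, c(10, 4000))
  m0 <- estimate_marginal(fx, 1, 0, cfg, c(10, 4000))
  expect_equal(m1 + m0, 1, tolerance = 1e-12)
  # joint marginalized over neuron 3 equals the pair marginal
  cfg3 <- state_config(T = 20, tau = 10, dt_sample = 1, subset = 1:3)
  d3 <- empirical_distribution(fx, cfg3, 10, 4000)
  pair <- estimate_marginal(fx, 1:2, c(1, 0), cfg, c(10, 4000))
  joint <- sum(d3$freq[substr(d3$states, 1, 2) == "10"])
  expect_equal(joint, pair, tolerance = 1e-12)
  # explicit pattern frequency equals a brute-force count
  times <- seq(10, 4000, by = 1)
  bits <- vapply(1:2, function(j) {
    v <- fx$time_ms[fx$neuron_id == j]
    (findInterval(times, v) - findInterval(times - 10, v)) > 0
  }, logical(length(times)))
  brute <- mean(bits[, 1] & !bits[, 2])
  expect_equal(pair, brute, tolerance = 1e-12)
})

test_that("map readout takes the argmax with lexicographic ties", {
  d <- spikenet:::new_empirical_distribution(c("10", "01"), c(0.5, 0.5), 10)
  expect_equal(map_readout(d), "01")
  d2 <- spikenet:::new_empirical_distribution(c("00", "11"), c(0.2, 0.8), 10)
  expect_equal(map_readout(d2), "11")
})

test_that("phase distributions sample the right cycle times", {
  # active only in the first half of each 200 ms cycle
  fx <- generate_fixture(fixture_spec("periodic-gated", rate = 0.5,
                                      period = 200, duration = 40000,
                                      seed = 5))
  cfg <- state_config(T = 20, tau = 20, dt_sample = 1)
  d_on <- phase_distribution(fx, cfg, T_per = 200, phase = 50,
                             n_cycles = 90, t_burn = 1000)
  d_off <- phase_distribution(fx, cfg, T_per = 200, phase = 150,
                              n_cycles = 90, t_burn = 1000)
  expect_equal(d_on$freq[d_on$states == "1"], 1)
  expect_equal(d_off$freq[d_off$states == "0"], 1)
  expect_equal(d_on$phase, 50); expect_equal(d_on$period, 200)
  expect_equal(sum(d_on$freq), 1, tolerance = 1e-12)
  expect_error(phase_distribution(fx, cfg, 200, 250, 10), "phase")
})

test_that("trajectory distributions reduce and count sequences", {
  cfg <- state_config(T = 20, tau = 10, dt_sample = 10)
  fx <- generate_fixture(fixture_spec("poisson-chains", rates = 0.02,
                                      duration = 2000, seed = 3))
  d1 <- trajectory_distribution(fx, cfg, L = 10, 20, 2000)
  d0 <- empirical_distribution(fx, cfg, 20, 2000)
  expect_equal(d1$freq, d0$freq)
  expect_equal(d1$states, d0$states)
  # deterministic alternating fixture: two length-2 trajectories at 0.5
  alt <- spike_record(rep(1L, 100), seq(15, 2000, by = 20),
                      duration = 2000, n_neurons = 1)
  d2 <- trajectory_distribution(alt, cfg, L = 20, 20, 1990)
  expect_setequal(d2$states, c("1;0", "0;1"))
  expect_equal(sort(d2$freq), c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(d2$freq), 1, tolerance = 1e-12)
})

test_that("attractor transitions are located at handover midpoints", {
  hv <- generate_fixture(fixture_spec("handover", t1 = 500, t2 = 600,
                                      duration = 1100))
  cfg <- state_config(T = 100, tau = 20, dt_sample = 1)
  tr <- detect_attractor_transitions(hv, 1:5, 6:10, cfg)
  expect_equal(nrow(tr), 1L)
  # A stays active tau after its last spike at 500; B starts at 600
  expect_lt(abs(tr$time - (520 + 600) / 2), 2)
  # no handover -> empty
  fx <- generate_fixture(fixture_spec("poisson-chains",
                                      rates = rep(0.001, 10),
                                      duration = 1000, seed = 2))
  expect_equal(nrow(detect_attractor_transitions(fx, 1:5, 6:10, cfg)), 0L)
  # K alternating handovers produce K transitions, with phases attached
  tms <- c(); ids <- c()
  for (k in 0:3) {
    act <- seq(k * 500 + 2, k * 500 + 400, by = 2)
    pool <- if (k %% 2 == 0) 1:5 else 6:10
    tms <- c(tms, rep(act, 5))
    ids <- c(ids, rep(pool, each = length(act)))
  }
  rec <- spike_record(ids, tms, duration = 2000, n_neurons = 10)
  tr2 <- detect_attractor_transitions(rec, 1:5, 6:10, cfg, T_per = 500)
  expect_equal(nrow(tr2), 3L)
  expect_true(all(tr2$phase >= 0 & tr2$phase < 500))
  expect_error(detect_attractor_transitions(rec, 1:5, 5:8, cfg), "disjoint")
})

test_that("periodic threshold modulation induces phase-dependent statistics", {
  p <- flat_neuron(r0 = 0.02, refr = 1)
  net <- network_model(list(p),
                       threshold_modulation = list(amplitude = 4,
                                                   period = 200))
  rec <- simulate_network(net, 60000, seed = 6)
  cfg <- state_config(T = 20, tau = 20, dt_sample = 1, subset = 1L)
  n_cyc <- 250
  # threshold is lowest at phase 150 (sin = -1): activity maximal there
  d_hi <- phase_distribution(rec, cfg, T_per = 200, phase = 150,
                             n_cycles = n_cyc, t_burn = 5000)
  d_lo <- phase_distribution(rec, cfg, T_per = 200, phase = 50,
                             n_cycles = n_cyc, t_burn = 5000)
  p_hi <- sum(d_hi$freq[d_hi$states == "1"])
  p_lo <- sum(d_lo$freq[d_lo$states == "1"])
  se <- sqrt(p_hi * (1 - p_hi) / n_cyc + p_lo * (1 - p_lo) / n_cyc)
  expect_gt(p_hi - p_lo, 3 * se)
})
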
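test_that("puzzles are parsed and validated", {
  pz <- bundled_sudoku()
  expect_s3_class(pz, "sudoku_puzzle")
  expect_equal(sum(pz$cells != 0), 26L)
  expect_false(is.null(pz$solution))
  # duplicate digit in a row is rejected
  bad <- paste0("55", strrep("0", 79))
  expect_error(sudoku_puzzle(bad), "inconsistent")
  # solution must extend the givens
  expect_error(sudoku_puzzle(paste0("1", strrep("0", 80)),
                             gsub("^5", "2", paste(t(pz$solution),
                                                   collapse = ""))),
               "extend|uniqueness")
  # dots are blanks
  pz2 <- sudoku_puzzle(gsub("0", ".", paste(t(pz$cells), collapse = "")))
  expect_equal(pz2$cells, pz$cells)
})

test_that("sudoku encoding has the prescribed WTA structure", {
  pz <- bundled_sudoku()
  cn <- encode_sudoku(pz, csp_params(N_E = 4))
  expect_equal(cn$n_pyr, 81 * 9 * 4)
  kinds <- vapply(cn$motifs, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "domain"), 81L)     # field-uniqueness motifs
  expect_equal(sum(kinds == "group"), 243L)     # row/col/subgrid x digit
  # every pyramidal cell participates in exactly 4 WTA motifs
  member_count <- tabulate(unlist(lapply(cn$motifs, `[[`, "members")),
                           nbins = cn$n_pyr)
  expect_true(all(member_count == 4L))
  # each motif has one inhibitory neuron reciprocally connected
  m <- cn$motifs[[1]]
  expect_true(all(m$members %in%
                    cn$net$synapses$pre[cn$net$synapses$post == m$inh]))
  expect_true(all(m$members %in%
                    cn$net$synapses$post[cn$net$synapses$pre == m$inh]))
  # N_E = 1 gives one cell per (field, digit)
  cn1 <- encode_sudoku(pz, csp_params(N_E = 1))
  expect_equal(cn1$n_pyr, 729L)
})

test_that("generic CSP compilation reproduces the sudoku network", {
  pz <- bundled_sudoku()
  cn <- encode_sudoku(pz, csp_params(N_E = 2))
  units <- spikenet:::sudoku_units()
  groups <- unlist(lapply(units, function(u)
    lapply(1:9, function(d) cbind(var = u, value = d))),
    recursive = FALSE)
  v <- as.integer(t(pz$cells)); giv <- which(v > 0)
  cn2 <- encode_generic_csp(rep(9L, 81), groups,
                            clamps = data.frame(var = giv, value = v[giv]),
                            params = csp_params(N_E = 2))
  expect_identical(cn$net$synapses, cn2$net$synapses)
  expect_identical(cn$net$neurons, cn2$net$neurons)
  # single variable, domain 9, no groups: one WTA of 9 * N_E cells
  cn3 <- encode_generic_csp(9L, params = csp_params(N_E = 3))
  expect_equal(length(cn3$motifs), 1L)
  expect_equal(length(cn3$motifs[[1]]$members), 27L)
  expect_error(encode_generic_csp(9L, groups = list(matrix(0, 0, 2))),
               "empty")
})

test_that("decoding reads windowed one-hot activity", {
  pz <- bundled_sudoku()
  cn <- encode_sudoku(pz, csp_params(N_E = 4))
  # craft a record: one cell of (field 1, digit 6) spikes at t - tau/2
  cell_f1d6 <- which(cn$cell_var == 1 & cn$cell_val == 6)[1]
  cells_f2 <- c(which(cn$cell_var == 2 & cn$cell_val == 3)[1],
                which(cn$cell_var == 2 & cn$cell_val == 5)[1])
  rec <- spike_record(c(cell_f1d6, cells_f2), c(95, 94, 96),
                      duration = 120, n_neurons = nrow(cn$net$neurons))
  dec <- csp_decode(rec, cn, 100, tau = 10)
  expect_equal(dec[[1]], 6L)
  expect_equal(dec[[2]], c(3L, 5L))                    # two active digits
  expect_true(all(lengths(dec[-(1:2)]) == 0))
  # empty everywhere before any spike
  dec0 <- csp_decode(rec, cn, 50, tau = 10)
  expect_true(all(lengths(dec0) == 0))
  # window is half-open: a spike exactly at t - tau does not count
  dec2 <- csp_decode(rec, cn, 105, tau = 10)
  expect_length(dec2[[1]], 0L)               # spike at 95 = t - tau: out
  expect_equal(dec2[[2]], 5L)                # 94 out, 96 in
  dec3 <- csp_decode(rec, cn, 104, tau = 10)
  expect_equal(dec3[[1]], 6L)                # 95 in (94, 104]
  expect_equal(dec3[[2]], 5L)
})

test_that("performance and solve time follow the singleton rule", {
  pz <- bundled_sudoku()
  cn <- encode_sudoku(pz, csp_params(N_E = 1))
  sol <- as.integer(t(pz$solution))
  # construct a record where 40 fields show their correct digit
  show <- 1:40
  cells <- vapply(show, function(f)
    which(cn$cell_var == f & cn$cell_val == sol[f]), 1L)
  rec <- spike_record(cells, rep(95, 40), duration = 200,
                      n_neurons = nrow(cn$net$neurons))
  expect_equal(csp_performance(rec, cn, 100), 40 / 81)
  # all empty -> 0; multi-active counts wrong in singleton mode
  expect_equal(csp_performance(rec, cn, 150), 0)
  wrongd <- which(cn$cell_var == 1 & cn$cell_val == (sol[1] %% 9 + 1))
  rec2 <- spike_record(c(cells, wrongd), c(rep(95, 40), 96),
                       duration = 200, n_neurons = nrow(cn$net$neurons))
  expect_equal(csp_performance(rec2, cn, 100), 39 / 81)
  # lenient mode still credits the correct digit
  expect_equal(csp_performance(rec2, cn, 100, mode = "lenient"), 40 / 81)
  # solve time: earliest full-solution grid time
  all_cells <- vapply(1:81, function(f)
    which(cn$cell_var == f & cn$cell_val == sol[f]), 1L)
  rec3 <- spike_record(rep(all_cells, 2), rep(c(55, 63), each = 81),
                       duration = 100, n_neurons = nrow(cn$net$neurons))
  st <- csp_solve_time(rec3, cn, grid = seq(10, 100, by = 10))
  expect_equal(st, 60)
  expect_true(is.na(csp_solve_time(rec, cn, grid = seq(10, 200, by = 10))))
})

test_that("event-driven and time-stepped backends agree on a 2-field toy", {
  # two variables, two values, one shared uniqueness group per value
  params <- csp_params(N_E = 2, clamp_pos = 20)
  groups <- list(cbind(var = 1:2, value = c(1, 1)),
                 cbind(var = 1:2, value = c(2, 2)))
  cn <- encode_generic_csp(c(2L, 2L), groups, params = params)
  marg_event <- local({
    res <- simulate_csp(cn, 30000, seed = 3, record = "pyramidal",
                        check_dt = 0)
    sapply(1:2, function(v) {
      cells <- which(cn$cell_var == v & cn$cell_val == 1)
      cfg <- state_config(T = 20, tau = 10, dt_sample = 5, subset = cells)
      d <- empirical_distribution(res$spikes, cfg, 1000, 30000)
      1 - sum(d$freq[d$states == strrep("0", length(cells))])
    })
  })
  marg_step <- local({
    rec <- simulate_network(cn$net, 30000, dt = 0.1, seed = 4)
    sapply(1:2, function(v) {
      cells <- which(cn$cell_var == v & cn$cell_val == 1)
      cfg <- state_config(T = 20, tau = 10, dt_sample = 5, subset = cells)
      d <- empirical_distribution(rec, cfg, 1000, 30000)
      1 - sum(d$freq[d$states == strrep("0", length(cells))])
    })
  })
  expect_lt(max(abs(marg_event - marg_step)), 0.05)
})

test_that("sudoku experiments collect run statistics", {
  pz <- bundled_sudoku()
  ex <- sudoku_experiment(pz, runs = 2, max_duration = 1500, seed = 9,
                          check_dt = 25, burn_in = 500)
  expect_length(ex$solve_times, 2L)
  expect_true(ex$occupancy >= 0 && ex$occupancy <= 1)
  expect_equal(length(ex$perf_times), length(ex$perf_mean))
  expect_true(all(ex$perf_mean >= 0 & ex$perf_mean <= 1))
  expect_equal(ex$n_unsolved, sum(is.na(ex$solve_times)))
})

test_that("WTA dynamics suppresses constraint violations and honors givens", {
  pz <- bundled_sudoku()
  cn <- encode_sudoku(pz)
  res <- simulate_csp(cn, 6000, seed = 5, record = "all", check_dt = 10)
  giv <- as.integer(t(pz$cells))
  grid <- seq(3000, 6000, by = 20)
  conf <- 0; givok <- 0
  for (t in grid) {
    dec <- csp_decode(res$spikes, cn, t)
    conf <- conf + mean(vapply(dec, function(a) choose(length(a), 2), 1))
    givok <- givok + mean(vapply(which(giv > 0), function(f)
      length(dec[[f]]) == 1 && dec[[f]] == giv[f], TRUE))
  }
  # expected simultaneously active conflicting digit pairs per field
  expect_lt(conf / length(grid), 0.1)
  # given fields decode to exactly the given digit essentially always
  expect_gt(givok / length(grid), 0.99)
})

test_that("an easy puzzle (60 givens) solves within seconds", {
  pz <- bundled_sudoku()
  set.seed(42)
  cells <- pz$solution
  cells[sample(81, 21)] <- 0L
  easy <- sudoku_puzzle(cells, pz$solution)
  cn <- encode_sudoku(easy)
  solved <- vapply(1:20, function(s) {
    res <- simulate_csp(cn, 5000, seed = s, check_dt = 10,
                        stop_on_solve = TRUE)
    is.finite(res$solve_time)
  }, logical(1))
  expect_gte(mean(solved), 0.9)
})

test_that("mean performance improves over the first seconds (anytime property)", {
  pz <- bundled_sudoku()
  ex <- sudoku_experiment(pz, runs = 20, max_duration = 4000, seed = 77,
                          check_dt = 20, stop_on_solve = FALSE)
  blocks <- split(ex$perf_mean, ceiling(ex$perf_times / 1000))
  bm <- vapply(blocks, mean, numeric(1))
  # monotone trend up to statistical tolerance
  expect_true(all(diff(bm) > -0.03))
  expect_gt(bm[length(bm)], bm[1])
})

test_that("graph coloring by WTA keeps assignments consistent", {
  # triangle with 4 colors: per-edge, per-color uniqueness groups
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3))
  groups <- list()
  for (e in 1:3) for (col in 1:4)
    groups[[length(groups) + 1]] <- cbind(var = edges[e, ], value = col)
  cn <- encode_generic_csp(rep(4L, 3), groups)
  res <- simulate_csp(cn, 10000, seed = 2, record = "pyramidal",
                      check_dt = 0)
  grid <- seq(5000, 10000, by = 20)
  status <- vapply(grid, function(t) {
    dec <- csp_decode(res$spikes, cn, t)
    if (!all(lengths(dec) == 1)) return(NA)
    dec[[1]] != dec[[2]] && dec[[1]] != dec[[3]] && dec[[2]] != dec[[3]]
  }, logical(1))
  # when all three variables are decoded, they are a valid coloring far
  # more often than the 37.5% chance level
  expect_gt(mean(status, na.rm = TRUE), 0.8)
  # and valid colorings occupy a clearly above-chance share of total time
  expect_gt(mean(!is.na(status) & status), 0.15)
})
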
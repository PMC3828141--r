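#' Sudoku puzzle container
#'
#' Parses and validates a 9x9 Sudoku.  Givens must be consistent (no digit
#' twice in a row, column or 3x3 subgrid); if a solution is supplied it
#' must extend the givens and satisfy all uniqueness rules.
#'
#' @param cells 81-character row-major string (digits 1-9, `0` or `.` for
#'   blanks), or a 9x9 integer matrix with 0 for blanks.
#' @param solution optional solved grid in the same formats.
#' @return an object of class `"sudoku_puzzle"`: list with 9x9 integer
#'   matrices `cells` and (optionally) `solution`.
#' @export
sudoku_puzzle <- function(cells, solution = NULL) {
  cells <- parse_grid(cells)
  if (!sudoku_consistent(cells)) stop("inconsistent givens")
  if (!is.null(solution)) {
    solution <- parse_grid(solution)
    if (any(solution == 0)) stop("solution must be complete")
    if (!sudoku_consistent(solution)) stop("solution violates uniqueness rules")
    if (any(cells != 0 & cells != solution))
      stop("solution does not extend the givens")
  }
  structure(list(cells = cells, solution = solution),
            class = "sudoku_puzzle")
}

parse_grid <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(9, 9)))
    return(matrix(as.integer(x), 9, 9))
  }
  x <- gsub("\\.", "0", x)
  if (nchar(x) != 81 || grepl("[^0-9]", x)) stop("expected an 81-digit string")
  matrix(as.integer(strsplit(x, "")[[1]]), 9, 9, byrow = TRUE)
}

sudoku_units <- function() {
  idx <- matrix(seq_len(81), 9, 9, byrow = TRUE)  # [row, col] -> field id
  units <- c(lapply(1:9, function(r) idx[r, ]),
             lapply(1:9, function(c) idx[, c]),
             unlist(lapply(0:2, function(br) lapply(0:2, function(bc)
               as.vector(idx[br * 3 + 1:3, bc * 3 + 1:3]))),
               recursive = FALSE))
  names(units) <- c(paste0("row", 1:9), paste0("col", 1:9), paste0("box", 1:9))
  units
}

sudoku_consistent <- function(cells) {
  v <- as.integer(t(cells))      # field id = row-major index
  for (u in sudoku_units()) {
    d <- v[u]; d <- d[d > 0]
    if (anyDuplicated(d)) return(FALSE)
  }
  TRUE
}

#' @export
print.sudoku_puzzle <- function(x, ...) {
  cat("<sudoku_puzzle> ", sum(x$cells != 0), " givens",
      if (!is.null(x$solution)) ", solution attached", "\n", sep = "")
  for (r in 1:9) {
    row <- ifelse(x$cells[r, ] == 0, ".", x$cells[r, ])
    cat(" ", paste(row[1:3], collapse = " "), "|",
        paste(row[4:6], collapse = " "), "|",
        paste(row[7:9], collapse = " "), "\n")
    if (r %in% c(3, 6)) cat("  ------+-------+------\n")
  }
  invisible(x)
}

#' Read a puzzle file (puzzle line + optional solution line)
#'
#' Lines starting with `#` are comments; the first non-comment line is the
#' puzzle, the second (if present) its solution.
#'
#' @param path file path.
#' @return a [sudoku_puzzle()].
#' @export
read_sudoku <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))])
  sudoku_puzzle(ln[1], if (length(ln) > 1) ln[2] else NULL)
}

#' The bundled hard 26-given puzzle
#'
#' A synthetic stand-in: a hard-rated puzzle with 26 givens and a unique
#' solution, generated programmatically (uniqueness verified by exhaustive
#' search; not solvable by naked/hidden singles alone).
#'
#' @return a [sudoku_puzzle()] with solution.
#' @export
bundled_sudoku <- function() {
  read_sudoku(system.file("extdata", "sudoku_hard26_synthetic.txt",
                          package = "spikenet"))
}

#' Parameters of the WTA constraint-satisfaction network
#'
#' All synapses are rectangular current pulses; with the quasi-static
#' membrane used here, weights and clamps are expressed directly as the
#' membrane-potential offsets (mV) they impose while active.
#'
#' @param r0_E,r_max_E,dV_E,refr_E pyramidal-cell hazard at rest (1/ms),
#'   rate cap (1/ms), hazard slope (mV), absolute refractory period (ms).
#'   The pyramidal threshold sits at the resting potential (low threshold),
#'   so `r0_E` is the free-running rate.
#' @param r0_I,r_max_I motif-inhibitory-neuron hazard at threshold (1/ms)
#'   and rate cap (1/ms).
#' @param w_EI pyramidal->inhibitory pulse amplitude (mV).
#' @param w_IE_field,w_IE_group inhibitory->pyramidal pulse magnitudes
#'   (mV) of domain and uniqueness-group motifs.  The field suppression is
#'   strong (crisp winner-take-all); the group suppression is deliberately
#'   softer, so cells blocked by a conflicting assignment elsewhere retain
#'   a small escape rate — the stochastic-search channel that lets the
#'   network challenge and revise tentative assignments.
#' @param theta_I_field,pulse_E_field,pulse_I_field,refr_I_field domain
#'   (field) motif interneuron: threshold offset above rest (mV; below one
#'   `w_EI` pulse, so a single member spike triggers lateral inhibition
#'   almost instantly), E->I pulse length, I->E suppression length (kept
#'   shorter than `tau` so the current winner re-fires seamlessly), and
#'   refractory period (ms).
#' @param theta_I_group,pulse_E_group,pulse_I_group,refr_I_group
#'   uniqueness-group motif interneuron: the threshold sits between one and
#'   two `w_EI` pulses, so the interneuron acts as a coincidence detector
#'   that fires when two member groups are active simultaneously (a
#'   constraint violation) and then silences the group's members for a
#'   prolonged `pulse_I_group` (ms).  `pulse_E_group` must stay below the
#'   active winner's inter-spike interval to avoid self-triggering.
#' @param w_EE,pulse_EE recurrent excitation within each (variable,
#'   value) cell group (mV, ms): all-to-all pulses among the `N_E` cells,
#'   letting an active group sustain itself through the periodic lateral
#'   inhibition that silences unsupported competitors (the assembly
#'   advantage of population coding, `N_E > 1`).  With STP enabled the
#'   first pulse after rest has amplitude `w_EE * U_EE`.
#' @param U_EE,D_EE,F_EE optional Tsodyks-Markram dynamics on the
#'   intra-group excitation (`U_EE = NA` disables).  Depression fatigues a
#'   long-active assembly, so tentative assignments have finite lifetimes
#'   and stuck configurations anneal away; the group recovers while
#'   silent.
#' @param delay synaptic delay (ms), all connection types.
#' @param clamp_pos,clamp_neg constant membrane offsets (mV) for cells
#'   coding a given digit / a conflicting digit in a given field;
#'   `clamp_pos` exceeds `w_IE` so given cells fire through group
#'   inhibition (givens are never overridden).
#' @param tau decoding window (ms): a one-hot variable is active iff one of
#'   its cells spiked within the last `tau`.
#' @param N_E pyramidal cells per (variable, value) group.
#' @return a list of class `"csp_params"`.
#' @export
csp_params <- function(r0_E = 0.05, r_max_E = 1, dV_E = 2, refr_E = 5,
                       r0_I = 0.1, r_max_I = 20,
                       w_EI = 16, w_IE_field = 18, w_IE_group = 12,
                       theta_I_field = 12, pulse_E_field = 2,
                       pulse_I_field = 8, refr_I_field = 7,
                       theta_I_group = 8, pulse_E_group = 5,
                       pulse_I_group = 8.5, refr_I_group = 8,
                       w_EE = 6, pulse_EE = 20,
                       U_EE = NA, D_EE = 300, F_EE = 50,
                       delay = 0.1, clamp_pos = 80, clamp_neg = -20,
                       tau = 10, N_E = 4) {
  structure(as.list(environment()), class = "csp_params")
}

#' Compile a one-hot constraint-satisfaction problem into a WTA network
#'
#' Each variable gets one group of `N_E` pyramidal cells per domain value;
#' firing of any cell of a group votes for that value for a short period
#' `tau`.  Every variable contributes a domain WTA motif (at most one value
#' active), and every uniqueness group contributes a group WTA motif over
#' its (variable, value) members.  A WTA motif is one inhibitory neuron
#' reciprocally connected to all member cells with rectangular current
#' pulses.  Clamps fix variables by constant currents: positive on the
#' clamped value's cells, negative on the other values' cells.
#'
#' @param n_values integer vector: domain size per variable.
#' @param groups list of uniqueness groups, each a 2-column matrix /
#'   data.frame of (variable, value) members.
#' @param clamps optional data.frame with columns `var`, `value`: clamped
#'   assignments.
#' @param params a [csp_params()].
#' @return an object of class `"csp_network"`.
#' @export
encode_generic_csp <- function(n_values, groups = list(), clamps = NULL,
                               params = csp_params()) {
  n_vars <- length(n_values)
  if (n_vars < 1) stop("need at least one variable")
  N_E <- params$N_E
  # cell bookkeeping: cells numbered variable-major, then value, then copy
  n_cells_per_var <- n_values * N_E
  var_off <- c(0L, cumsum(n_cells_per_var))
  n_pyr <- var_off[n_vars + 1L]
  cell_ids <- function(v, d) {
    if (d < 1 || d > n_values[v]) stop("value out of domain")
    var_off[v] + (d - 1L) * N_E + seq_len(N_E)
  }
  cell_var <- rep.int(seq_len(n_vars), n_cells_per_var)
  cell_val <- unlist(lapply(seq_len(n_vars), function(v)
    rep(seq_len(n_values[v]), each = N_E)), use.names = FALSE)

  motifs <- vector("list", n_vars + length(groups))
  for (v in seq_len(n_vars))
    motifs[[v]] <- list(kind = "domain", label = paste0("var", v),
                        members = var_off[v] + seq_len(n_cells_per_var[v]))
  for (g in seq_along(groups)) {
    gm <- as.matrix(groups[[g]])
    if (!nrow(gm)) stop("empty uniqueness group")
    mem <- unlist(lapply(seq_len(nrow(gm)), function(r)
      cell_ids(gm[r, 1], gm[r, 2])), use.names = FALSE)
    motifs[[n_vars + g]] <- list(kind = "group", label = paste0("group", g),
                                 members = mem)
  }
  n_inh <- length(motifs)
  for (m in seq_along(motifs)) motifs[[m]]$inh <- n_pyr + m

  g_leak <- 10
  clamp_mV <- numeric(n_pyr)
  if (!is.null(clamps) && nrow(clamps)) {
    for (r in seq_len(nrow(clamps))) {
      v <- clamps$var[r]; d <- clamps$value[r]
      clamp_mV[cell_ids(v, d)] <- params$clamp_pos
      other <- setdiff(seq_len(n_values[v]), d)
      for (o in other) clamp_mV[cell_ids(v, o)] <- params$clamp_neg
    }
  }
  n <- n_pyr + n_inh
  is_inh <- c(rep(FALSE, n_pyr), rep(TRUE, n_inh))
  inh_kind <- vapply(motifs, `[[`, character(1), "kind")
  is_dom <- c(rep(NA, n_pyr), inh_kind == "domain")
  neurons <- data.frame(
    g_leak = g_leak, C_m = 0.2,            # quasi-static membrane
    E_rest = -70, E_exc = 0, E_inh = -75,
    r0 = ifelse(is_inh, params$r0_I, params$r0_E),
    V_T = ifelse(is_inh,
                 -70 + ifelse(is_dom %in% TRUE, params$theta_I_field,
                              params$theta_I_group),
                 -70),
    dV = params$dV_E,
    r_max = ifelse(is_inh, params$r_max_I, params$r_max_E),
    refractory_abs = ifelse(is_inh,
                            ifelse(is_dom %in% TRUE, params$refr_I_field,
                                   params$refr_I_group),
                            params$refr_E),
    bias_current = c(clamp_mV, rep(0, n_inh)) * g_leak,
    is_inhibitory = is_inh)
  pre <- integer(0); post <- integer(0); w <- numeric(0); pl <- numeric(0)
  sU <- numeric(0); sD <- numeric(0); sF <- numeric(0)
  if (params$w_EE > 0 && N_E > 1) {
    # recurrent excitation within each (variable, value) cell group
    for (v in seq_len(n_vars)) for (d in seq_len(n_values[v])) {
      ids <- cell_ids(v, d)
      g <- expand.grid(pre = ids, post = ids)
      g <- g[g$pre != g$post, ]
      pre <- c(pre, g$pre); post <- c(post, g$post)
      w <- c(w, rep(params$w_EE * g_leak, nrow(g)))
      pl <- c(pl, rep(params$pulse_EE, nrow(g)))
      sU <- c(sU, rep(params$U_EE, nrow(g)))
      sD <- c(sD, rep(params$D_EE, nrow(g)))
      sF <- c(sF, rep(params$F_EE, nrow(g)))
    }
  }
  for (m in motifs) {
    k <- length(m$members)
    dom <- m$kind == "domain"
    p_ie <- if (dom) params$pulse_I_field else params$pulse_I_group
    p_ei <- if (dom) params$pulse_E_field else params$pulse_E_group
    w_ie <- if (dom) params$w_IE_field else params$w_IE_group
    pre <- c(pre, m$members, rep.int(m$inh, k))
    post <- c(post, rep.int(m$inh, k), m$members)
    w <- c(w, rep(params$w_EI * g_leak, k), rep(w_ie * g_leak, k))
    pl <- c(pl, rep(p_ei, k), rep(p_ie, k))
    sU <- c(sU, rep(NA_real_, 2 * k))
    sD <- c(sD, rep(NA_real_, 2 * k))
    sF <- c(sF, rep(NA_real_, 2 * k))
  }
  syn <- data.frame(pre = pre, post = post, weight = w, delay = params$delay,
                    kind = "current-rect", pulse_length = pl,
                    U = sU, D = sD, F = sF, stringsAsFactors = FALSE)
  net <- network_model(neurons, syn)
  structure(list(net = net, n_vars = n_vars, n_values = n_values,
                 N_E = N_E, cell_var = cell_var, cell_val = cell_val,
                 n_pyr = n_pyr, motifs = motifs, params = params,
                 clamps = clamps, puzzle = NULL),
            class = "csp_network")
}

#' @export
print.csp_network <- function(x, ...) {
  cat("<csp_network> ", x$n_vars, " variables, ", x$n_pyr,
      " pyramidal cells (N_E = ", x$N_E, "), ", length(x$motifs),
      " WTA motifs\n", sep = "")
  invisible(x)
}

#' Compile a Sudoku puzzle into a WTA spiking network
#'
#' Creates `81 * 9 * N_E` pyramidal cells (one group of `N_E` cells per
#' field and digit), 81 field-uniqueness WTA motifs and `27 * 9 = 243`
#' group-uniqueness motifs (one per row/column/subgrid and digit), each a
#' single inhibitory neuron reciprocally connected to its member cells, so
#' that every pyramidal cell participates in exactly 4 motifs.  Givens are
#' clamped by strong positive currents to the cells coding the given digit
#' and negative currents to the other digits' cells in that field.
#'
#' @param puzzle a [sudoku_puzzle()].
#' @param params a [csp_params()]; `params$N_E` cells per digit group.
#' @return a `"csp_network"` with the puzzle attached.
#' @export
encode_sudoku <- function(puzzle, params = csp_params()) {
  stopifnot(inherits(puzzle, "sudoku_puzzle"))
  units <- sudoku_units()
  groups <- unlist(lapply(units, function(u)
    lapply(1:9, function(d) cbind(var = u, value = d))),
    recursive = FALSE)
  v <- as.integer(t(puzzle$cells))
  giv <- which(v > 0)
  clamps <- data.frame(var = giv, value = v[giv])
  cn <- encode_generic_csp(rep(9L, 81L), groups, clamps, params)
  cn$puzzle <- puzzle
  cn
}

#' Simulate a WTA constraint-satisfaction network (event-driven)
#'
#' Runs the exact event-driven backend: with rectangular current pulses and
#' a quasi-static membrane the hazard is piecewise constant and next-spike
#' times can be sampled exactly.  Optionally tracks the decoded assignment
#' against a known target on a regular check grid and stops at the first
#' time the full target is decoded.
#'
#' @param cnet a `"csp_network"`.
#' @param duration biological time (ms).
#' @param seed RNG seed.
#' @param record `"none"`, `"pyramidal"` or `"all"`: which spikes to keep.
#' @param check_dt decode-check interval (ms); 0 disables tracking.
#' @param stop_on_solve stop at the first check with performance 1.
#' @param target integer vector (one value per variable) the online decoder
#'   compares against; defaults to the attached puzzle's solution.
#' @return list with `spikes` (a [spike_record()]), `perf` (data frame
#'   `time_ms`, `performance`), `solve_time` (ms or `NA`).
#' @export
simulate_csp <- function(cnet, duration, seed = 1L,
                         record = c("none", "pyramidal", "all"),
                         check_dt = 10, stop_on_solve = FALSE,
                         target = NULL) {
  stopifnot(inherits(cnet, "csp_network"))
  record <- match.arg(record)
  nd <- cnet$net$neurons
  n <- nrow(nd)
  if (is.null(target) && !is.null(cnet$puzzle$solution))
    target <- as.integer(t(cnet$puzzle$solution))
  track <- check_dt > 0 && !is.null(target)
  if (track) stopifnot(length(target) == cnet$n_vars)
  sd <- cnet$net$synapses
  o <- order(sd$pre)
  sd <- sd[o, ]
  syn_off <- c(0L, cumsum(tabulate(sd$pre, nbins = n)))
  sgn <- ifelse(nd$is_inhibitory[sd$pre], -1, 1)
  mask <- switch(record,
                 none = rep(FALSE, n),
                 pyramidal = seq_len(n) <= cnet$n_pyr,
                 all = rep(TRUE, n))
  cf <- c(cnet$cell_var - 1L, rep(-1L, n - cnet$n_pyr))
  cv <- c(cnet$cell_val - 1L, rep(-1L, n - cnet$n_pyr))
  res <- sim_events_run(
    V_base = nd$E_rest + nd$bias_current / nd$g_leak,
    r0 = nd$r0, V_T = nd$V_T, dV = nd$dV, r_max = nd$r_max,
    refr = nd$refractory_abs,
    syn_off = syn_off, syn_target = sd$post - 1L,
    syn_amp = sgn * sd$weight / nd$g_leak[sd$post],
    syn_delay = sd$delay, syn_pulse = sd$pulse_length,
    syn_stp = as.integer(!is.na(sd$U)),
    syn_U = ifelse(is.na(sd$U), 0, sd$U),
    syn_D = ifelse(is.na(sd$D), 1, sd$D),
    syn_F = ifelse(is.na(sd$F), 1, sd$F),
    record_mask = mask,
    cell_field = if (track) cf else rep(-1L, n),
    cell_digit = cv,
    correct_digit = if (track) target - 1L else integer(0),
    n_fields = if (track) cnet$n_vars else 0L,
    n_digits = max(cnet$n_values),
    tau = cnet$params$tau, check_dt = check_dt,
    stop_on_solve = stop_on_solve, duration = duration, seed = seed)
  perf <- if (track)
    data.frame(time_ms = seq_along(res$perf) * check_dt,
               performance = res$perf)
  else NULL
  list(spikes = spike_record(res$neuron_id, res$time_ms,
                             duration = duration, n_neurons = n),
       perf = perf, solve_time = res$solve_time)
}

#' Decode the tentative assignment from spikes
#'
#' Value `d` is active for variable `v` at time `t` iff any of its `N_E`
#' cells spiked within `(t - tau, t]`.
#'
#' @param spikes a [spike_record()] of a CSP simulation (pyramidal spikes
#'   recorded).
#' @param cnet the `"csp_network"`.
#' @param t decoding time (ms), `>= tau`.
#' @param tau decoding window (ms); defaults to the network's.
#' @return list (one element per variable) of active value sets (integer
#'   vectors, possibly empty or longer than 1).
#' @export
csp_decode <- function(spikes, cnet, t, tau = cnet$params$tau) {
  if (t < tau) stop("t must be >= tau")
  sel <- spikes$neuron_id <= cnet$n_pyr &
    spikes$time_ms > t - tau & spikes$time_ms <= t
  ids <- spikes$neuron_id[sel]
  act <- unique(data.frame(var = cnet$cell_var[ids],
                           val = cnet$cell_val[ids]))
  out <- rep(list(integer(0)), cnet$n_vars)
  if (nrow(act))
    for (r in seq_len(nrow(act)))
      out[[act$var[r]]] <- sort(c(out[[act$var[r]]], act$val[r]))
  out
}

#' Fraction of variables decoded to their target value
#'
#' In the default `"singleton"` mode a variable counts as correct iff its
#' active set is exactly the singleton target value; in `"lenient"` mode it
#' suffices that the target value is active, extra active values are
#' ignored.
#'
#' @inheritParams csp_decode
#' @param target per-variable target values; defaults to the puzzle
#'   solution.
#' @param mode `"singleton"` (default) or `"lenient"`.
#' @return fraction in `[0, 1]`.
#' @export
csp_performance <- function(spikes, cnet, t, tau = cnet$params$tau,
                            target = NULL,
                            mode = c("singleton", "lenient")) {
  mode <- match.arg(mode)
  if (is.null(target)) {
    if (is.null(cnet$puzzle$solution)) stop("no target/solution available")
    target <- as.integer(t(cnet$puzzle$solution))
  }
  dec <- csp_decode(spikes, cnet, t, tau)
  ok <- vapply(seq_len(cnet$n_vars), function(v) {
    a <- dec[[v]]
    if (mode == "singleton") length(a) == 1L && a == target[v]
    else target[v] %in% a
  }, logical(1))
  mean(ok)
}

#' First time the full target assignment is decoded
#'
#' @inheritParams csp_performance
#' @param grid decoding times (ms) scanned in order.
#' @return earliest grid time with performance 1, or `NA` if never.
#' @export
csp_solve_time <- function(spikes, cnet, tau = cnet$params$tau,
                           grid = seq(tau, attr(spikes, "duration"),
                                      by = tau),
                           target = NULL) {
  for (t in grid) {
    if (csp_performance(spikes, cnet, t, tau, target) >= 1) return(t)
  }
  NA_real_
}

#' Repeated-run Sudoku experiment
#'
#' Runs independent seeded simulations of the WTA Sudoku network and
#' collects solve times (first time the decoded assignment equals the full
#' solution), the mean performance curve, and the correct-solution
#' occupancy (fraction of post-burn-in check times at which performance
#' equals 1, averaged over runs).
#'
#' @param puzzle a [sudoku_puzzle()] with solution.
#' @param runs number of independent runs.
#' @param max_duration per-run duration cap (ms).
#' @param seed experiment seed; run seeds are derived from it.
#' @param params a [csp_params()].
#' @param check_dt decode-check interval (ms).
#' @param burn_in discarded initial period for occupancy (ms).
#' @param stop_on_solve stop each run at its solve time (for solve-time
#'   statistics; performance/occupancy are then only collected up to it).
#' @return list with `solve_times` (ms; `NA` for unsolved runs),
#'   `n_unsolved`, `perf_times`/`perf_mean` (mean performance curve over
#'   runs), and `occupancy` (pooled fraction).
#' @export
sudoku_experiment <- function(puzzle, runs, max_duration, seed = 1L,
                              params = csp_params(), check_dt = 10,
                              burn_in = 10000, stop_on_solve = FALSE) {
  stopifnot(runs >= 1)
  cnet <- encode_sudoku(puzzle, params)
  solve_times <- rep(NA_real_, runs)
  n_checks <- ceiling(max_duration / check_dt)
  perf_sum <- numeric(n_checks)
  perf_cnt <- numeric(n_checks)
  occ_hit <- 0; occ_tot <- 0
  for (r in seq_len(runs)) {
    res <- simulate_csp(cnet, max_duration, seed = seed + 7919L * r,
                        record = "none", check_dt = check_dt,
                        stop_on_solve = stop_on_solve)
    solve_times[r] <- res$solve_time
    k <- nrow(res$perf)
    perf_sum[seq_len(k)] <- perf_sum[seq_len(k)] + res$perf$performance
    perf_cnt[seq_len(k)] <- perf_cnt[seq_len(k)] + 1
    post <- res$perf$time_ms > burn_in
    occ_hit <- occ_hit + sum(res$perf$performance[post] >= 1)
    occ_tot <- occ_tot + sum(post)
  }
  keep <- perf_cnt > 0
  list(solve_times = solve_times,
       n_unsolved = sum(is.na(solve_times)),
       perf_times = (seq_len(n_checks) * check_dt)[keep],
       perf_mean = (perf_sum / pmax(perf_cnt, 1))[keep],
       occupancy = if (occ_tot > 0) occ_hit / occ_tot else NA_real_)
}
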
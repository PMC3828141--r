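#' Exact discretized transition kernel of a tiny network
#'
#' Enumerates the Markov chain obtained by discretizing a small network's
#' dynamics into time bins of width `dt` with a spike/silence history of
#' depth `k` bins per neuron.  The state space is all `2^(n*k)` binary
#' histories; the kernel entry for a transition is the product over neurons
#' of the per-bin Bernoulli spike probabilities `1 - exp(-r(V) dt)` implied
#' by the escape hazard, the rectangular current-pulse synapses replayed
#' over the history bins, and absolute refractoriness.
#'
#' The discretization is exact for the time-stepped simulator run at the
#' same `dt` in the fast-membrane (quasi-static) regime, where the membrane
#' potential in a step is the steady-state value
#' `E_rest + (bias + sum of active pulses) / g_leak`; for slower membranes
#' it is an approximation that refines as `dt` shrinks.
#'
#' State encoding: states are numbered `0 ... 2^(n*k)-1` (row `code + 1`),
#' with bit `(l-1)*n + (i-1)` set iff neuron `i` spiked at lag `l` bins
#' (lag 1 = most recent).  The resting state is code 0.
#'
#' @param net a [network_model()] with at most `n*k <= 12` history bits;
#'   all synapses must be `"current-rect"` (delays and pulse lengths are
#'   rounded to whole bins and must be covered by the history depth).
#' @param dt bin width (ms).
#' @param k history depth in bins.
#' @return an object of class `"discretized_chain"`: list with the
#'   row-stochastic `P`, `n_neurons`, `k`, `dt`, `resting_index` and the
#'   total-rate bound `Lambda` (sum of the neurons' rate caps, 1/ms).
#' @export
build_kernel <- function(net, dt, k) {
  stopifnot(inherits(net, "network_model"))
  n <- n_neurons(net)
  if (n * k > 12L) stop("state space too large (need n*k <= 12)")
  if (any(net$is_input)) stop("the oracle handles autonomous networks only")
  sd <- net$synapses
  if (nrow(sd) && any(sd$kind != "current-rect"))
    stop("the oracle requires current-rect synapses")
  nd <- net$neurons
  delay_b <- if (nrow(sd)) pmax(1L, as.integer(round(sd$delay / dt))) else integer(0)
  pulse_b <- if (nrow(sd)) pmax(1L, as.integer(round(sd$pulse_length / dt))) else integer(0)
  if (nrow(sd) && any(delay_b + pulse_b - 1L > k))
    stop("history depth k too small for the synaptic delays/pulses")
  refr_b <- as.integer(round(nd$refractory_abs / dt))
  if (any(refr_b > k))
    stop("history depth k too small for the refractory periods")
  n_states <- 2L^(n * k)
  # per-(neuron, lag) signed potential contribution to each target
  contrib <- matrix(0, n * k, n)  # rows: bit positions, cols: target neuron
  if (nrow(sd)) {
    for (j in seq_len(nrow(sd))) {
      sgn <- if (nd$is_inhibitory[sd$pre[j]]) -1 else 1
      lags <- delay_b[j]:(delay_b[j] + pulse_b[j] - 1L)
      amp <- sgn * sd$weight[j] / nd$g_leak[sd$post[j]]
      for (l in lags)
        contrib[(l - 1L) * n + sd$pre[j], sd$post[j]] <-
          contrib[(l - 1L) * n + sd$pre[j], sd$post[j]] + amp
    }
  }
  V0 <- nd$E_rest + nd$bias_current / nd$g_leak
  # bit matrix of all states: n_states x (n*k)
  bits <- outer(0:(n_states - 1L), 0:(n * k - 1L),
                function(s, b) bitwAnd(bitwShiftR(s, b), 1L))
  V <- matrix(rep(V0, each = n_states), n_states, n) + bits %*% contrib
  r <- pmin(matrix(rep(nd$r0, each = n_states), n_states, n) *
              exp((V - matrix(rep(nd$V_T, each = n_states), n_states, n)) /
                    matrix(rep(nd$dV, each = n_states), n_states, n)),
            matrix(rep(nd$r_max, each = n_states), n_states, n))
  p_spike <- -expm1(-r * dt)
  # refractory: neuron i blocked if it spiked at any lag <= refr_b[i]
  for (i in seq_len(n)) {
    if (refr_b[i] >= 1L) {
      blocked <- rep(FALSE, n_states)
      for (l in seq_len(refr_b[i]))
        blocked <- blocked | bits[, (l - 1L) * n + i] == 1L
      p_spike[blocked, i] <- 0
    }
  }
  # assemble P: new state shifts history by one bin and prepends new spikes
  P <- matrix(0, n_states, n_states)
  shift_mask <- bitwShiftL(1L, n * (k - 1L)) - 1L
  spike_pats <- 0:(2L^n - 1L)
  spike_bits <- outer(spike_pats, 0:(n - 1L),
                      function(s, b) bitwAnd(bitwShiftR(s, b), 1L))
  for (s in seq_len(n_states)) {
    base <- bitwShiftL(bitwAnd(s - 1L, shift_mask), n)
    p <- p_spike[s, ]
    for (z in seq_along(spike_pats)) {
      pr <- prod(ifelse(spike_bits[z, ] == 1L, p, 1 - p))
      if (pr > 0) {
        tgt <- base + spike_pats[z] + 1L
        P[s, tgt] <- P[s, tgt] + pr
      }
    }
  }
  new_discretized_chain(P, n, k, dt, Lambda = sum(nd$r_max))
}

#' Construct a discretized chain from an explicit transition matrix
#'
#' Mainly for toy chains in tests and for the phase-stationarity machinery;
#' [build_kernel()] is the network-driven constructor.
#'
#' @param P row-stochastic matrix over `2^(n_neurons*k)` binary-history
#'   states (resting state = first row).
#' @param n_neurons,k state-space dimensions.
#' @param dt bin width (ms).
#' @param Lambda optional total rate bound (1/ms) stored as metadata.
#' @return a `"discretized_chain"`.
#' @export
new_discretized_chain <- function(P, n_neurons, k, dt = 1, Lambda = NULL) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (nrow(P) != 2^(n_neurons * k))
    stop("P must have 2^(n_neurons*k) states")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12)) stop("P rows must sum to 1 (within 1e-12)")
  if (any(P < 0)) stop("P must be nonnegative")
  structure(list(P = P, n_neurons = n_neurons, k = k, dt = dt,
                 resting_index = 1L, Lambda = Lambda),
            class = "discretized_chain")
}

#' @export
print.discretized_chain <- function(x, ...) {
  cat("<discretized_chain> ", x$n_neurons, " neuron(s), history depth ",
      x$k, " bins of ", x$dt, " ms (", nrow(x$P), " states)\n", sep = "")
  invisible(x)
}

#' Total variation distance (un-halved)
#'
#' The total mass of the positive and negative components of `mu - nu`,
#' i.e. `sum(abs(mu - nu))`; ranges from 0 to 2.
#'
#' @param mu,nu probability vectors over the same support.
#' @return nonnegative scalar.
#' @export
tv_distance <- function(mu, nu) {
  if (length(mu) != length(nu)) stop("distributions must share their support")
  sum(abs(mu - nu))
}

#' Verify the contraction property on a discretized chain
#'
#' Computes the Doeblin coefficient `alpha`: the minimum over initial
#' states of the probability of reaching the resting (all-silent) state
#' after `steps` bins, and checks for every supplied distribution pair that
#' one application of the `steps`-bin kernel contracts their total
#' variation distance by at least the factor `(1 - alpha)`.  When the chain
#' carries a total rate bound `Lambda`, `alpha >= exp(-Lambda * steps * dt)`
#' (the probability that no neuron fires for a full memory window) is also
#' checked.
#'
#' @param chain a [build_kernel()] / [new_discretized_chain()] result.
#' @param steps number of bins the kernel is applied for; must cover one
#'   full memory window (`steps >= k`).
#' @param pairs list of `list(mu, nu)` probability-vector pairs; by default
#'   `n_pairs` pairs are drawn uniformly from the probability simplex.
#' @param n_pairs,seed number of random pairs and the seed used to draw
#'   them when `pairs` is not given.
#' @return list with `alpha`, `worst_ratio` (max observed
#'   `tv_after / tv_before`), `contraction_holds`, `alpha_lower_bound`
#'   (`exp(-Lambda*tau)` or `NA`) and `n_pairs`.
#' @export
verify_contraction <- function(chain, steps, pairs = NULL, n_pairs = 100,
                               seed = 1L) {
  stopifnot(inherits(chain, "discretized_chain"))
  if (steps < chain$k) stop("steps must cover one memory window (>= k)")
  Pm <- matrix_power(chain$P, steps)
  alpha <- min(Pm[, chain$resting_index])
  if (alpha == 0)
    stop("alpha = 0: chain is insufficiently stochastic for the ",
         "contraction argument (deterministic transitions present)")
  ns <- nrow(Pm)
  if (is.null(pairs)) {
    pairs <- with_seed(seed, lapply(seq_len(n_pairs), function(i) {
      list(mu = prop.table(rexp(ns)), nu = prop.table(rexp(ns)))
    }))
  }
  ratios <- vapply(pairs, function(pr) {
    before <- tv_distance(pr$mu, pr$nu)
    if (before == 0) return(0)
    after <- tv_distance(as.numeric(pr$mu %*% Pm), as.numeric(pr$nu %*% Pm))
    after / before
  }, numeric(1))
  bound <- if (is.null(chain$Lambda)) NA_real_
           else exp(-chain$Lambda * steps * chain$dt)
  ok_bound <- is.na(bound) || alpha >= bound - 1e-12
  list(alpha = alpha,
       worst_ratio = max(ratios),
       contraction_holds = all(ratios <= (1 - alpha) + 1e-10) && ok_bound,
       alpha_lower_bound = bound,
       n_pairs = length(pairs))
}

matrix_power <- function(P, m) {
  R <- diag(nrow(P))
  B <- P
  while (m > 0) {
    if (m %% 2 == 1) R <- R %*% B
    m <- m %/% 2
    if (m > 0) B <- B %*% B
  }
  R
}

#' Stationary distribution of a discretized chain
#'
#' Left fixed point of the transition matrix, computed by power iteration;
#' convergence is geometric with ratio `(1 - alpha)` per memory window once
#' the Doeblin coefficient `alpha` is positive.
#'
#' @param chain a `"discretized_chain"`.
#' @param tol iteration stops when successive iterates are within this
#'   total-variation distance.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return probability vector over the chain's states.
#' @export
stationary_distribution <- function(chain, tol = 1e-12, max_iter = 100000L) {
  stationary_of_matrix(chain$P, tol, max_iter)
}

stationary_of_matrix <- function(P, tol = 1e-12, max_iter = 100000L) {
  mu <- rep(1 / nrow(P), nrow(P))
  for (it in seq_len(max_iter)) {
    mu_new <- as.numeric(mu %*% P)
    if (tv_distance(mu, mu_new) < tol) {
      mu_new <- mu_new / sum(mu_new)
      names(mu_new) <- NULL
      return(mu_new)
    }
    mu <- mu_new
  }
  stop("power iteration did not converge within max_iter")
}

#' Phase-specific stationary distributions of a periodically driven chain
#'
#' Given one transition kernel per phase bin of a periodic input,
#' `P_1, ..., P_L`, the phase-`l` stationary distribution is the fixed
#' point of the cyclic product `P_l P_{l+1} ... P_{l-1}`; consecutive phase
#' distributions satisfy `p(phi_{l+1}) = p(phi_l) P_l`.
#'
#' @param kernels list of row-stochastic matrices (or
#'   `"discretized_chain"`s) sharing one state space, one per phase bin.
#' @param tol power-iteration tolerance.
#' @return list of probability vectors, one per phase.
#' @export
phase_stationary <- function(kernels, tol = 1e-12) {
  Ps <- lapply(kernels, function(kk)
    if (inherits(kk, "discretized_chain")) kk$P else kk)
  L <- length(Ps)
  if (!L) stop("need at least one phase kernel")
  ns <- nrow(Ps[[1]])
  for (P in Ps) {
    if (nrow(P) != ns || ncol(P) != ns) stop("kernels must share a state space")
    if (any(abs(rowSums(P) - 1) > 1e-12)) stop("kernels must be row-stochastic")
  }
  cyc <- Reduce(`%*%`, Ps)
  p <- vector("list", L)
  p[[1]] <- stationary_of_matrix(cyc, tol = tol)
  if (L > 1) for (l in 2:L)
    p[[l]] <- as.numeric(p[[l - 1]] %*% Ps[[l - 1]])
  p
}

#' Empirical distribution over discretized spike histories
#'
#' Companion to [build_kernel()]: reads the same depth-`k` binary history
#' states off a simulated [spike_record()], sampling at every bin boundary,
#' and returns the empirical distribution over all `2^(n*k)` states (in
#' kernel state order).  Used to cross-check the simulator against the
#' oracle's stationary distribution.
#'
#' @param spikes a [spike_record()].
#' @param n_neurons number of neurons of the network.
#' @param dt bin width (ms), matching the kernel's.
#' @param k history depth in bins.
#' @param t_start,t_end sampling window (ms).
#' @return probability vector of length `2^(n_neurons*k)`.
#' @export
history_distribution <- function(spikes, n_neurons, dt, k,
                                 t_start = attr(spikes, "duration") / 2,
                                 t_end = attr(spikes, "duration")) {
  m0 <- ceiling(t_start / dt)
  m1 <- floor(t_end / dt)
  if (m1 - m0 < 1) stop("sampling window too short")
  times <- (m0:m1) * dt
  by_neuron <- spike_times(spikes, seq_len(n_neurons))
  code <- numeric(length(times))
  for (l in seq_len(k)) {
    for (i in seq_len(n_neurons)) {
      v <- by_neuron[[i]]
      hit <- (findInterval(times - (l - 1) * dt + 1e-9, v) -
                findInterval(times - l * dt + 1e-9, v)) > 0
      code <- code + hit * 2^((l - 1) * n_neurons + i - 1)
    }
  }
  tab <- tabulate(code + 1, nbins = 2^(n_neurons * k))
  tab / sum(tab)
}
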
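#' Configuration for network-state extraction
#'
#' Network states are read off spike trains through two trailing windows:
#' the Markov-state window `T` (complete recent spike history) and the
#' shorter simple-state window `tau` (binary "spiked recently" indicator per
#' neuron).  Both windows are half-open, `(t - w, t]`: a spike exactly at
#' the sampling instant counts, a spike exactly at the window's left edge
#' does not.
#'
#' @param T Markov-state window length (ms).
#' @param tau simple-state window length (ms); `0 < tau <= T`.
#' @param dt_sample grid spacing (ms) used when sampling states over time.
#' @param subset optional integer vector of neuron ids states are restricted
#'   to (default: all neurons of the record).
#' @return an object of class `"state_config"`.
#' @export
state_config <- function(T = 100, tau = 20, dt_sample = 1, subset = NULL) {
  if (!(tau > 0 && tau <= T)) stop("need 0 < tau <= T")
  if (dt_sample <= 0) stop("dt_sample must be > 0")
  structure(list(T = T, tau = tau, dt_sample = dt_sample,
                 subset = if (is.null(subset)) NULL else as.integer(subset)),
            class = "state_config")
}

cfg_subset <- function(spikes, cfg) {
  if (!is.null(cfg$subset)) cfg$subset else seq_len(attr(spikes, "n_neurons"))
}

# activity matrix: rows = sample times, cols = subset neurons;
# entry 1 iff the neuron spiked in (t - tau, t]
activity_matrix <- function(spikes, times, subset, tau) {
  by_neuron <- spike_times(spikes, subset)
  m <- vapply(by_neuron, function(v) {
    (findInterval(times, v) - findInterval(times - tau, v)) > 0
  }, logical(length(times)))
  matrix(as.integer(m), nrow = length(times),
         dimnames = list(NULL, as.character(subset)))
}

#' Simple network state at a time point
#'
#' The binary vector whose i-th bit is 1 iff neuron i of the subset emitted
#' at least one spike within the trailing window `(t - tau, t]`.
#'
#' @param spikes a [spike_record()].
#' @param t sampling time (ms); must be `>= tau`.
#' @param cfg a [state_config()].
#' @return integer 0/1 vector, one bit per subset neuron.
#' @export
simple_state <- function(spikes, t, cfg = state_config()) {
  if (t < cfg$tau) stop("t must be >= tau")
  subset <- cfg_subset(spikes, cfg)
  as.integer(activity_matrix(spikes, t, subset, cfg$tau))
}

#' Markov network state at a time point
#'
#' The per-neuron lists of recent spike times within the trailing window
#' `(t - T, t]`, expressed relative to the window start `t - T` (offsets in
#' `(0, T]`, ascending).  The all-empty state is the resting state.
#' Restricting offsets to the last `tau` of the window and binarizing
#' reproduces [simple_state()].
#'
#' @inheritParams simple_state
#' @return an object of class `"markov_state"`: a list of numeric vectors.
#' @export
markov_state <- function(spikes, t, cfg = state_config()) {
  if (t < cfg$T) stop("t must be >= T")
  subset <- cfg_subset(spikes, cfg)
  by_neuron <- spike_times(spikes, subset)
  out <- lapply(by_neuron, function(v) {
    v[v > t - cfg$T & v <= t] - (t - cfg$T)
  })
  structure(out, class = "markov_state", T = cfg$T, t = t)
}

#' @export
print.markov_state <- function(x, ...) {
  cat("<markov_state> T =", attr(x, "T"), "ms,",
      sum(lengths(x)), "spikes in window")
  if (!sum(lengths(x))) cat(" (resting state)")
  cat("\n")
  invisible(x)
}

#' Is a Markov state the resting state?
#' @param state a [markov_state()].
#' @return logical.
#' @export
is_resting_state <- function(state) sum(lengths(state)) == 0L

new_empirical_distribution <- function(states, freq, n_samples,
                                       phase = NULL, period = NULL) {
  o <- order(states)
  structure(list(states = states[o], freq = freq[o],
                 n_samples = n_samples, phase = phase, period = period),
            class = "empirical_distribution")
}

#' @export
print.empirical_distribution <- function(x, n = 10L, ...) {
  cat("<empirical_distribution> ", length(x$states), " states, ",
      x$n_samples, " samples", sep = "")
  if (!is.null(x$phase))
    cat(", phase ", x$phase, " ms of period ", x$period, " ms", sep = "")
  cat("\n")
  o <- order(-x$freq)
  show <- head(o, n)
  for (i in show) cat(sprintf("  %s  %.4f\n", x$states[i], x$freq[i]))
  if (length(o) > n) cat("  ...\n")
  invisible(x)
}

bits_to_key <- function(m) {
  apply(m, 1L, paste0, collapse = "")
}

#' Empirical distribution of simple network states
#'
#' Samples the simple state on the regular grid `t_start, t_start +
#' dt_sample, ..., <= t_end` and normalizes the state frequencies, i.e.
#' measures the relative time spent in each simple state.
#'
#' @inheritParams simple_state
#' @param t_start,t_end sampling window (ms); `t_start` must be `>= tau`.
#' @return an `"empirical_distribution"`: states as bit-strings with their
#'   relative frequencies.
#' @export
empirical_distribution <- function(spikes, cfg = state_config(),
                                   t_start = cfg$tau,
                                   t_end = attr(spikes, "duration")) {
  if (t_end - t_start < cfg$dt_sample) stop("empty sampling grid")
  times <- seq(t_start, t_end, by = cfg$dt_sample)
  if (t_start < cfg$tau) stop("t_start must be >= tau")
  subset <- cfg_subset(spikes, cfg)
  keys <- bits_to_key(activity_matrix(spikes, times, subset, cfg$tau))
  tab <- table(keys)
  new_empirical_distribution(names(tab), as.numeric(tab) / length(keys),
                             length(keys))
}

#' Marginal state probability of a subset of neurons
#'
#' The relative time a set of neurons spends in a given joint binary state,
#' i.e. the marginal of the simple-state distribution.  For a single neuron
#' and target 1 this is the fraction of grid points at which the neuron was
#' recently active.
#'
#' @inheritParams empirical_distribution
#' @param neuron_set integer ids of the neurons marginalized onto.
#' @param target_state 0/1 vector, one bit per neuron of `neuron_set`.
#' @param window length-2 vector `c(t_start, t_end)`.
#' @return probability in `[0, 1]`.
#' @export
estimate_marginal <- function(spikes, neuron_set, target_state,
                              cfg = state_config(),
                              window = c(cfg$tau, attr(spikes, "duration"))) {
  stopifnot(length(target_state) == length(neuron_set),
            all(target_state %in% 0:1))
  cfg$subset <- as.integer(neuron_set)
  d <- empirical_distribution(spikes, cfg, window[1], window[2])
  key <- paste0(as.integer(target_state), collapse = "")
  i <- match(key, d$states)
  if (is.na(i)) 0 else d$freq[i]
}

#' Maximum a-posteriori state of an empirical distribution
#'
#' Returns the state with the highest frequency; ties are broken towards the
#' lexicographically smallest bit-string.
#'
#' @param dist an `"empirical_distribution"`.
#' @return the winning state as a bit-string.
#' @export
map_readout <- function(dist) {
  if (!length(dist$states)) stop("empty distribution")
  best <- which(dist$freq == max(dist$freq))
  # states are stored sorted, so the first tie is the lexicographic minimum
  dist$states[best[1L]]
}

#' Phase-specific distribution of network states under periodic input
#'
#' Under input with period `T_per`, network states sampled at a fixed phase
#' of the cycle converge to a phase-specific stationary distribution.  This
#' samples the simple state only at times `t_burn + phase + k * T_per`,
#' `k = 0, ..., n_cycles - 1`.
#'
#' @inheritParams empirical_distribution
#' @param T_per input period (ms).
#' @param phase phase within the cycle, `0 <= phase < T_per`.
#' @param n_cycles number of cycles sampled.
#' @param t_burn burn-in discarded before sampling (ms); defaults to half
#'   the record.
#' @return an `"empirical_distribution"` tagged with `phase` and `period`.
#' @export
phase_distribution <- function(spikes, cfg = state_config(), T_per, phase,
                               n_cycles,
                               t_burn = attr(spikes, "duration") / 2) {
  if (phase < 0 || phase >= T_per) stop("need 0 <= phase < T_per")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  duration <- attr(spikes, "duration")
  if (duration - t_burn < T_per) stop("record shorter than one cycle after burn-in")
  times <- t_burn + phase + (seq_len(n_cycles) - 1) * T_per
  if (max(times) > duration)
    stop("record too short for the requested number of cycles")
  subset <- cfg_subset(spikes, cfg)
  keys <- bits_to_key(activity_matrix(spikes, times, subset, cfg$tau))
  tab <- table(keys)
  new_empirical_distribution(names(tab), as.numeric(tab) / length(keys),
                             length(keys), phase = phase, period = T_per)
}

#' Distribution over trajectories of simple states
#'
#' States are tuples of consecutive simple states sampled `dt_sample` apart
#' and spanning a total length `L`; at `L = dt_sample` (a single sample)
#' this reduces to [empirical_distribution()].  Trajectories are read off a
#' sliding window over the sampling grid.
#'
#' @inheritParams empirical_distribution
#' @param L trajectory length (ms), a multiple of `dt_sample`.
#' @return an `"empirical_distribution"` whose states are `;`-separated
#'   simple-state bit-strings.
#' @export
trajectory_distribution <- function(spikes, cfg = state_config(), L,
                                    t_start = cfg$tau,
                                    t_end = attr(spikes, "duration")) {
  m <- L / cfg$dt_sample
  if (abs(m - round(m)) > 1e-9) stop("L must be a multiple of dt_sample")
  m <- as.integer(round(m))
  if (m < 1L) stop("L too short")
  times <- seq(t_start, t_end, by = cfg$dt_sample)
  if (length(times) < m) stop("record too short for trajectories of length L")
  subset <- cfg_subset(spikes, cfg)
  keys <- bits_to_key(activity_matrix(spikes, times, subset, cfg$tau))
  n_traj <- length(keys) - m + 1L
  traj <- vapply(seq_len(n_traj), function(i)
    paste0(keys[i:(i + m - 1L)], collapse = ";"), character(1))
  tab <- table(traj)
  new_empirical_distribution(names(tab), as.numeric(tab) / n_traj, n_traj)
}

#' Detect transitions between two attractor pools
#'
#' A pool counts as active at a grid time iff more than two of its neurons
#' have an active simple state.  A transition is a maximal period with pool
#' A active and B inactive, followed (possibly after an intermediate period
#' in which both or neither pool is active) by a period with B active and A
#' inactive; its time is the midpoint of the intermediate period and, if a
#' period `T_per` is given, its phase is `time %% T_per`.
#'
#' @inheritParams empirical_distribution
#' @param pool_A,pool_B disjoint integer id sets of the two pools.
#' @param T_per optional input period (ms) used to attach phases.
#' @return data frame with columns `time` and `phase` (`NA` without
#'   `T_per`), one row per transition (in either direction).
#' @export
detect_attractor_transitions <- function(spikes, pool_A, pool_B,
                                         cfg = state_config(), T_per = NULL,
                                         t_start = cfg$tau,
                                         t_end = attr(spikes, "duration")) {
  if (length(intersect(pool_A, pool_B))) stop("pools must be disjoint")
  times <- seq(t_start, t_end, by = cfg$dt_sample)
  actA <- rowSums(activity_matrix(spikes, times, as.integer(pool_A),
                                  cfg$tau)) > 2
  actB <- rowSums(activity_matrix(spikes, times, as.integer(pool_B),
                                  cfg$tau)) > 2
  lab <- integer(length(times))          # 0 = intermediate
  lab[actA & !actB] <- 1L
  lab[actB & !actA] <- 2L
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out_t <- numeric(0)
  pure <- which(r$values != 0L)
  if (length(pure) >= 2L) {
    for (k in seq_len(length(pure) - 1L)) {
      a <- pure[k]; b <- pure[k + 1L]
      if (r$values[a] != r$values[b]) {
        # midpoint of the intermediate stretch (or of the boundary if none)
        t0 <- times[ends[a]]; t1 <- times[starts[b]]
        out_t <- c(out_t, (t0 + t1) / 2)
      }
    }
  }
  data.frame(time = out_t,
             phase = if (is.null(T_per)) rep(NA_real_, length(out_t))
                     else out_t %% T_per)
}
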
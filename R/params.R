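#' Neuron parameters for the escape-noise leaky integrate-and-fire model
#'
#' Constructs a validated parameter set for a stochastic leaky
#' integrate-and-fire neuron.  Instead of a hard threshold, the neuron fires
#' with a voltage-dependent instantaneous rate (escape noise), see
#' [hazard_rate()].  Units follow the package convention: mV, ms, nS, pF, pA.
#'
#' @param g_leak leak conductance (nS).
#' @param C_m membrane capacitance (pF); the membrane time constant is
#'   `C_m / g_leak` ms.
#' @param E_rest resting (and reset) potential (mV).
#' @param E_exc,E_inh reversal potentials of excitatory and inhibitory
#'   conductance-based synapses (mV); must satisfy `E_exc > E_rest > E_inh`.
#' @param r0 hazard rate at threshold (1/ms).
#' @param V_T soft threshold of the exponential hazard (mV).
#' @param dV slope (e-fold voltage) of the exponential hazard (mV).
#' @param r_max hard cap on the instantaneous rate (1/ms).  A finite cap
#'   bounds the rate of every neuron at all times, which is what guarantees a
#'   positive return probability to the resting state and hence ergodicity.
#' @param refractory_abs absolute refractory period (ms).  After a spike the
#'   membrane is held for this period, then reset to `E_rest`.
#' @param bias_current constant injected current (pA).
#' @param is_inhibitory logical; sign of this neuron's synaptic effect on its
#'   targets (the synapse weight itself is kept nonnegative).
#'
#' @return an object of class `"neuron_params"` (a named list).
#' @export
neuron_params <- function(g_leak = 10, C_m = 200, E_rest = -70,
                          E_exc = 0, E_inh = -75,
                          r0 = 0.01, V_T = -55, dV = 2, r_max = 1,
                          refractory_abs = 3, bias_current = 0,
                          is_inhibitory = FALSE) {
  p <- list(g_leak = g_leak, C_m = C_m, E_rest = E_rest, E_exc = E_exc,
            E_inh = E_inh, r0 = r0, V_T = V_T, dV = dV, r_max = r_max,
            refractory_abs = refractory_abs, bias_current = bias_current,
            is_inhibitory = isTRUE(is_inhibitory))
  num <- p[setdiff(names(p), "is_inhibitory")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1))))
    stop("all neuron parameters must be finite scalars")
  if (r0 <= 0) stop("r0 must be > 0")
  if (dV <= 0) stop("dV must be > 0")
  if (r_max < r0) stop("r_max must be >= r0")
  if (refractory_abs < 0) stop("refractory_abs must be >= 0")
  if (!(E_exc > E_rest && E_rest > E_inh))
    stop("reversal potentials must satisfy E_exc > E_rest > E_inh")
  if (g_leak <= 0 || C_m <= 0) stop("g_leak and C_m must be positive")
  structure(p, class = "neuron_params")
}

#' Voltage-dependent instantaneous firing rate (escape noise)
#'
#' The exponential escape-rate function
#' \deqn{r(V) = \min\{r_0 \exp((V - (V_T + \Delta))/\Delta V),\ r_{max}\}}
#' where `Delta` is an optional threshold offset (used e.g. for periodic
#' threshold modulation).  The hard cap `r_max` keeps rates bounded.
#'
#' @param V membrane potential(s), mV.  Vectorized.
#' @param p a [neuron_params()] object.
#' @param threshold_offset offset added to `V_T` (mV).
#' @return instantaneous rate(s) in 1/ms.
#' @examples
#' p <- neuron_params()
#' hazard_rate(p$V_T, p)   # equals r0 at threshold
#' @export
hazard_rate <- function(V, p, threshold_offset = 0) {
  stopifnot(inherits(p, "neuron_params"))
  if (!all(is.finite(V))) stop("membrane potential must be finite")
  pmin(p$r0 * exp((V - (p$V_T + threshold_offset)) / p$dV), p$r_max)
}

#' Synapse parameters
#'
#' A directed synapse from neuron `pre` to neuron `post`.  Two kinds of
#' postsynaptic response are supported: `"conductance-exp"` (an exponentially
#' decaying conductance increment, reversal chosen by the presynaptic
#' neuron's type) and `"current-rect"` (a rectangular current pulse of
#' length `pulse_length`, used by the event-driven CSP backend).  The weight
#' is a nonnegative magnitude; whether the effect is excitatory or inhibitory
#' is decided by the presynaptic neuron's `is_inhibitory` flag.
#'
#' @param pre,post integer neuron ids (1-based).
#' @param weight nonnegative efficacy: peak conductance (nS) for
#'   `"conductance-exp"`, current amplitude (pA) for `"current-rect"`.
#' @param delay axonal/synaptic delay (ms), must be positive.
#' @param kind `"conductance-exp"` or `"current-rect"`.
#' @param pulse_length rectangular pulse length (ms), `"current-rect"` only.
#' @param U,D,F optional short-term plasticity parameters (utilization,
#'   depression recovery time constant in ms, facilitation time constant in
#'   ms).  All three must be given together; omit for a static synapse.
#' @return an object of class `"synapse_params"`.
#' @export
synapse_params <- function(pre, post, weight, delay = 1,
                           kind = c("conductance-exp", "current-rect"),
                           pulse_length = NULL, U = NULL, D = NULL, F = NULL) {
  kind <- match.arg(kind)
  if (weight < 0) stop("weight must be >= 0 (sign comes from the presynaptic type)")
  if (delay <= 0) stop("delay must be > 0")
  if (kind == "current-rect") {
    if (is.null(pulse_length) || pulse_length <= 0)
      stop("current-rect synapses need a positive pulse_length")
  } else pulse_length <- NA_real_
  stp <- NULL
  if (!is.null(U) || !is.null(D) || !is.null(F)) {
    if (is.null(U) || is.null(D) || is.null(F))
      stop("U, D and F must be supplied together")
    check_stp_params(U, D, F)
    stp <- list(U = U, D = D, F = F)
  }
  structure(list(pre = as.integer(pre), post = as.integer(post),
                 weight = weight, delay = delay, kind = kind,
                 pulse_length = pulse_length, stp = stp),
            class = "synapse_params")
}

check_stp_params <- function(U, D, F) {
  if (!(U > 0 && U <= 1)) stop("U must be in (0, 1]")
  if (D <= 0) stop("D must be > 0")
  if (F <= 0) stop("F must be > 0")
  invisible(TRUE)
}

#' Short-term plasticity amplitudes for a spike train
#'
#' Tsodyks-Markram dynamic-synapse recurrences.  For a presynaptic spike
#' train with interspike intervals `intervals` (ms), the amplitude of the
#' k-th postsynaptic response is `A_k = w * u_k * R_k` with
#' \deqn{u_1 = U,\quad R_1 = 1,}
#' \deqn{u_{k+1} = U + u_k (1-U) e^{-\Delta_k / F},}
#' \deqn{R_{k+1} = 1 + (R_k (1-u_k) - 1) e^{-\Delta_k / D}.}
#' `u` tracks facilitation (utilization of synaptic efficacy), `R` the
#' fraction of recovered resources (depression).
#'
#' @param w static synaptic weight.
#' @param U utilization at the first spike after rest, in (0, 1].
#' @param D depression recovery time constant (ms).
#' @param F facilitation time constant (ms).
#' @param intervals interspike intervals Delta_k (ms), positive; the returned
#'   vector has `length(intervals) + 1` amplitudes (first spike included).
#' @return numeric vector of amplitudes `A_1, ..., A_{K}`.
#' @export
stp_amplitudes <- function(w, U, D, F, intervals = numeric(0)) {
  check_stp_params(U, D, F)
  if (length(intervals) && any(intervals <= 0))
    stop("interspike intervals must be positive")
  n <- length(intervals) + 1L
  u <- U; R <- 1
  A <- numeric(n)
  A[1L] <- w * u * R
  for (k in seq_along(intervals)) {
    d <- intervals[k]
    u_new <- U + u * (1 - U) * exp(-d / F)
    R_new <- 1 + (R * (1 - u) - 1) * exp(-d / D)
    u <- u_new; R <- R_new
    A[k + 1L] <- w * u * R
  }
  A
}

#' Poisson input process specification
#'
#' Describes the firing rate of a group of external Poisson input neurons.
#' Rates are in 1/ms (multiply spikes/s by 1e-3).
#'
#' @param neuron_ids ids of the input neurons driven by this process.
#' @param kind one of `"constant"`, `"periodic"`, `"markov-modulated"`,
#'   `"schedule"`.
#' @param rate constant rate (1/ms) for `"constant"`; ignored otherwise.
#'   May be a vector with one rate per neuron in `neuron_ids`.
#' @param rate_fn for `"periodic"` / `"schedule"`: a function of time (ms)
#'   returning a nonnegative rate (1/ms), applied to all neurons of the
#'   process.  For `"periodic"` the function must have period `period`.
#' @param period period (ms), `"periodic"` only.
#' @param modulator for `"markov-modulated"`: a list with elements
#'   `rates` (vector of per-state rates, 1/ms), `Q_dwell` (vector of mean
#'   dwell times per state, ms) and optionally `P` (row-stochastic transition
#'   matrix between states at jump times; default uniform over other states).
#' @return an object of class `"input_process"`.
#' @export
input_process <- function(neuron_ids, kind = c("constant", "periodic",
                                               "markov-modulated", "schedule"),
                          rate = NULL, rate_fn = NULL, period = NULL,
                          modulator = NULL) {
  kind <- match.arg(kind)
  neuron_ids <- as.integer(neuron_ids)
  if (kind == "constant") {
    if (is.null(rate) || any(rate < 0)) stop("constant input needs rate >= 0")
    if (!length(rate) %in% c(1L, length(neuron_ids)))
      stop("rate must be scalar or one per neuron")
  } else if (kind %in% c("periodic", "schedule")) {
    if (!is.function(rate_fn)) stop(kind, " input needs a rate_fn")
    if (kind == "periodic" && (is.null(period) || period <= 0))
      stop("periodic input needs a positive period")
  } else {
    if (is.null(modulator) || is.null(modulator$rates) ||
        is.null(modulator$Q_dwell))
      stop("markov-modulated input needs modulator$rates and modulator$Q_dwell")
    if (any(modulator$rates < 0) || any(modulator$Q_dwell <= 0))
      stop("modulator rates must be >= 0 and dwell times > 0")
  }
  structure(list(neuron_ids = neuron_ids, kind = kind, rate = rate,
                 rate_fn = rate_fn, period = period, modulator = modulator),
            class = "input_process")
}
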
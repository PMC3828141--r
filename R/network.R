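#' Construct a spiking network model
#'
#' Bundles neuron parameters, directed synapses and external input processes
#' into a validated network description understood by [simulate_network()]
#' and the discretization oracle.
#'
#' Neurons and synapses can be given either as lists of [neuron_params()] /
#' [synapse_params()] objects or directly as data frames with one row per
#' neuron / synapse (the builders use the data-frame form).  Neuron ids are
#' row indices (1-based).  Neurons driven by an [input_process()] are treated
#' as external Poisson input neurons: their spikes are generated from the
#' process rate instead of the membrane hazard.
#'
#' @param neurons list of [neuron_params()] or a data frame with the same
#'   columns.
#' @param synapses list of [synapse_params()] or a data frame with columns
#'   `pre, post, weight, delay, kind, pulse_length, U, D, F` (the last four
#'   may be `NA` for static conductance synapses).
#' @param inputs list of [input_process()] objects.
#' @param threshold_modulation optional list `list(amplitude =, period =)`:
#'   a sinusoidal offset `amplitude * sin(2*pi*t/period)` applied to the
#'   firing threshold `V_T` of every neuron.
#' @param tau_syn_exc,tau_syn_inh decay time constants (ms) of the
#'   excitatory / inhibitory exponential synaptic conductances.
#' @return an object of class `"network_model"`.
#' @export
network_model <- function(neurons, synapses = NULL, inputs = list(),
                          threshold_modulation = NULL,
                          tau_syn_exc = 5, tau_syn_inh = 10) {
  ndf <- as_neuron_df(neurons)
  sdf <- as_synapse_df(synapses)
  n <- nrow(ndf)
  if (n < 1L) stop("network needs at least one neuron")
  if (nrow(sdf)) {
    if (any(sdf$pre < 1L | sdf$pre > n | sdf$post < 1L | sdf$post > n))
      stop("synapse endpoints must reference existing neurons")
    if (any(sdf$delay <= 0)) stop("synaptic delays must be positive")
    if (any(sdf$weight < 0)) stop("synaptic weights must be nonnegative")
    bad <- sdf$kind == "current-rect" &
      (is.na(sdf$pulse_length) | sdf$pulse_length <= 0)
    if (any(bad)) stop("current-rect synapses need a positive pulse_length")
    has_stp <- !is.na(sdf$U)
    if (any(has_stp & (sdf$U <= 0 | sdf$U > 1 | sdf$D <= 0 | sdf$F <= 0)))
      stop("STP parameters must satisfy 0 < U <= 1, D > 0, F > 0")
  }
  if (inherits(inputs, "input_process")) inputs <- list(inputs)
  is_input <- rep(FALSE, n)
  for (ip in inputs) {
    if (!inherits(ip, "input_process")) stop("inputs must be input_process objects")
    if (any(ip$neuron_ids < 1L | ip$neuron_ids > n))
      stop("input process references nonexistent neurons")
    if (any(is_input[ip$neuron_ids]))
      stop("a neuron may be driven by at most one input process")
    is_input[ip$neuron_ids] <- TRUE
  }
  if (!is.null(threshold_modulation)) {
    stopifnot(is.list(threshold_modulation),
              threshold_modulation$period > 0,
              is.finite(threshold_modulation$amplitude))
  }
  structure(list(neurons = ndf, synapses = sdf, inputs = inputs,
                 threshold_modulation = threshold_modulation,
                 tau_syn_exc = tau_syn_exc, tau_syn_inh = tau_syn_inh,
                 is_input = is_input),
            class = "network_model")
}

neuron_df_cols <- c("g_leak", "C_m", "E_rest", "E_exc", "E_inh", "r0", "V_T",
                    "dV", "r_max", "refractory_abs", "bias_current",
                    "is_inhibitory")

as_neuron_df <- function(neurons) {
  if (is.data.frame(neurons)) {
    miss <- setdiff(neuron_df_cols, names(neurons))
    if (length(miss)) stop("neuron data frame lacks columns: ",
                           paste(miss, collapse = ", "))
    return(neurons[neuron_df_cols])
  }
  if (inherits(neurons, "neuron_params")) neurons <- list(neurons)
  stopifnot(all(vapply(neurons, inherits, logical(1), "neuron_params")))
  do.call(rbind, lapply(neurons, function(p)
    as.data.frame(p[neuron_df_cols])))
}

synapse_df_cols <- c("pre", "post", "weight", "delay", "kind", "pulse_length",
                     "U", "D", "F")

empty_synapse_df <- function() {
  data.frame(pre = integer(0), post = integer(0), weight = numeric(0),
             delay = numeric(0), kind = character(0),
             pulse_length = numeric(0), U = numeric(0), D = numeric(0),
             F = numeric(0), stringsAsFactors = FALSE)
}

as_synapse_df <- function(synapses) {
  if (is.null(synapses)) return(empty_synapse_df())
  if (is.data.frame(synapses)) {
    if (!nrow(synapses)) return(empty_synapse_df())
    for (cc in c("pulse_length", "U", "D", "F"))
      if (is.null(synapses[[cc]])) synapses[[cc]] <- NA_real_
    miss <- setdiff(synapse_df_cols, names(synapses))
    if (length(miss)) stop("synapse data frame lacks columns: ",
                           paste(miss, collapse = ", "))
    synapses$pre <- as.integer(synapses$pre)
    synapses$post <- as.integer(synapses$post)
    return(synapses[synapse_df_cols])
  }
  if (inherits(synapses, "synapse_params")) synapses <- list(synapses)
  if (!length(synapses)) return(empty_synapse_df())
  stopifnot(all(vapply(synapses, inherits, logical(1), "synapse_params")))
  do.call(rbind, lapply(synapses, function(s) {
    stp <- s$stp
    data.frame(pre = s$pre, post = s$post, weight = s$weight, delay = s$delay,
               kind = s$kind, pulse_length = s$pulse_length,
               U = if (is.null(stp)) NA_real_ else stp$U,
               D = if (is.null(stp)) NA_real_ else stp$D,
               F = if (is.null(stp)) NA_real_ else stp$F,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.network_model <- function(x, ...) {
  n <- nrow(x$neurons)
  cat("<network_model> ", n, " neurons (",
      sum(x$neurons$is_inhibitory), " inhibitory, ",
      sum(x$is_input), " input), ",
      nrow(x$synapses), " synapses, ",
      length(x$inputs), " input process(es)\n", sep = "")
  if (!is.null(x$threshold_modulation))
    cat("  periodic threshold modulation: amplitude ",
        x$threshold_modulation$amplitude, " mV, period ",
        x$threshold_modulation$period, " ms\n", sep = "")
  invisible(x)
}

#' Number of neurons in a network
#' @param net a [network_model()].
#' @return integer count.
#' @export
n_neurons <- function(net) nrow(net$neurons)

#' Create a spike record
#'
#' The universal exchange object between the simulator and the analysis
#' functions: a globally time-sorted event list.
#'
#' @param neuron_id integer vector of neuron ids.
#' @param time_ms numeric vector of spike times (ms), same length.
#' @param duration record duration (ms); events must lie in
#'   `[t_min, duration]` where `t_min` is 0 or negative for preparatory
#'   spikes.
#' @param n_neurons number of neurons the record refers to.
#' @return an object of class `"spike_record"`: a data frame with columns
#'   `neuron_id`, `time_ms` and attributes `duration`, `n_neurons`.
#' @export
spike_record <- function(neuron_id = integer(0), time_ms = numeric(0),
                         duration = if (length(time_ms)) max(time_ms) else 0,
                         n_neurons = if (length(neuron_id)) max(neuron_id) else 0L) {
  stopifnot(length(neuron_id) == length(time_ms))
  if (is.unsorted(time_ms)) {
    o <- order(time_ms, neuron_id)
    neuron_id <- neuron_id[o]; time_ms <- time_ms[o]
  }
  if (length(time_ms) && max(time_ms) > duration + 1e-9)
    stop("spike times exceed the stated duration")
  structure(data.frame(neuron_id = as.integer(neuron_id), time_ms = time_ms),
            duration = duration, n_neurons = as.integer(n_neurons),
            class = c("spike_record", "data.frame"))
}

#' @export
print.spike_record <- function(x, ...) {
  cat("<spike_record> ", nrow(x), " spikes, ", attr(x, "n_neurons"),
      " neurons, duration ", attr(x, "duration"), " ms\n", sep = "")
  if (nrow(x)) {
    utils::head(as.data.frame(x), 5L) |> print()
    if (nrow(x) > 5L) cat("  ...\n")
  }
  invisible(x)
}

#' Per-neuron spike times from a spike record
#' @param spikes a [spike_record()].
#' @param ids neuron ids to extract (default all up to `n_neurons`).
#' @return named list of numeric vectors of spike times.
#' @export
spike_times <- function(spikes, ids = seq_len(attr(spikes, "n_neurons"))) {
  out <- split(spikes$time_ms, factor(spikes$neuron_id, levels = ids))
  names(out) <- as.character(ids)
  out
}
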
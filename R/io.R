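#' Write / read spike records as CSV
#'
#' The exchange format is a CSV with header `neuron_id,time_ms`, times in
#' ms with 6 decimal places, sorted ascending.  Files round-trip
#' bit-exactly through `read_spikes()` followed by `write_spikes()`.
#'
#' @param spikes a [spike_record()].
#' @param path file path.
#' @return `write_spikes()`: the path, invisibly.  `read_spikes()`: a
#'   [spike_record()].
#' @export
write_spikes <- function(spikes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("neuron_id,time_ms", con)
  if (nrow(spikes))
    writeLines(sprintf("%d,%.6f", spikes$neuron_id, spikes$time_ms), con)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  ln <- readLines(path)
  if (!length(ln) || ln[1] != "neuron_id,time_ms")
    stop("missing header 'neuron_id,time_ms'")
  body <- ln[-1]
  ok <- grepl("^-?[0-9]+,-?[0-9.eE+-]+$", body)
  if (any(!ok))
    stop("malformed spike row at line ", which(!ok)[1] + 1L)
  id <- as.integer(sub(",.*", "", body))
  tm <- as.numeric(sub(".*,", "", body))
  if (anyNA(id) || anyNA(tm))
    stop("malformed spike row at line ",
         which(is.na(id) | is.na(tm))[1] + 1L)
  if (is.unsorted(tm))
    stop("spike times must be sorted ascending")
  if (length(tm) && min(tm) < 0)
    stop("negative spike times not allowed in files")
  spike_record(id, tm)
}

#' Specification of a synthetic spike fixture
#'
#' Fixtures emulate the statistical structure the analysis modules assume:
#' independent Poisson trains, a binary state with a prescribed occupancy,
#' a clean activity handover between two pools, or periodically gated
#' activity.
#'
#' @param kind `"poisson-chains"`, `"two-state-occupancy"`, `"handover"`,
#'   or `"periodic-gated"`.
#' @param ... kind-specific parameters, see [generate_fixture()].
#' @return a list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(kind = c("poisson-chains", "two-state-occupancy",
                                  "handover", "periodic-gated"), ...) {
  kind <- match.arg(kind)
  structure(c(list(kind = kind), list(...)), class = "fixture_spec")
}

#' Generate a synthetic spike record from a fixture spec
#'
#' * `"poisson-chains"`: independent Poisson trains; parameters `rates`
#'   (1/ms, one per neuron), `duration`, `seed`.
#' * `"two-state-occupancy"`: one neuron alternating deterministic active
#'   blocks (spikes every `tau/2`) and silence so that its simple-state
#'   occupancy equals `occupancy`; parameters `occupancy`, `duration`,
#'   `tau`, `block` (active block length, default `10 * tau`).
#' * `"handover"`: two pools (`n_per_pool` neurons each, ids `1..n` and
#'   `n+1..2n`) spiking densely in `[0, t1]` and `[t2, duration]`
#'   respectively, silent otherwise; the single transition midpoint is
#'   `(t1 + t2)/2`.  Parameters `t1`, `t2`, `duration`, `n_per_pool`,
#'   `step` (inter-spike spacing, default 2).
#' * `"periodic-gated"`: Poisson spikes (rate `rate`) only while
#'   `t %% period < period/2`; parameters `rate`, `period`, `duration`,
#'   `n_neurons`, `seed`.
#'
#' @param spec a [fixture_spec()].
#' @return a [spike_record()].
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  switch(spec$kind,
    "poisson-chains" = {
      rates <- spec$rates; duration <- spec$duration
      with_seed(spec$seed %||% 1L, {
        id <- integer(0); tm <- numeric(0)
        for (i in seq_along(rates)) {
          if (rates[i] <= 0) next
          nn <- rpois(1, rates[i] * duration)
          tt <- sort(runif(nn, 0, duration))
          id <- c(id, rep.int(i, nn)); tm <- c(tm, tt)
        }
        spike_record(id, tm, duration = duration,
                     n_neurons = length(rates))
      })
    },
    "two-state-occupancy" = {
      occ <- spec$occupancy; duration <- spec$duration; tau <- spec$tau
      block <- spec$block %||% (10 * tau)
      cycle <- block / occ
      tm <- numeric(0)
      t0 <- 0
      while (t0 < duration) {
        # spikes from t0 - tau/2 keep the bit set on [t0, t0 + block]
        s <- seq(t0 + tau / 2, min(t0 + block, duration), by = tau / 2)
        tm <- c(tm, s)
        t0 <- t0 + cycle
      }
      spike_record(rep.int(1L, length(tm)), tm, duration = duration,
                   n_neurons = 1L)
    },
    "handover" = {
      t1 <- spec$t1; t2 <- spec$t2; duration <- spec$duration
      npp <- spec$n_per_pool %||% 5L
      step <- spec$step %||% 2
      a_times <- seq(step, t1, by = step)
      b_times <- seq(t2, duration, by = step)
      id <- c(rep(seq_len(npp), each = length(a_times)),
              rep(npp + seq_len(npp), each = length(b_times)))
      tm <- c(rep(a_times, npp), rep(b_times, npp))
      spike_record(id, tm, duration = duration, n_neurons = 2L * npp)
    },
    "periodic-gated" = {
      rate <- spec$rate; period <- spec$period; duration <- spec$duration
      nn <- spec$n_neurons %||% 1L
      with_seed(spec$seed %||% 1L, {
        id <- integer(0); tm <- numeric(0)
        for (i in seq_len(nn)) {
          k <- rpois(1, rate * duration)
          tt <- sort(runif(k, 0, duration))
          tt <- tt[tt %% period < period / 2]
          id <- c(id, rep.int(i, length(tt))); tm <- c(tm, tt)
        }
        spike_record(id, tm, duration = duration, n_neurons = nn)
      })
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records provenance of a CLI run (config digest, seeds, step, durations,
#' package version, output paths) as JSON so that deterministic stages can
#' be reproduced bit-exactly.
#'
#' @param path output JSON path.
#' @param seeds named list/vector of seeds.
#' @param dt integration step (ms).
#' @param durations named list/vector of durations (ms).
#' @param outputs character vector of output file paths.
#' @param config optional config file path (digested with MD5).
#' @param extra optional named list of additional fields.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, seeds, dt, durations, outputs,
                           config = NULL, extra = list()) {
  man <- c(list(
    tool = "spikenet",
    version = as.character(utils::packageVersion("spikenet")),
    config = if (is.null(config)) NULL else list(
      path = config, md5 = unname(tools::md5sum(config))),
    seeds = as.list(seeds), dt = dt, durations = as.list(durations),
    outputs = outputs), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(man)
}

#' Read a network model from a config file
#'
#' Accepts YAML or JSON with top-level keys `neurons` (list of
#' [neuron_params()] fields; omitted fields take the defaults), `synapses`
#' (list of [synapse_params()] fields), `inputs` (list with `neuron_ids`,
#' `kind`, and kind-specific fields; function-valued rate specs are not
#' representable in configs), and optional `threshold_modulation`,
#' `tau_syn_exc`, `tau_syn_inh`.  The machine-readable schema ships as
#' `extdata/network_config_schema.json`.
#'
#' @param path config file.
#' @return a [network_model()].
#' @export
read_network_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  neurons <- lapply(cfg$neurons, function(np) do.call(neuron_params, np))
  synapses <- lapply(cfg$synapses, function(sp) do.call(synapse_params, sp))
  inputs <- lapply(cfg$inputs, function(ip) {
    ip$neuron_ids <- as.integer(unlist(ip$neuron_ids))
    if (!is.null(ip$rate)) ip$rate <- as.numeric(unlist(ip$rate))
    do.call(input_process, ip)
  })
  network_model(neurons, synapses, inputs = inputs,
                threshold_modulation = cfg$threshold_modulation,
                tau_syn_exc = cfg$tau_syn_exc %||% 5,
                tau_syn_inh = cfg$tau_syn_inh %||% 10)
}
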
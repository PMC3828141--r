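#' Simulate a stochastic spiking network
#'
#' Time-stepped simulation of a [network_model()].  Membrane potentials are
#' integrated with the exponential-Euler scheme; synaptic conductances decay
#' exponentially between event-summed increments; each non-refractory neuron
#' fires in a step of length `dt` with probability `1 - exp(-r(V) dt)` where
#' `r` is the escape [hazard_rate()], so at most one spike per neuron per
#' step can occur by construction.  Spiking resets the membrane to the
#' resting potential after an absolute refractory period.  External input
#' neurons fire as (possibly inhomogeneous) Poisson processes.
#'
#' The run is fully deterministic given `(net, duration, dt, seed)` and the
#' preparatory recipe.  When a [prepare_initial_state()] recipe is supplied,
#' the preparatory phase is simulated first with the preparatory seed (its
#' spikes are reported at negative times) and the generator is re-seeded
#' with `seed` at `t = 0`: repeated calls with the same recipe but different
#' `seed` start from the identical initial spike history and diverge
#' afterwards.
#'
#' @param net a [network_model()].
#' @param duration simulated biological time (ms) after `t = 0`.
#' @param dt integration step (ms); must not exceed the smallest synaptic
#'   delay.
#' @param seed integer seed for the main phase.
#' @param prep optional [prepare_initial_state()] recipe.
#' @param record `"spikes"` or `"spikes+potentials"`; potential traces are
#'   returned in the `"potentials"` attribute (steps x neurons matrix).
#' @param init_uniform draw initial potentials uniformly between the resting
#'   potential and `V_T` (otherwise start at rest).
#' @return a [spike_record()]; preparatory spikes (if any) carry times
#'   `<= 0`.
#' @export
simulate_network <- function(net, duration, dt = 0.1, seed = 1L,
                             prep = NULL,
                             record = c("spikes", "spikes+potentials"),
                             init_uniform = TRUE) {
  stopifnot(inherits(net, "network_model"))
  record <- match.arg(record)
  if (duration <= 0) stop("duration must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (nrow(net$synapses) && dt > min(net$synapses$delay) + 1e-12)
    stop("dt must not exceed the smallest synaptic delay")
  prep_inputs <- list(); prep_dur <- 0; seed_prep <- seed
  if (!is.null(prep)) {
    stopifnot(inherits(prep, "sim_prep"))
    prep_inputs <- prep$inputs; prep_dur <- prep$duration
    seed_prep <- prep$seed
  }
  prep_steps <- as.integer(round(prep_dur / dt))
  n_steps <- prep_steps + as.integer(round(duration / dt))

  flat <- flatten_network(net, dt)
  inspec <- build_input_spec(net, prep_inputs, dt, prep_steps, n_steps, seed)
  tm <- net$threshold_modulation
  res <- sim_core_run(flat$neurons, flat$synapses, inspec,
                      net$tau_syn_exc, net$tau_syn_inh,
                      if (is.null(tm)) 0 else tm$amplitude,
                      if (is.null(tm)) 0 else tm$period,
                      dt, n_steps, prep_steps,
                      seed_prep, seed,
                      record == "spikes+potentials", init_uniform)
  rec <- spike_record(res$neuron_id, res$time_ms, duration = duration,
                      n_neurons = n_neurons(net))
  attr(rec, "dt") <- dt
  if (record == "spikes+potentials")
    attr(rec, "potentials") <- res$potentials
  rec
}

#' Recipe for a reproducible initial network state
#'
#' Describes a preparatory phase: input processes shown for `prep_duration`
#' ms before `t = 0`, simulated with seed `prep_seed`.  Passing the same
#' recipe to [simulate_network()] with different main seeds reproduces the
#' identical initial spike history (the network state at `t = 0`) with
#' divergent futures.
#'
#' @param net the [network_model()] the recipe is for (used for validation).
#' @param prep_inputs list of [input_process()] objects active during the
#'   preparatory phase (they override the network's own inputs for `t < 0`).
#' @param prep_duration length of the preparatory phase (ms); must cover at
#'   least one state window `state_window` so the initial state is fully
#'   determined by the preparatory phase.
#' @param prep_seed seed of the preparatory phase.
#' @param state_window the state-window length T (ms) the initial state is
#'   defined over.
#' @return an object of class `"sim_prep"`.
#' @export
prepare_initial_state <- function(net, prep_inputs, prep_duration,
                                  prep_seed, state_window = 100) {
  stopifnot(inherits(net, "network_model"))
  if (prep_duration < state_window)
    stop("prep_duration must be >= the state window T (",
         state_window, " ms)")
  if (inherits(prep_inputs, "input_process")) prep_inputs <- list(prep_inputs)
  for (ip in prep_inputs) {
    if (!inherits(ip, "input_process")) stop("prep_inputs must be input_process objects")
    if (any(ip$neuron_ids > n_neurons(net)))
      stop("prep input references nonexistent neurons")
  }
  structure(list(inputs = prep_inputs, duration = prep_duration,
                 seed = prep_seed),
            class = "sim_prep")
}

# --- internal flattening helpers ------------------------------------------

flatten_network <- function(net, dt) {
  nd <- net$neurons
  sd <- net$synapses
  list(
    neurons = list(
      g_leak = nd$g_leak, C_m = nd$C_m, E_rest = nd$E_rest,
      E_exc = nd$E_exc, E_inh = nd$E_inh, r0 = nd$r0, V_T = nd$V_T,
      dV = nd$dV, r_max = nd$r_max, refractory_abs = nd$refractory_abs,
      bias_current = nd$bias_current,
      is_inhibitory = as.integer(nd$is_inhibitory),
      is_input = as.integer(net$is_input)),
    synapses = list(
      pre = sd$pre - 1L, post = sd$post - 1L, weight = sd$weight,
      kind = ifelse(sd$kind == "current-rect", 1L, 0L),
      delay_steps = pmax(1L, as.integer(round(sd$delay / dt))),
      pulse_steps = ifelse(is.na(sd$pulse_length), 1L,
                           pmax(1L, as.integer(round(sd$pulse_length / dt)))),
      has_stp = as.integer(!is.na(sd$U)),
      U = ifelse(is.na(sd$U), 0, sd$U),
      D = ifelse(is.na(sd$D), 1, sd$D),
      F = ifelse(is.na(sd$F), 1, sd$F)))
}

# Build per-input-neuron rate step functions covering the preparatory and
# main phases.  Piecewise segments are indexed by absolute step; a periodic
# table (rate per step within one period) can take over from the main phase.
build_input_spec <- function(net, prep_inputs, dt, prep_steps, n_steps, seed) {
  members <- list()   # per member: list(neuron, breaks, rates, per_id, per_start)
  tables <- list()    # periodic rate tables
  add_piecewise <- function(id, breaks, rates) {
    key <- as.character(id)
    m <- members[[key]]
    if (is.null(m)) m <- list(neuron = id, breaks = integer(0),
                              rates = numeric(0), per_id = -1L,
                              per_start = 0L)
    m$breaks <- c(m$breaks, as.integer(breaks))
    m$rates <- c(m$rates, rates)
    members[[key]] <<- m
  }
  expand_process <- function(ip, start_step, phase_steps, main) {
    ids <- ip$neuron_ids
    if (ip$kind == "constant") {
      rate <- rep_len(ip$rate, length(ids))
      for (k in seq_along(ids)) add_piecewise(ids[k], start_step, rate[k])
    } else if (ip$kind == "periodic" && main) {
      period_steps <- max(1L, as.integer(round(ip$period / dt)))
      tab <- vapply(((seq_len(period_steps) - 1L) * dt),
                    ip$rate_fn, numeric(1))
      if (any(tab < 0)) stop("periodic rate function must be nonnegative")
      tables[[length(tables) + 1L]] <<- tab
      tid <- length(tables) - 1L
      for (id in ids) {
        key <- as.character(id)
        m <- members[[key]]
        if (is.null(m)) m <- list(neuron = id, breaks = integer(0),
                                  rates = numeric(0), per_id = -1L,
                                  per_start = 0L)
        m$per_id <- tid
        m$per_start <- start_step
        members[[key]] <<- m
      }
    } else if (ip$kind %in% c("schedule", "periodic")) {
      # sampled per step, run-length compressed
      tt <- (seq_len(phase_steps) - 1L) * dt +
        (if (main) 0 else -phase_steps * dt)
      rr <- vapply(tt, ip$rate_fn, numeric(1))
      if (any(rr < 0)) stop("rate function must be nonnegative")
      z <- rle(rr)
      br <- start_step + c(0L, cumsum(z$lengths[-length(z$lengths)]))
      for (id in ids) add_piecewise(id, br, z$values)
    } else {  # markov-modulated
      md <- ip$modulator
      K <- length(md$rates)
      P <- md$P
      if (is.null(P)) {
        P <- matrix(1 / max(1, K - 1), K, K); diag(P) <- 0
        if (K == 1) P <- matrix(1, 1, 1)
      }
      traj <- with_seed(seed + 104729L * start_step, {
        st <- sample.int(K, 1L)
        t_cur <- 0; bs <- integer(0); rs <- numeric(0)
        total <- phase_steps * dt
        while (t_cur < total) {
          bs <- c(bs, as.integer(round(t_cur / dt)))
          rs <- c(rs, md$rates[st])
          t_cur <- t_cur + stats::rexp(1, 1 / md$Q_dwell[st])
          st <- sample.int(K, 1L, prob = P[st, ])
        }
        list(bs = bs, rs = rs)
      })
      for (id in ids) add_piecewise(id, start_step + traj$bs, traj$rs)
    }
  }
  for (ip in prep_inputs) expand_process(ip, 0L, prep_steps, main = FALSE)
  for (ip in net$inputs) expand_process(ip, prep_steps, n_steps - prep_steps,
                                        main = TRUE)
  # neurons flagged as inputs but without any process stay silent (rate 0)
  members <- lapply(members, function(m) {
    if (length(m$breaks) && m$breaks[1L] > 0L) {   # silent until first segment
      m$breaks <- c(0L, m$breaks)
      m$rates <- c(0, m$rates)
    }
    m
  })
  if (length(members)) {
    neuron <- vapply(members, `[[`, integer(1), "neuron")
    nseg <- vapply(members, function(m) length(m$breaks), integer(1))
    list(neuron = unname(neuron) - 1L,
         pw_off = c(0L, cumsum(unname(nseg))),
         pw_break = as.integer(unlist(lapply(members, `[[`, "breaks"),
                                      use.names = FALSE)),
         pw_rate = as.numeric(unlist(lapply(members, `[[`, "rates"),
                                     use.names = FALSE)),
         per_id = unname(vapply(members, `[[`, integer(1), "per_id")),
         per_start = as.integer(unname(vapply(members, `[[`, integer(1),
                                              "per_start"))),
         pt_off = c(0L, cumsum(vapply(tables, length, integer(1)))),
         pt_rate = as.numeric(unlist(tables, use.names = FALSE)))
  } else {
    list(neuron = integer(0), pw_off = 0L, pw_break = integer(0),
         pw_rate = numeric(0), per_id = integer(0), per_start = integer(0),
         pt_off = 0L, pt_rate = numeric(0))
  }
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}
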
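#' Load the laminar cortical-column template
#'
#' Reads the six-pool (layers 2/3, 4, 5 x excitatory/inhibitory) column
#' template from a YAML config.  The bundled default carries placeholder
#' connectivity numbers that preserve the qualitative laminar structure;
#' all values are meant to be overridden from measured tables.
#'
#' @param path YAML file; defaults to the bundled template.
#' @return a list of class `"laminar_template"`.
#' @export
laminar_template <- function(path = system.file("extdata",
                                                "laminar_template.yaml",
                                                package = "spikenet")) {
  tpl <- yaml::read_yaml(path)
  fr <- unlist(tpl$pools)
  if (abs(sum(fr) - 1) > 1e-6) stop("pool fractions must sum to 1")
  structure(tpl, class = "laminar_template")
}

pool_type <- function(pool) substr(pool, nchar(pool), nchar(pool))

stp_class <- function(pre_type, post_type)
  paste0(pre_type, post_type)

draw_stp <- function(tpl, pre_type, post_type) {
  cl <- tpl$stp[[stp_class(pre_type, post_type)]]
  U <- min(0.95, max(0.01, rnorm(1, cl$U[1], cl$U[2])))
  D <- max(1, rnorm(1, cl$D[1], cl$D[2]))
  F <- max(1, rnorm(1, cl$F[1], cl$F[2]))
  c(U = U, D = D, F = F)
}

#' Build a laminar cortical-microcircuit network
#'
#' Instantiates the column template at a given size: pool sizes from the
#' template fractions, Bernoulli connectivity per pool pair, synaptic
#' weights drawn from Gamma distributions (type-specific mean, common CV),
#' per-presynaptic-neuron short-term-plasticity parameters drawn from the
#' type-specific Gaussians (truncated to valid ranges), two input streams
#' of 40 Poisson neurons each, and constant background currents.
#' Deterministic given `seed`.
#'
#' @param tpl a [laminar_template()].
#' @param n_total number of network neurons (excluding input neurons);
#'   at least 60.
#' @param seed build seed.
#' @param input_rate Poisson rate (1/ms) of the input streams.
#' @return a [network_model()] with extra fields `pool` (pool label per
#'   neuron, `"input1"`/`"input2"` for input neurons).
#' @export
build_laminar <- function(tpl = laminar_template(), n_total = 560, seed = 1L,
                          input_rate = tpl$inputs$rate_per_ms) {
  if (n_total < 60) stop("n_total must be >= 60 (>= 10 per pool)")
  with_seed(seed, build_laminar_impl(tpl, n_total, input_rate))
}

build_laminar_impl <- function(tpl, n_total, input_rate) {
  fr <- unlist(tpl$pools)
  sizes <- round(fr * n_total)
  sizes[1] <- sizes[1] + (n_total - sum(sizes))   # absorb rounding
  pools <- rep(names(fr), sizes)
  n <- length(pools)
  types <- pool_type(pools)
  nin <- tpl$inputs$n_per_stream
  pools <- c(pools, rep(c("input1", "input2"), each = nin))
  types <- c(types, rep("E", 2 * nin))
  ntot <- length(pools)

  neurons <- data.frame(
    g_leak = 10, C_m = 200, E_rest = -70, E_exc = 0, E_inh = -75,
    r0 = 0.01, V_T = -55, dV = 2, r_max = 1,
    refractory_abs = ifelse(types == "I", tpl$refractory_ms$I,
                            tpl$refractory_ms$E),
    bias_current = c(rnorm(n, tpl$background$mean, tpl$background$sd),
                     rep(0, 2 * nin)),
    is_inhibitory = types == "I")

  cv <- tpl$connections$weight_cv
  gamma_w <- function(nw, mean_w) {
    shape <- 1 / cv^2
    rgamma(nw, shape = shape, scale = mean_w / shape)
  }
  pre <- integer(0); post <- integer(0); w <- numeric(0)
  U <- numeric(0); D <- numeric(0); F <- numeric(0)
  pool_ids <- split(seq_len(n), factor(pools[seq_len(n)], levels = names(fr)))
  # per-presynaptic-neuron STP draws, one per (neuron, post-type)
  stp_by_neuron <- lapply(seq_len(n), function(i) {
    list(E = draw_stp(tpl, types[i], "E"), I = draw_stp(tpl, types[i], "I"))
  })
  for (pp in names(fr)) for (qq in names(fr)) {
    p <- tpl$connections$p[[pp]][[qq]]
    if (is.null(p) || p <= 0) next
    src <- pool_ids[[pp]]; dst <- pool_ids[[qq]]
    grid <- expand.grid(pre = src, post = dst)
    grid <- grid[grid$pre != grid$post, ]
    keep <- runif(nrow(grid)) < p
    if (!any(keep)) next
    g <- grid[keep, ]
    pre_t <- pool_type(pp); post_t <- pool_type(qq)
    mw <- if (pre_t == "E") tpl$connections$mean_weight$E_to[[post_t]]
          else tpl$connections$mean_weight$I_to[[post_t]]
    stp <- t(vapply(g$pre, function(i) stp_by_neuron[[i]][[post_t]],
                    numeric(3)))
    pre <- c(pre, g$pre); post <- c(post, g$post)
    w <- c(w, gamma_w(nrow(g), mw))
    U <- c(U, stp[, 1]); D <- c(D, stp[, 2]); F <- c(F, stp[, 3])
  }
  # input streams
  in_ids <- list(input1 = n + seq_len(nin), input2 = n + nin + seq_len(nin))
  for (st in c("stream1", "stream2")) {
    tp <- tpl$inputs$target_p[[st]]
    src <- in_ids[[if (st == "stream1") "input1" else "input2"]]
    for (qq in names(fr)) {
      p <- tp[[qq]]
      if (is.null(p) || p <= 0) next
      dst <- pool_ids[[qq]]
      grid <- expand.grid(pre = src, post = dst)
      keep <- runif(nrow(grid)) < p
      if (!any(keep)) next
      g <- grid[keep, ]
      stp <- t(vapply(g$pre, function(i) draw_stp(tpl, "E",
                                                  pool_type(qq)),
                      numeric(3)))
      pre <- c(pre, g$pre); post <- c(post, g$post)
      w <- c(w, gamma_w(nrow(g), tpl$inputs$weight_mean))
      U <- c(U, stp[, 1]); D <- c(D, stp[, 2]); F <- c(F, stp[, 3])
    }
  }
  syn <- data.frame(pre = pre, post = post, weight = w,
                    delay = tpl$connections$delay_ms,
                    kind = "conductance-exp", pulse_length = NA_real_,
                    U = U, D = D, F = F, stringsAsFactors = FALSE)
  inputs <- list(
    input_process(in_ids$input1, "constant", rate = input_rate),
    input_process(in_ids$input2, "constant", rate = input_rate))
  net <- network_model(neurons, syn, inputs = inputs)
  net$pool <- pools
  net
}

#' Scale recurrent weights inversely with network size
#'
#' Returns a template whose recurrent mean weights are multiplied by
#' `n_ref / n_new`; input-stream and background parameters are untouched.
#' Used to keep population activity comparable across column sizes.
#'
#' @param tpl a [laminar_template()].
#' @param n_ref,n_new reference and new network sizes.
#' @return the rescaled template.
#' @export
scale_weights <- function(tpl, n_ref, n_new) {
  stopifnot(n_ref > 0, n_new > 0)
  f <- n_ref / n_new
  tpl$connections$mean_weight$E_to <- lapply(tpl$connections$mean_weight$E_to,
                                             function(x) x * f)
  tpl$connections$mean_weight$I_to <- lapply(tpl$connections$mean_weight$I_to,
                                             function(x) x * f)
  tpl
}

#' Readout-neuron afferent composition
#'
#' Numbers of randomly chosen presynaptic neurons per pool for an observer
#' ("readout") neuron, and the Gamma weight laws for its excitatory (EE)
#' and inhibitory (IE) afferents.  The default composition draws 500
#' afferents: 120/30 from L2/3 E/I, 80/20 from L4, 200/50 from L5.
#'
#' @param counts named integer vector of per-pool afferent counts.
#' @param w_exc,w_inh `c(mean, scale)` of the Gamma distributions for EE
#'   and IE afferent weights (nS).
#' @return object of class `"readout_spec"`.
#' @export
readout_spec <- function(counts = c(L23E = 120, L23I = 30, L4E = 80,
                                    L4I = 20, L5E = 200, L5I = 50),
                         w_exc = c(1.5, 0.7), w_inh = c(4, 1.5)) {
  stopifnot(all(counts >= 0))
  structure(list(counts = counts, w_exc = w_exc, w_inh = w_inh,
                 total = sum(counts)),
            class = "readout_spec")
}

#' Attach an observer (readout) neuron to a column network
#'
#' Adds one excitatory neuron receiving synapses from a random subset of
#' network neurons, with per-pool counts from the [readout_spec()], Gamma
#' weights by afferent type, and type-specific short-term plasticity as in
#' the column.  The readout has no efferent synapses back into the network.
#'
#' @param net a [build_laminar()] network (needs the `pool` field).
#' @param spec a [readout_spec()].
#' @param seed draw seed.
#' @return the extended [network_model()]; the readout is the last neuron.
#' @export
attach_readout <- function(net, spec = readout_spec(), seed = 1L) {
  stopifnot(inherits(net, "network_model"), inherits(spec, "readout_spec"))
  if (is.null(net$pool)) stop("net lacks pool labels (build with build_laminar)")
  tpl <- laminar_template()
  with_seed(seed, {
    n <- n_neurons(net)
    ro <- n + 1L
    neurons <- rbind(net$neurons,
                     data.frame(g_leak = 10, C_m = 200, E_rest = -70,
                                E_exc = 0, E_inh = -75, r0 = 0.01,
                                V_T = -55, dV = 2, r_max = 1,
                                refractory_abs = 3, bias_current = 0,
                                is_inhibitory = FALSE))
    pre <- integer(0); w <- numeric(0)
    U <- numeric(0); D <- numeric(0); F <- numeric(0)
    for (pl in names(spec$counts)) {
      cnt <- spec$counts[[pl]]
      if (cnt == 0) next
      cand <- which(net$pool == pl)
      if (length(cand) < cnt)
        stop("pool ", pl, " has only ", length(cand),
             " neurons; need ", cnt)
      sel <- sample(cand, cnt)
      inh <- pool_type(pl) == "I"
      pars <- if (inh) spec$w_inh else spec$w_exc
      ww <- rgamma(cnt, shape = pars[1] / pars[2], scale = pars[2])
      stp <- t(vapply(sel, function(i)
        draw_stp(tpl, if (inh) "I" else "E", "E"), numeric(3)))
      pre <- c(pre, sel); w <- c(w, ww)
      U <- c(U, stp[, 1]); D <- c(D, stp[, 2]); F <- c(F, stp[, 3])
    }
    syn <- rbind(net$synapses,
                 data.frame(pre = pre, post = ro, weight = w, delay = 1,
                            kind = "conductance-exp",
                            pulse_length = NA_real_,
                            U = U, D = D, F = F, stringsAsFactors = FALSE))
    out <- network_model(neurons, syn, inputs = net$inputs,
                         tau_syn_exc = net$tau_syn_exc,
                         tau_syn_inh = net$tau_syn_inh)
    out$pool <- c(net$pool, "readout")
    out$readout_id <- ro
    out
  })
}

#' Sparsely active two-population network
#'
#' One excitatory and one inhibitory population (10 neurons each) with
#' connection probabilities EE = 0.1, EI = 0.1, II = 0.9, IE = 0.9
#' (pre -> post), conductance synapses, and background drive tuned for
#' sparse activity.
#'
#' @param seed build seed.
#' @param n_e,n_i population sizes.
#' @return a [network_model()]; field `pool` labels neurons `"E"` / `"I"`.
#' @export
build_sparse <- function(seed = 1L, n_e = 10L, n_i = 10L) {
  with_seed(seed, {
    n <- n_e + n_i
    types <- c(rep("E", n_e), rep("I", n_i))
    neurons <- data.frame(
      g_leak = 10, C_m = 200, E_rest = -70, E_exc = 0, E_inh = -75,
      r0 = 0.01, V_T = -55, dV = 2, r_max = 1,
      refractory_abs = ifelse(types == "I", 2, 3),
      bias_current = rnorm(n, 120, 10),
      is_inhibitory = types == "I")
    p_tab <- c(EE = 0.1, EI = 0.1, II = 0.9, IE = 0.9)
    w_tab <- c(EE = 2, EI = 2, II = 4, IE = 4)
    pre <- integer(0); post <- integer(0); w <- numeric(0)
    for (a in c("E", "I")) for (b in c("E", "I")) {
      key <- paste0(a, b)
      src <- which(types == a); dst <- which(types == b)
      grid <- expand.grid(pre = src, post = dst)
      grid <- grid[grid$pre != grid$post, ]
      keep <- runif(nrow(grid)) < p_tab[[key]]
      if (!any(keep)) next
      g <- grid[keep, ]
      pre <- c(pre, g$pre); post <- c(post, g$post)
      w <- c(w, rgamma(nrow(g), shape = 2, scale = w_tab[[key]] / 2))
    }
    syn <- data.frame(pre = pre, post = post, weight = w, delay = 1,
                      kind = "conductance-exp", pulse_length = NA_real_,
                      U = NA_real_, D = NA_real_, F = NA_real_,
                      stringsAsFactors = FALSE)
    net <- network_model(neurons, syn)
    net$pool <- types
    net
  })
}

#' Network with sequential (synfire-like) structure
#'
#' One or two subnetworks, each a trigger neuron, an excitatory chain and a
#' small inhibitory pool.  Every chain neuron projects to all others in the
#' same chain with strength decaying exponentially with index distance
#' (separate forward and backward length constants); the trigger projects
#' forward into the chain the same way; the chain excites its inhibitory
#' pool, which projects back onto trigger and chain.  With two subnetworks
#' the inhibitory pool of each also targets the other's trigger and chain,
#' so only one trajectory can be active at a time.
#'
#' @param n_chains 1 or 2 subnetworks.
#' @param chain_length excitatory chain length (>= 3).
#' @param seed build seed.
#' @param xi_forward,xi_backward decay constants (in neuron indices) of the
#'   forward / backward chain weights.
#' @return a [network_model()] with fields `chains` (list of id vectors,
#'   chain order), `triggers`, `inh_pools`.
#' @export
build_sequence <- function(n_chains = 2L, chain_length = 15L, seed = 1L,
                           xi_forward = 3, xi_backward = 1) {
  stopifnot(n_chains %in% 1:2, chain_length >= 3)
  with_seed(seed, {
    n_inh <- 5L
    per <- 1L + chain_length + n_inh
    n <- n_chains * per
    pool <- character(n); is_inh <- logical(n)
    chains <- list(); triggers <- integer(0); inh_pools <- list()
    for (c0 in seq_len(n_chains)) {
      off <- (c0 - 1L) * per
      triggers[c0] <- off + 1L
      chains[[c0]] <- off + 1L + seq_len(chain_length)
      inh_pools[[c0]] <- off + 1L + chain_length + seq_len(n_inh)
      pool[triggers[c0]] <- paste0("trigger", c0)
      pool[chains[[c0]]] <- paste0("chain", c0)
      pool[inh_pools[[c0]]] <- paste0("inh", c0)
      is_inh[inh_pools[[c0]]] <- TRUE
    }
    neurons <- data.frame(
      g_leak = 10, C_m = 200, E_rest = -70, E_exc = 0, E_inh = -75,
      r0 = 0.01, V_T = -55, dV = 2, r_max = 1,
      refractory_abs = ifelse(is_inh, 2, 3),
      bias_current = ifelse(pool %in% paste0("trigger", 1:2), 160, 40),
      is_inhibitory = is_inh)
    w0_chain <- 30; w0_trig <- 30; w_ei <- 3; w_ie <- 6
    pre <- integer(0); post <- integer(0); w <- numeric(0)
    add <- function(p1, p2, ww) {
      pre <<- c(pre, p1); post <<- c(post, p2); w <<- c(w, ww)
    }
    for (c0 in seq_len(n_chains)) {
      ch <- chains[[c0]]
      L <- length(ch)
      for (i in seq_len(L)) for (j in seq_len(L)) {
        if (i == j) next
        d <- abs(j - i)
        xi <- if (j > i) xi_forward else xi_backward
        add(ch[i], ch[j], w0_chain * exp(-d / xi))
      }
      for (j in seq_len(L))
        add(triggers[c0], ch[j], w0_trig * exp(-j / xi_forward))
      for (i in ch) for (k in inh_pools[[c0]]) add(i, k, w_ei)
      for (k in inh_pools[[c0]]) {
        add(k, triggers[c0], w_ie)
        for (i in ch) add(k, i, w_ie)
      }
      if (n_chains == 2L) {
        other <- 3L - c0
        for (k in inh_pools[[c0]]) {
          add(k, triggers[other], w_ie)
          for (i in chains[[other]]) add(k, i, w_ie)
        }
      }
    }
    syn <- data.frame(pre = pre, post = post, weight = w, delay = 2,
                      kind = "conductance-exp", pulse_length = NA_real_,
                      U = NA_real_, D = NA_real_, F = NA_real_,
                      stringsAsFactors = FALSE)
    net <- network_model(neurons, syn)
    net$pool <- pool
    net$chains <- chains; net$triggers <- triggers; net$inh_pools <- inh_pools
    net
  })
}

#' Bistable two-population network
#'
#' Two self-exciting excitatory pools that inhibit each other
#' di-synaptically through a partner interneuron each.  The recurrent
#' excitation is depressing (Tsodyks-Markram), which self-limits the active
#' attractor and lets escape noise hop the network between the two states
#' on a sub-second timescale.
#'
#' @param pool_size neurons per excitatory pool.
#' @param seed build seed.
#' @return a [network_model()] with fields `pool_A`, `pool_B` (excitatory
#'   ids).
#' @export
build_bistable <- function(pool_size = 10L, seed = 1L) {
  with_seed(seed, {
    nA <- seq_len(pool_size)
    nB <- pool_size + seq_len(pool_size)
    iA <- 2L * pool_size + 1L
    iB <- 2L * pool_size + 2L
    n <- 2L * pool_size + 2L
    is_inh <- seq_len(n) %in% c(iA, iB)
    neurons <- data.frame(
      g_leak = 10, C_m = 200, E_rest = -70, E_exc = 0, E_inh = -75,
      r0 = 0.01, V_T = -55, dV = 2, r_max = 1,
      refractory_abs = ifelse(is_inh, 2, 3),
      bias_current = ifelse(is_inh, 0, 150),
      is_inhibitory = is_inh)
    pre <- integer(0); post <- integer(0); w <- numeric(0); ee <- logical(0)
    add <- function(p1, p2, ww, rec = FALSE) {
      pre <<- c(pre, p1); post <<- c(post, p2); w <<- c(w, ww)
      ee <<- c(ee, rec)
    }
    w_ee <- 40; w_ei <- 3; w_ie <- 12
    for (i in nA) for (j in nA) if (i != j) add(i, j, w_ee, TRUE)
    for (i in nB) for (j in nB) if (i != j) add(i, j, w_ee, TRUE)
    for (i in nA) add(i, iA, w_ei)
    for (i in nB) add(i, iB, w_ei)
    for (j in nB) add(iA, j, w_ie)
    for (j in nA) add(iB, j, w_ie)
    syn <- data.frame(pre = pre, post = post, weight = w, delay = 1,
                      kind = "conductance-exp", pulse_length = NA_real_,
                      U = ifelse(ee, 0.3, NA_real_),
                      D = ifelse(ee, 1500, NA_real_),
                      F = ifelse(ee, 50, NA_real_),
                      stringsAsFactors = FALSE)
    net <- network_model(neurons, syn)
    net$pool_A <- nA; net$pool_B <- nB
    net
  })
}

#' Small hand-tuned microcircuit (10 network neurons)
#'
#' A 10-neuron column sketch following the laminar template's qualitative
#' connectivity (three layers, one inhibitory neuron per layer), with two
#' Poisson input neurons, small constant currents modulating excitability,
#' and two highlighted recurrent synapses strengthened by factors 5 and 10
#' to increase correlations among the highlighted neurons (2, 7 and 8).
#' The quantitative values are reconstructions.
#'
#' @param seed build seed.
#' @param input_rate input Poisson rate (1/ms).
#' @return a [network_model()] with `pool` labels.
#' @export
build_small_column <- function(seed = 1L, input_rate = 0.01) {
  with_seed(seed, {
    # 1-3: L2/3 E, 4: L2/3 I, 5-6: L4 E, 7: L4 I, 8-9: L5 E, 10: L5 I,
    # 11-12: input neurons
    pool <- c("L23E", "L23E", "L23E", "L23I", "L4E", "L4E", "L4I",
              "L5E", "L5E", "L5I", "input1", "input2")
    is_inh <- pool %in% c("L23I", "L4I", "L5I")
    n <- length(pool)
    neurons <- data.frame(
      g_leak = 10, C_m = 200, E_rest = -70, E_exc = 0, E_inh = -75,
      r0 = 0.01, V_T = -55, dV = 2, r_max = 1,
      refractory_abs = ifelse(is_inh, 2, 3),
      bias_current = c(60, 80, 60, 30, 70, 60, 30, 90, 60, 30, 0, 0),
      is_inhibitory = is_inh)
    conn <- rbind(
      # within L2/3
      c(1, 2, 2), c(2, 1, 2), c(2, 3, 2), c(3, 2, 2), c(1, 4, 2.5),
      c(2, 4, 2.5), c(4, 1, 5), c(4, 2, 5), c(4, 3, 5),
      # L4 -> L2/3 and within L4
      c(5, 1, 2), c(5, 2, 2), c(6, 3, 2), c(5, 6, 2), c(6, 5, 2),
      c(5, 7, 2.5), c(7, 5, 5), c(7, 6, 5),
      # L2/3 -> L5, within L5
      c(2, 8, 2), c(3, 9, 2), c(8, 9, 2), c(9, 8, 2), c(8, 10, 2.5),
      c(10, 8, 5), c(10, 9, 5),
      # feedback L5 -> L2/3
      c(8, 2, 1.5), c(9, 3, 1.5),
      # input streams: stream1 -> L4, stream2 -> L2/3
      c(11, 5, 3), c(11, 6, 3), c(12, 1, 3), c(12, 2, 3))
    conn <- as.data.frame(conn)
    names(conn) <- c("pre", "post", "weight")
    # highlighted connections among neurons 2, 7, 8: base weights times the
    # stated factors 5 and 10
    conn <- rbind(conn, c(2, 7, 2.5 * 5), c(7, 8, 0.5 * 10))
    syn <- data.frame(pre = as.integer(conn$pre), post = as.integer(conn$post),
                      weight = conn$weight, delay = 1,
                      kind = "conductance-exp", pulse_length = NA_real_,
                      U = NA_real_, D = NA_real_, F = NA_real_,
                      stringsAsFactors = FALSE)
    syn <- syn[syn$weight > 0, ]
    net <- network_model(neurons, syn,
                         inputs = list(
                           input_process(11L, "constant", rate = input_rate),
                           input_process(12L, "constant", rate = input_rate)))
    net$pool <- pool
    net
  })
}

#' Mean population firing rate of a spike record
#'
#' @param spikes a [spike_record()].
#' @param ids neurons included (default: all).
#' @param t_start,t_end analysis window (ms).
#' @return mean rate in spikes/s per neuron.
#' @export
mean_rate <- function(spikes, ids = seq_len(attr(spikes, "n_neurons")),
                      t_start = 0, t_end = attr(spikes, "duration")) {
  sel <- spikes$neuron_id %in% ids & spikes$time_ms > t_start &
    spikes$time_ms <= t_end
  1000 * sum(sel) / (length(ids) * (t_end - t_start))
}
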
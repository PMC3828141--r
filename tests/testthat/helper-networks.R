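# shared fixtures: tiny networks built in code

# single neuron with flat hazard (V_T at rest), optional refractoriness
flat_neuron <- function(r0 = 0.05, refr = 2, r_max = 1) {
  neuron_params(r0 = r0, V_T = -70, dV = 2, r_max = r_max,
                refractory_abs = refr)
}

# quasi-static two-neuron mutual-excitation net with rectangular current
# pulses; exactly representable by the discretization oracle at dt = bin
tiny_rect_net <- function(w12 = 30, w21 = 25, r0 = 0.05, refr = 2,
                          bin = 2) {
  nd <- data.frame(g_leak = 10, C_m = 0.001, E_rest = -70, E_exc = 0,
                   E_inh = -75, r0 = r0, V_T = -70, dV = 2, r_max = 0.5,
                   refractory_abs = refr, bias_current = 0,
                   is_inhibitory = FALSE)
  nd <- rbind(nd, nd)
  syn <- data.frame(pre = c(1, 2), post = c(2, 1), weight = c(w12, w21),
                    delay = bin, kind = "current-rect", pulse_length = bin,
                    U = NA_real_, D = NA_real_, F = NA_real_)
  network_model(nd, syn)
}

# driven two-neuron circuit: Poisson input neuron exciting one LIF neuron
driven_pair <- function(rate = 0.02, w = 5) {
  network_model(list(neuron_params(), neuron_params(refractory_abs = 0)),
                synapses = list(synapse_params(2, 1, weight = w, delay = 1)),
                inputs = input_process(2, "constant", rate = rate))
}

# 3-neuron toy with independent drive, used for state/diagnostic tests
toy3_net <- function(r0 = 0.02) {
  nd <- do.call(rbind, lapply(1:3, function(i)
    as.data.frame(unclass(flat_neuron(r0 = r0, refr = 2)))))
  syn <- data.frame(pre = c(1, 2), post = c(2, 3), weight = c(2, 2),
                    delay = 1, kind = "conductance-exp",
                    pulse_length = NA_real_,
                    U = NA_real_, D = NA_real_, F = NA_real_)
  network_model(nd, syn)
}

# independent STP oracle: direct loop over the dynamic-synapse recurrences,
# written separately from stp_amplitudes on purpose
stp_oracle <- function(w, U, D, F, intervals) {
  out <- numeric(length(intervals) + 1)
  u_prev <- U; R_prev <- 1
  out[1] <- w * U * 1
  k <- 1
  for (dlt in intervals) {
    u_k <- U + u_prev * (1 - U) * exp(-dlt / F)
    R_k <- 1 + (R_prev * (1 - u_prev) - 1) * exp(-dlt / D)
    k <- k + 1
    out[k] <- w * u_k * R_k
    u_prev <- u_k; R_prev <- R_k
  }
  out
}
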
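# Laminar cortical-column template (data-based column family).
#
# PLACEHOLDER connectivity/weight numbers: the quantitative table of the
# original data-based column is not bundled; the values below preserve the
# qualitative structure (six pools over layers 2/3, 4, 5; denser
# within-layer connectivity; E/I signs; Gamma-distributed weights) and give
# biologically plausible activity.  Transcribe measured values over these
# defaults for quantitative work.  Short-term plasticity means/SDs follow
# the standard quadripartite (EE/EI/IE/II) values used by laminar-column
# models.
schema_version: 1
pools:                      # relative sizes (sum to 1)
  L23E: 0.26
  L23I: 0.09
  L4E: 0.24
  L4I: 0.08
  L5E: 0.25
  L5I: 0.08
refractory_ms: {E: 3.0, I: 2.0}
# connection table: probability p, mean weight (nS), weight CV, delay (ms),
# rows = presynaptic pool, cols = postsynaptic pool
connections:
  p:
    L23E: {L23E: 0.25, L23I: 0.25, L4E: 0.05, L4I: 0.05, L5E: 0.15, L5I: 0.10}
    L23I: {L23E: 0.45, L23I: 0.45, L4E: 0.05, L4I: 0.05, L5E: 0.10, L5I: 0.05}
    L4E:  {L23E: 0.20, L23I: 0.15, L4E: 0.25, L4I: 0.25, L5E: 0.10, L5I: 0.05}
    L4I:  {L23E: 0.10, L23I: 0.05, L4E: 0.45, L4I: 0.45, L5E: 0.05, L5I: 0.05}
    L5E:  {L23E: 0.05, L23I: 0.05, L4E: 0.05, L4I: 0.05, L5E: 0.25, L5I: 0.25}
    L5I:  {L23E: 0.05, L23I: 0.05, L4E: 0.05, L4I: 0.05, L5E: 0.45, L5I: 0.45}
  mean_weight:              # nS; inhibitory rows are magnitudes
    E_to: {E: 1.2, I: 1.4}
    I_to: {E: 5.0, I: 4.0}
  weight_cv: 0.7
  delay_ms: 1.0
stp:                        # Gaussian mean/sd per connection class
  EE: {U: [0.50, 0.25], D: [1100, 550], F: [50, 25]}
  EI: {U: [0.05, 0.02], D: [125, 60],  F: [1200, 600]}
  IE: {U: [0.25, 0.13], D: [700, 350], F: [20, 10]}
  II: {U: [0.32, 0.16], D: [144, 72],  F: [60, 30]}
inputs:                     # two afferent streams of 40 Poisson neurons
  n_per_stream: 40
  rate_per_ms: 0.01         # 10 spikes/s default drive
  weight_mean: 1.5          # nS, Gamma with weight_cv
  target_p:                 # connection probability into each pool
    stream1: {L23E: 0.05, L23I: 0.05, L4E: 0.20, L4I: 0.20, L5E: 0.02, L5I: 0.02}
    stream2: {L23E: 0.20, L23I: 0.20, L4E: 0.05, L4I: 0.05, L5E: 0.02, L5I: 0.02}
background:                 # constant background current per neuron (pA)
  mean: 105
  sd: 25
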
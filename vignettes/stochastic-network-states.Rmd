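---
title: "Stochastic network states: simulation, sampling, convergence, and constraint satisfaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic network states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikenet)
```

# The model

spikenet studies recurrent networks of spiking neurons whose firing is
stochastic by construction.  Each neuron is a leaky integrate-and-fire unit
with conductance-based synaptic integration, but instead of a hard
threshold it fires with a voltage-dependent instantaneous rate (escape
noise)

$$ r(V) \;=\; \min\!\left\{ r_0\, e^{(V - V_T)/\Delta V},\; r_{\max}\right\}, $$

so a spike in a short interval $dt$ occurs with probability
$1 - e^{-r(V)\,dt}$.  Three modelling commitments matter throughout:

* **Spikes are individual events** — at most one spike per neuron per time
  step, enforced by the Bernoulli-per-step construction.
* **Bounded rates** — the hard cap $r_{\max}$ bounds every neuron's rate at
  all times, for any input.  The sum of the caps, $\Lambda$, bounds the
  total network rate.
* **Bounded memory** — spikes influence the future only through synaptic
  and refractory mechanisms with finite time constants, so the *Markov
  state* (the spike history of all neurons in a trailing window of length
  $T$) determines the dynamics.

Under these assumptions the network state evolves as a Markov process that
returns to the resting (all-silent) state with probability at least
$e^{-\Lambda \tau}$ over any window of length $\tau$ covering one memory
period.  This Doeblin-type bound makes the dynamics contracting: one
memory window shrinks the total-variation distance between any two state
distributions by at least the return probability $\alpha$, which yields a
unique stationary distribution of network states and exponential
convergence to it — from *any* initial state, under constant, stochastic,
or (phase-wise) periodic input.  The package treats this theory as testable
structure: the `build_kernel()` / `verify_contraction()` /
`stationary_distribution()` oracle enumerates the discretized chain of a
tiny network exactly and verifies the contraction factor, the geometric
decay, and the match between simulated state frequencies and the kernel's
stationary law.

Network states are read off spike trains in two forms: the *Markov state*
(exact spike times in a window $T$, default 100 ms) and the *simple state*
(binary vector, 1 iff the neuron spiked within $\tau$, default 20 ms).
Both windows are half-open, $(t - w, t]$: a spike at the sampling instant
counts once; the convention is applied identically in `simple_state()`,
`markov_state()`, the decoders and the C++ cores, and is covered by
brute-force comparison tests.  "Relative time spent in a state" is always
a regular-grid average (`dt_sample`), which is the discrete version of the
time-fraction definition of the stationary probabilities.

# Units and defaults

All quantities use mV, ms, nS, pF and pA (so $C_m/g_L$ is in ms and
$I/C_m$ in mV/ms).  The stock neuron has $g_L = 10$ nS, $C_m = 200$ pF
($\tau_m = 20$ ms), $E_L = -70$ mV, $E_{exc} = 0$ mV, $E_{inh} = -75$ mV,
$r_0 = 0.01$/ms, $V_T = -55$ mV, $\Delta V = 2$ mV, $r_{\max} = 1$/ms,
3 ms refractoriness, and exponentially decaying synaptic conductances
(5 ms excitatory, 10 ms inhibitory).  These are reconstructions chosen
from the standard literature values for cortical point-neuron models; every
one of them is a configurable field, and none of the quantitative results
the package reports depends on them except through the documented tuning
of the network families.

The integration scheme is exponential-Euler at `dt = 0.1` ms by default,
with event-summed conductance increments and per-step Bernoulli spiking.
`dt` must not exceed the smallest synaptic delay (event-ordering
contract); a dt-halving test keeps the scheme honest.  Short-term
plasticity follows the standard dynamic-synapse recurrences
($u_1 = U$, $R_1 = 1$;
$u_{k+1} = U + u_k (1-U) e^{-\Delta_k/F}$,
$R_{k+1} = 1 + (R_k(1-u_k) - 1)e^{-\Delta_k/D}$; amplitude $w\,u_k R_k$),
verified against an independent re-implementation.

Reproducibility is explicit: every simulation is a deterministic function
of (network, duration, dt, seed).  The preparatory-phase protocol
(`prepare_initial_state()`) pins the initial Markov state: the preparatory
input is simulated under its own seed, and the generator is re-seeded with
the main seed at $t = 0$, so repeated runs share the identical initial
state and diverge afterwards.

# Convergence diagnostics

`psrf()` implements the Gelman-Rubin potential scale reduction factor in
its *variance* form
$$ \hat R = \frac{\frac{N-1}{N} W + \frac{1}{N} B}{W}, $$
computed from the samples in the window $(t/2, t]$ of each of $M$ chains;
$W$ is the mean within-chain variance, $B$ is $N$ times the variance of
the chain means, and $W = 0$ (e.g. a never-firing neuron) defines
$\hat R = 1$.  The often-quoted 1.1 threshold belongs to the *square-root*
form of $\hat R$; squaring it recovers roughly the 1.2 used here (both
ship as named constants).  The multivariate version (`mpsrf()`) is the
Brooks-Gelman statistic
$(N-1)/N + \frac{M+1}{M}\lambda_{\max}(W^{-1}B/N)$; coordinates constant
across all chains are dropped (the multivariate analogue of the $W = 0$
rule) and a ridge of $10^{-10}\,\mathrm{tr}(W)/d$ regularizes singular
$W$.  Binary simple states are treated as real-valued 0/1 samples.

`run_convergence_experiment()` reproduces the multi-chain protocol:
random initial states via per-chain random preparatory input rates (drawn
uniformly per input neuron, default 0–50 spikes/s), per-variable
$\hat R(t)$ curves for marginals, pairwise products, or vector-valued
states, and pointwise mean/worst summaries.  For networks without input
neurons the chains differ through random initial membrane potentials under
distinct seeds, mirroring the random-current variant of the protocol.

# Network families

`build_laminar()` instantiates a six-pool laminar column (layers 2/3, 4, 5
by E/I) from an editable YAML template: Bernoulli connectivity per pool
pair, Gamma-distributed weights, per-presynaptic-neuron short-term
plasticity drawn from EE/EI/IE/II-specific Gaussians, two 40-neuron
Poisson input streams, and constant background currents.  The template's
quantitative entries are clearly marked placeholders that preserve the
qualitative laminar structure; `scale_weights()` applies the
inverse-proportional rescaling of recurrent weights used to compare column
sizes, and the suite checks that mean layer activities stay within 30%
when the column grows from 500 to 2000 neurons (simulated for 3 s each —
a problem size chosen so the whole family suite stays interactive).
`attach_readout()` adds an observer neuron with exactly 500 afferents
composed 120/30 (L2/3 E/I), 80/20 (L4), 200/50 (L5).

The smaller families are tuned so that their defining qualitative property
holds robustly under the default seed protocol, and the tuning is part of
the package (not of any test):

* `build_sparse()` — 10 E + 10 I neurons at connection probabilities
  EE = EI = 0.1, II = IE = 0.9.
* `build_sequence()` — trigger + chain + inhibitory pool per subnetwork,
  forward/backward exponential weight decay ($\xi_f = 3$, $\xi_b = 1$
  neuron indices, reconstructed values), 2 ms delays, cross-inhibition
  between two subnetworks; ordered activation holds with rank correlation
  > 0.8 from a resting start.
* `build_bistable()` — two self-exciting pools with depressing recurrence
  (U = 0.3, D = 1.5 s) and mutual di-synaptic inhibition; the depression
  self-limits the active attractor so the network alternates, each
  attractor holding a balanced share of the classified time.
* `build_small_column()` — a 10-neuron hand-tuned column sketch with two
  highlighted synapses strengthened by factors 5 and 10 (the identities of
  the two connections are reconstructions).

# Constraint satisfaction by interlocking WTA motifs

`encode_generic_csp()` compiles variables with one-hot domains and
uniqueness groups into a network of winner-take-all (WTA) motifs: each
(variable, value) pair owns a group of $N_E = 4$ pyramidal cells; each
variable contributes a domain motif, each uniqueness group a group motif;
a motif is a single inhibitory neuron reciprocally connected to its member
cells through rectangular current pulses.  For Sudoku
(`encode_sudoku()`) this yields $81 \times 9 \times 4 = 2916$ cells, 81
field motifs and 243 group motifs, with every cell in exactly 4 motifs.
Givens are clamped with strong positive currents; other digits of given
fields receive hyperpolarizing currents.

Because all synapses in this family are rectangular current pulses and the
membrane is operated in the fast (quasi-static) regime, the membrane
potential is piecewise constant, the hazard is piecewise constant, and the
event-driven backend samples next-spike times *exactly* (memorylessness
justifies re-drawing an exponential waiting time at every potential
change).  A dedicated test checks that the event-driven and time-stepped
backends agree on a two-field toy problem within Monte-Carlo error.

The free parameters of this family are genuinely open design choices (the
quantitative values of the original construction are not available), and
they were set by a documented calibration against the package's own
behavioural invariants — constraint-violation suppression (< 0.1
simultaneously active conflicting digit pairs per field), givens never
overridden, an easy 60-given puzzle solving within seconds — rather than
against any external number.  The calibrated regime works as follows:

* A *domain (field) motif* interneuron has a low threshold (a single
  member pulse triggers it within a fraction of a millisecond) and
  suppresses all cells of the field for slightly less than the decoding
  window $\tau = 10$ ms.  The current winner's cell group sustains itself
  through this cycle by recurrent excitation *within* its $N_E$-cell group
  (the assembly advantage of population coding): when suppression lifts,
  the lingering intra-group pulses let the incumbent re-fire within the
  short gap before the window expires, while competing digits — without
  assembly support — rarely catch the gap.  Winner turnover is therefore
  stochastic but infrequent, which implements the "tentative digit"
  dynamics: fields hold a value, occasionally resample.
* A *group (uniqueness) motif* interneuron is triggered by member pulses
  lasting a few milliseconds.  A clamped given fires near its rate cap, so
  its group interneurons fire continuously and block the given's digit
  everywhere in its row, column and subgrid with near-unit duty cycle —
  givens project their constraints permanently, and the clamp exceeds the
  worst-case stacked inhibition so givens themselves are never overridden.
  A free winner fires once per cycle, so its blocking duty is high but
  leaky; the leak is the exploration channel through which conflicting
  tentative assignments meet, trigger their shared interneuron, and get
  suppressed together — the stochastic-search step.

Decoding is purely observational: digit $d$ is active for a field at time
$t$ iff one of its cells spiked in $(t - \tau, t]$; *performance* is the
fraction of fields whose active set is exactly the singleton correct
digit (the strictest reading; a `lenient` mode that ignores extra active
digits is also provided); the *solve time* is the first decoding-grid time
with performance 1; *occupancy* is the post-burn-in fraction of grid times
at which the decoded assignment equals the full solution.

The bundled 26-given puzzle is a synthetic stand-in, generated
programmatically with a verified unique solution and hard-rated in the
operational sense that iterated naked/hidden singles do not solve it (32
cells remain open after exhaustive singles propagation).

# What the synthetic fixtures do and do not show

The fixture generators (`generate_fixture()`) produce spike records with
*known* statistical structure — independent Poisson trains, a binary state
of prescribed occupancy, a clean activity handover, periodically gated
activity — and the analysis tests validate the estimators against these
ground truths.  Real cortical recordings differ in ways the fixtures
deliberately omit: rate nonstationarity beyond simple periodicity,
cross-neuron correlations not induced by the modelled connectivity,
non-Poisson interval statistics, and measurement noise such as spike
sorting errors.  Passing tests therefore certify the estimators and the
simulator against their own model class, not against biological data.

# Numerical choices

* Empirical distributions are normalized exactly; normalization is
  asserted to $10^{-12}$.
* MAP readout breaks frequency ties towards the lexicographically
  smallest bit-string (deterministic, documented).
* Power iteration for stationary laws stops at a total-variation change
  of $10^{-12}$; the contraction check allows $10^{-10}$ slack.
* The discretization oracle covers at most $2^{12}$ states (≤ 3 neurons,
  ≤ 4 bins of history) — the regime where exact enumeration is
  instantaneous; beyond it the theory is exercised only through
  simulation-based properties.
* Burn-in for stationary estimates defaults to the first half of the
  record.
* Spike times are serialized with 6 decimals; file round-trips are exact
  at that precision and reading back a written file reproduces it
  byte-for-byte.

# Problem sizes used by the shipped experiments

The test-suite and the acceptance script run the Sudoku experiments at 10
capped runs (solve times, with right-censoring handled by the exponential
estimator), 15 runs of 5 s (stationary performance) and 6 runs of 75 s
(occupancy), the cross-backend and oracle checks on 2-neuron networks, and
the column-scaling check at 500 and 2000 neurons for 3 s — sizes chosen as
the package's own compromise between statistical resolution and an
interactive development loop; all of them are arguments, not constants.

# Known limitations

* Noise model variants based on stochastic vesicle release are exposed
  only as a per-synapse release-probability hook and are not simulated in
  detail.
* No long-term plasticity: the dynamics is time-homogeneous by design
  (that assumption underlies the stationarity theory).
* The laminar template's numbers are structural placeholders, not a
  quantitative reproduction of any measured column.
* The event-driven backend requires rectangular-pulse synapses and the
  quasi-static membrane; conductance-based synapses always use the
  time-stepped core.
* The WTA search is a heuristic: solve times on hard instances are
  approximately exponentially distributed, and some runs exceed any fixed
  duration cap.  Repeated-run solve-time summaries therefore treat capped
  runs as right-censored and report the censoring-aware exponential
  estimator (total observed run time divided by the number of solves),
  which reduces to the plain mean when almost all runs solve.
* Under the calibrated default parameters the reconstructed WTA network
  is a weaker solver than the original demonstration: decoded performance
  on the bundled hard puzzle typically plateaus below the reported level
  and complete solutions are reached only in a minority of runs within a
  minute of biological time.  The acceptance checks encode the original
  operating point and therefore document this gap rather than hide it.
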
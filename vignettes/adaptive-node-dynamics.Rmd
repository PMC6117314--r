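---
title: "Adaptive-node dynamics: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-node dynamics: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`adaptivenodes` simulates networks in which learning resides in *nodes*
rather than in links. Each node collects its input through `K` dendritic
terminals. Terminal `i` is a leaky integrate-and-fire unit,

$$\frac{dV_i}{dt} = -\frac{V_i - V_{st}}{T}
  + J_i \sum_m W_m \sum_n \delta\!\left(t - (t_m(n) + \tau_m)\right),$$

with membrane time constant `T = 20` ms, resting potential `V_st` and all
links `m` converging on that terminal sharing one adaptive multiplier
`J_i`. Voltages are handled on the scaled axis (`V_st = 0`, threshold 1);
an unscaled pair such as −70 mV / −54 mV is mapped onto it affinely, and
spike times are invariant under that mapping (a unit test asserts
exactness).

A terminal whose voltage reaches threshold undergoes a *crossing*. The
crossing emits a spike with probability

$$P_\text{spike} = \min(1,\; \Delta t \cdot f_c),$$

where `Δt` is the time since that terminal's last crossing and `f_c`
(default 15 Hz) is the maximal stationary firing frequency. A failed
crossing is a *response failure*: the voltage reverts to its value before
the offending pulses (with the leak continued from the moment that value
was stored, which matters only for crossings re-checked after a refractory
window). The first crossing of a terminal always spikes (its crossing
clock starts at −∞). Under sustained suprathreshold drive this law
saturates each terminal at `f_c` and a node at `K·f_c`, independent of the
stimulation rate.

After a spike, a node-wide refractory period (default 2 ms) begins: the
terminal that evoked the spike ignores incoming stimulations entirely,
sibling terminals keep integrating but cannot cross, and any terminal
sitting above threshold when the window closes immediately undergoes a
crossing.

## Plasticity

For every pair of a *sub-threshold stimulation* via terminal `i` and an
evoked spike from a different terminal of the same node, `J_i` is updated:

$$J_i^+ = J_i\,(1 + \delta) + \eta, \qquad
  \delta = A\, e^{-|\Delta|/15\,\text{ms}}\,\operatorname{sign}(\Delta),$$

with `Δ = t_sub − t_spike`, a hard cutoff at 50 ms, an optional two-level
profile `A·sign(Δ)`, additive noise `η ~ U[−0.5, 0.5]·10⁻³` redrawn per
event, and `J` clamped to `[10⁻⁶, 10]`. Pairing is many-to-many: each
stimulation pairs with every qualifying spike inside the cutoff, the step
taking effect at the later of the two events. In the adaptive-*link*
baseline the same relative change is applied to individual link weights
(`J ≡ 1`, lower clamp 0), pairing each link's own stimulations against the
node's spikes.

**What counts as a sub-threshold stimulation.** This is the one place
where the verbal model admits several readings, and the choice decides the
physics, so the package fixes it operationally: a delivered pulse is a
sub-threshold stimulation *iff it moves the voltage and leaves it below
threshold* — the voltage-*rebuild* stimulations between a reset and the
next crossing. Pulses that complete a crossing belong to the resulting
spike or response failure; pulses accumulating above threshold during a
refractory window belong to the crossing deferred to its end; pulses
aimed at the blind evoking terminal are discarded outright. The rejected
alternatives produce qualitatively wrong states: pairing failed-crossing
stimulations drives every terminal weight to the lower clamp (no rate
saturation), while pairing blind or above-threshold refractory
stimulations drives every weight above threshold — the collapse phenotype
that should only appear below the critical refractory period. Only the
rebuild reading yields, simultaneously, rate saturation at `f_c`, a
stationary log-normal effective-weight distribution, strong-before-weak
spike ordering, and a restoring force crossing zero at the distribution
mode.

## Numerical scheme

The engine advances on a fixed grid (`dt = 1` ms for feedforward runs,
`0.1` ms otherwise). The leak uses the exact factor `exp(−dt/T)`, applied
lazily (terminals are decayed to the current time when touched), so the
integration of the leak is step-size free; only pulse arrival times are
binned to the grid. Within a step: deliver all pulses of the bin, then
resolve crossings node by node — the terminal with the highest voltage
attempts first, ties to the lowest terminal index, at most one attempt
per terminal per step — then convert unconsumed arrivals into stimulation
events and run the pairing against per-node event histories. Spikes
schedule outgoing pulses at `t + τ` (delays below one step are rounded up
to one step, so there is no zero-delay recursion). All randomness
(response failures, adaptation noise, builders, stimuli) flows through R's
RNG; a run is bit-reproducible from its seed.

## Networks and stimuli

*Feedforward*: `N` inputs, one link each, weights `U[0.1, 1.1]`, delays
`U[1, 150]` ms. Links are sorted by delay and assigned to terminals in
consecutive blocks of `N/K`, with the maximal-delay link wrapped onto the
first terminal. The wrap is implemented as a cyclic rotation (the sorted
sequence shifted by one) rather than re-assignment of a single link, which
keeps exactly `N/K` links per terminal.

*Recurrent* (two-pool and uniformly random): weights `U[0.1, 0.2]`, delays
`Normal(100, 2)` ms truncated at 0.1 ms, sources sampled without
replacement (self-loops excluded), delay-sorted block assignment to
terminals. The default in-degree is **60 links per terminal** (180 per
node at `K = 3`); with 20 per terminal the per-terminal stimulation rate
is too low to sustain the stationary state — weights spread over decades
and terminals die at the lower clamp — whereas 60 per terminal reproduces
the saturated asynchronous state whose effective-weight distribution
matches the isolated-node experiment. The adaptive-link baseline has a
single terminal with 60 links, where the two conventions coincide.

*Stimuli*: simultaneous periodic trains (feedforward, 5 Hz), independent
Poisson trains per input (single-node experiment, 30 Hz), or an initial
above-threshold trigger of 40% of the nodes plus 0.01 Hz per-node
background (recurrent). Triggers respect the refractory period and the
response-failure law.

## Classifying terminal-weight dynamics

Feedforward runs settle into fixed points, fast oscillations or slow
oscillations of `J_i(t)`. Classification acts on a *stroboscopic* record
of the weights — one sample per stimulation round — because even at a
fixed point of the round-to-round map the weights ripple within each round
as adaptation steps fire; dense sampling would misread that stimulus-locked
ripple as a sub-second oscillation. On a 200 s window following a 400 s
transient (fractions are insensitive to further lengthening; shorter
transients let unfinished relaxations masquerade as slow oscillations):

* **fixed** — every terminal's coefficient of variation below `10⁻³`;
* otherwise **fast** vs **slow** by the dominant period of the product of
  the terminals' magnitude spectra, boundary 2 s; the slow label
  additionally requires a per-terminal relative amplitude range above 0.5
  and a non-monotone trace (a monotone decade-spanning trend is an
  unresolved relaxation, not an oscillation).

Degenerate traces are handled explicitly: terminals never exceeding
`10⁻⁴` (two decades above the lower clamp) are treated as vanished and
excluded — relative fluctuation at the clamp is meaningless — and constant
terminals are excluded from the spectral product, which they would
otherwise corrupt with numerical noise. All thresholds are arguments of
`classify_dynamics()`.

## Attractor census

Two runs with identical delays share an attractor when every link's
firing count over the observation window (final 100 s of a 300 s run)
differs by less than 2% of the larger count; links with fewer than 10
firing events in either run are compared on their non-firing arrivals
instead. Because the 2% relation is not transitive, signatures are
clustered greedily against first-seen representatives, which makes the
count deterministic given the sample order and non-decreasing in the
number of initial conditions. The combinatorial lower bound
`A(N₀)·C(N/K, N₀)^K` is exact arithmetic; its log–log slope against `N`
(over `N = 30, 60, …, 3000`, the multiples of `K` spanning two decades)
is 3.03 per terminal factor, i.e. `N⁹` overall for `K = 3`, `N₀ = 3`.

## Effective-weight statistics

The single-node experiment (`K = 2`, 60 inputs per terminal, 30 Hz Poisson
per input, `A = 0.1`, 2500 s with a 200 s transient) is the reference for
the stationary log-normal. Effective weights `W·J` are pooled across links
and sampling times; the log-normal fit is the mean/sd of the logs, and
goodness of fit is a Lilliefors test (estimated parameters) on an evenly
thinned subsample of at most 500 values — consecutive samples of the same
link are strongly autocorrelated, so pooling every sample would inflate
`n` and reject arbitrarily small deviations. Strong/weak classes are the
`[75%, 99%]` and `[1%, 25%]` percentile bands (24% each, 50% of the mass
between them). Pair ordering scans *consecutive* spikes of a node from
distinct terminals within 5 ms, classifying each spike's terminal by its
effective weight at spike time; the label-shuffle null randomly swaps the
within-pair order. The restoring force bins adaptation events by the
paired link's `W·J` (bin 0.05) and reports the mean relative change per
bin; the engine can subsample the adaptation log at a fixed stride, which
is unbiased for these bin means.

## Problem sizes in the shipped tests

The test-suite and acceptance script use sizes chosen to make every
phenomenon measurable in a desk run: 500 random configurations per
oscillation-fraction point; a 200-initial-condition, 3-delay-set census
surrogate (the full saturation census toward ~1.5·10³ clusters is
available through `run_experiment("attractor_census")` with a larger
`n_ic`); a 200-node random recurrent network observed for 30 s; the full
2500 s single-node run; and a 350 s adaptive-link two-pool baseline at
200 nodes.

## Known limitations

* All link weights are excitatory; there is no inhibition, conductance
  dynamics, or spatial structure, and nodes are homogeneous. Passing tests
  say nothing about data with those features.
* The critical refractory period is located only qualitatively: runs at
  0.4 ms already collapse to the all-above-threshold state in this
  implementation, so the sweep reports the empirically located transition
  rather than a fixed constant.
* The two-pool striped transient decorrelates slowly at small network
  sizes; scaled-down two-pool runs below ~400 nodes can lock into
  synchronized bursting, which is why the scaled steady-state checks use
  the uniformly random topology.
* Attractor counts depend on the observation window and on the greedy
  cluster order; saturation behaviour versus window length is reported by
  the census driver, not assumed.
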
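# adaptivenodes

Spiking neural networks whose learning lives in **adaptive nodes**
(dendritic terminals) rather than in individual links — an R package with
a compiled fixed-step simulation engine and analysis drivers for the
phenomena this class of models produces: oscillating terminal weights,
exponentially many dynamical attractors in feedforward nets, and a
stationary **log-normal distribution of effective link weights** in
recurrent nets, maintained by a stochastic restoring force that emerges
from spontaneous strong-before-weak spike-pair ordering.

## The model

Each node has `K` dendritic terminals. Terminal `i` is a leaky
integrate-and-fire unit,

    dV_i/dt = -(V_i - V_st)/T  +  J_i * sum_m W_m * sum_n delta(t - (t_m(n) + tau_m)),

with `T = 20` ms, fixed link weights `W_m` and delays `tau_m`, and one
adaptive multiplier `J_i` shared by every link into terminal `i`. A
threshold crossing emits a spike with probability `min(1, dt * f_c)`
(`dt` = time since the terminal's last crossing), so a terminal's
stationary rate saturates at `f_c`; failed crossings are *response
failures* that revert the voltage. A spike triggers a 2 ms node-wide
refractory period. For every pair of a sub-threshold stimulation via
terminal `i` and a spike from a different terminal, the terminal weight
updates multiplicatively,

    J_i+ = J_i * (1 + delta) + eta,    delta = A * exp(-|D|/15 ms) * sign(D),

with `D = t_sub - t_spike`, a 50 ms cutoff, uniform noise `eta`, and `J`
clamped to `[1e-6, 10]`. The classical adaptive-*link* rule (the same
`delta` applied to individual `W_m`) is included as a baseline. The
`W_m * J_i` products are the *effective link weights* whose population
distribution is the central observable.

The package provides builders for the three studied topologies
(feedforward; two pools of mutually coupled nodes; uniformly random
recurrent), stimulation protocols (simultaneous periodic, Poisson per
input, initial trigger plus background), and estimators for dynamics
classification, attractor censuses, strong/weak spike-pair ordering
(`P_SW`, `P_WS`), and the restoring-force curve. The methods vignette
(`vignettes/adaptive-node-dynamics.Rmd`) documents the model semantics,
numerical scheme and every tunable default.

## Worked example

```r
library(adaptivenodes)

## 1. A feedforward adaptive node under 5 Hz simultaneous stimulation:
##    classify the stationary dynamics of its terminal weights.
net  <- build_feedforward(15, K = 3, seed = 1)
stim <- make_stimulus("periodic_simultaneous", duration_s = 600,
                      n_inputs = 15, rate_hz = 5)
sim  <- simulate_network(net, stim, 600,
                         params = lif_params(f_c = Inf, dt_ms = 1),
                         record = list(record_J_every_ms = 200))
tr <- j_traces(sim)
classify_dynamics(tr$J[tr$time_s >= 400, ], dt_s = 0.2)
#> Dynamics: fast_oscillation (dominant period 0.476 s)

## 2. The random-input single node (K = 2, 120 Poisson inputs at 30 Hz):
##    stationary log-normal weights and spontaneous spike ordering.
node <- simulate_random_input_node(duration_s = 800, transient_s = 200,
                                   seed = 21)
node
#> Simulation of 1 node(s) for 800 s: 24084 spikes, 2088602 response failures
#> Mean node rate over counting window: 29.97 Hz

wj <- as.vector(node$wj_samples)          # pooled effective weights W * J
effective_weight_distribution(wj)
#> Effective-weight distribution (n = 72120 ): meanlog = -1.637 , sdlog = 0.4068
#>   log-normal KS stat = 0.0464 , p = 0.012

cl <- classify_strong_weak(wj)
spike_pair_ordering(node, cl)
#> Pair ordering over 1417 pairs: P_SW = 0.1108 , P_WS = 0.02752 , ratio = 4.026 , z = 8.43

subset(restoring_force(node$adapt_log), n > 5000)
#>   wj_mid     n  force    sd
#> 1  0.040  5237  0.028 0.518
#> 2  0.081 57611  0.011 0.380
#> 3  0.125 99546  0.000 0.276
#> 4  0.172 68740 -0.002 0.226
#> 5  0.221 32145 -0.004 0.208
#> 6  0.271 13122 -0.002 0.196
```

Reading the output: the node fires at ~30 Hz (`K * f_c`) while each
terminal saturates at `f_c = 15` Hz; the effective weights follow a
log-normal (Lilliefors p > 0.01) although individual weights keep moving;
a strong-terminal spike precedes a weak-terminal one four times more often
than the reverse; and the mean relative change of `J` is positive below
the distribution mode (~0.17) and negative above it — the restoring force
that holds the distribution stationary.

Full experiments (including the 1000-node recurrent networks and the
refractory-period sweep) run through `run_experiment()` or the
command-line front-end:

```sh
Rscript inst/scripts/run-experiment.R --experiment random_recurrent \
    --seed 1 --out results/recurrent
```

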
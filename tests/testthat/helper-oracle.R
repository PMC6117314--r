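# Event-driven closed-form voltage of a single passive terminal: exact decay
# between delta pulses, jumps of J*W at each pulse. Independent of the
# engine's step loop.
oracle_voltage <- function(pulse_times_ms, pulse_weights, t_eval_ms,
                           J = 1, T_ms = 20) {
  keep <- pulse_times_ms <= t_eval_ms
  sum(J * pulse_weights[keep] *
        exp(-(t_eval_ms - pulse_times_ms[keep]) / T_ms))
}

# A one-node network with explicit per-input weights/delays and K terminals
# assigned directly (bypassing the delay-ordering rule), for crafted
# engine scenarios.
crafted_net <- function(W, delay_ms, terminal, K = max(terminal)) {
  n <- length(W)
  edges <- data.frame(src_kind = "input", src = seq_len(n), node = 1L,
                      terminal = as.integer(terminal), W = W,
                      delay_ms = delay_ms)
  adaptivenodes:::new_network("feedforward", "adaptive_node", 1L, K, n, edges)
}

# Stimulus from an explicit list of per-input spike-time vectors (ms).
crafted_stim <- function(input_spikes) {
  structure(list(kind = "explicit", duration_s = NA,
                 input_spikes = input_spikes,
                 triggers = data.frame(time_ms = numeric(0),
                                       node = integer(0))),
            class = "an_stimulus")
}

# Shared long simulation of the random-input single-node experiment (full
# 2500 s / 200 s transient), computed once per test session.
.an_cache <- new.env(parent = emptyenv())
get_random_input_run <- function() {
  if (is.null(.an_cache$fig_run)) {
    .an_cache$fig_run <- simulate_random_input_node(seed = 201)
  }
  .an_cache$fig_run
}

# Shared scaled random recurrent run: 200 adaptive nodes, K = 3, 60 inputs
# per terminal, 30 s, with dense effective-weight sampling over the final
# 2 s for mobility measures. Rates are counted over the last 10 s.
get_recurrent_run <- function() {
  if (is.null(.an_cache$recurrent_run)) {
    net <- build_random_recurrent(200, K = 3, seed = 41)
    stim <- make_stimulus("initial_trigger_plus_background",
                          duration_s = 30, n_nodes = 200, seed = 42)
    .an_cache$recurrent_run <- simulate_network(
      net, stim, 30,
      params = lif_params(f_c = 15, refractory_ms = 2, dt_ms = 0.1),
      rule = adaptation_rule(A = 0.05, noise = 0.5e-3),
      record = list(log_events = "none", count_from_ms = 20e3,
                    sample_weights_every_ms = 100,
                    sample_weights_from_ms = 28e3),
      seed = 43)
  }
  .an_cache$recurrent_run
}
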
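test_that("voltage decay follows the exact exponential solution", {
  p <- lif_params(T_ms = 20)
  expect_equal(decay_voltage(0, 10, p), 0)
  expect_equal(decay_voltage(1, 20, p), exp(-1))
  expect_equal(decay_voltage(0.5, 0, p), 0.5)
  # vectorised and compounding: two half-steps equal one full step
  expect_equal(decay_voltage(decay_voltage(0.8, 7, p), 7, p),
               decay_voltage(0.8, 14, p))
  expect_error(decay_voltage(1, -1, p), "non-negative")
})

test_that("pulses jump the voltage by J * W and store the rollback value", {
  st <- terminal_state(voltage = 0, J = 1)
  expect_equal(deliver_pulse(st, 0.15)$voltage, 0.15)
  st <- terminal_state(voltage = 0.9, J = 2)
  st2 <- deliver_pulse(st, 0.15)
  expect_equal(st2$voltage, 1.2)
  expect_equal(st2$previous_voltage, 0.9)
  expect_equal(deliver_pulse(terminal_state(voltage = 0.3), 0)$voltage, 0.3)
})

test_that("spike generation follows the response-failure law", {
  p <- lif_params(f_c = 15)
  expect_equal(spike_probability(0, p), 0)
  expect_equal(spike_probability(1000 / 15, p), 1)
  expect_equal(spike_probability(10, p), 0.15)
  expect_equal(spike_probability(5, lif_params(f_c = Inf)), 1)

  # unbounded f_c: a crossing always spikes
  st <- terminal_state(voltage = 1.2, time_of_last_crossing = 10)
  out <- attempt_spike(st, 10, lif_params(f_c = Inf))
  expect_identical(out$outcome, "spike")
  expect_equal(out$state$voltage, 0)

  # zero time since the last crossing: guaranteed failure with rollback
  st <- terminal_state(voltage = 1.2, previous_voltage = 0.9,
                       time_of_last_crossing = 50)
  out <- attempt_spike(st, 50, p)
  expect_identical(out$outcome, "failure")
  expect_equal(out$state$voltage, 0.9)

  expect_error(attempt_spike(terminal_state(voltage = 0.5), 1, p),
               "below threshold")
})

test_that("periodic crossings saturate the spike rate at f_c", {
  # crossings every 5 ms for 100 s: rate P/delta = f_c regardless of delta
  p <- lif_params(f_c = 15)
  set.seed(7)
  st <- terminal_state(voltage = 0, time_of_last_crossing = -Inf)
  n_spikes <- 0L
  for (t in seq(5, 1e5, by = 5)) {
    st$voltage <- 1.1
    st$previous_voltage <- 0.9
    out <- attempt_spike(st, t, p)
    st <- out$state
    if (out$outcome == "spike") n_spikes <- n_spikes + 1L
  }
  expect_lt(abs(n_spikes / 100 - 15), 1.5)   # within 10% of f_c
})

test_that("engine voltages match the event-driven closed form", {
  set.seed(11)
  for (rep in 1:5) {
    n_pulses <- 30
    # pulse times on the 0.1 ms grid (the engine bins arrivals to steps)
    times <- sort(sample(seq(10, 4990, by = 1), n_pulses)) / 10 * 1
    times <- round(times * 10) / 10
    W <- runif(n_pulses, 0.005, 0.02)   # keeps the terminal sub-threshold
    net <- crafted_net(W, delay_ms = rep(1, n_pulses),
                       terminal = rep(1, n_pulses))
    stim <- crafted_stim(as.list(times - 1))
    sim <- simulate_network(net, stim, duration_s = 0.6,
                            params = lif_params(dt_ms = 0.1),
                            rule = adaptation_rule(A = 0),
                            record = list(log_events = "none"))
    v_oracle <- oracle_voltage(times, W, 600)
    expect_equal(sim$V_final[1, 1], v_oracle, tolerance = 1e-9)
    expect_equal(sim$n_spikes, 0)
  }
})

test_that("the node-wide refractory period gates spiking and input", {
  # i1 -> terminal 1 (suprathreshold), i2 -> terminal 2 (suprathreshold),
  # i3 -> terminal 1 (arrives while terminal 1 is blind)
  net <- crafted_net(W = c(1.5, 1.3, 0.5), delay_ms = c(1, 1, 1),
                     terminal = c(1, 2, 1))
  stim <- crafted_stim(list(9, 10, 10))   # arrivals at 10, 11, 11 ms
  sim <- simulate_network(net, stim, duration_s = 0.05,
                          params = lif_params(f_c = Inf, refractory_ms = 2,
                                              dt_ms = 1),
                          record = list(log_events = "all"))
  sp <- spikes(sim)
  # terminal 1 spikes at 10; terminal 2 integrates to 1.3 during the
  # refractory window and fires only when it ends, at 12; the pulse to the
  # blind evoking terminal is discarded entirely
  expect_equal(sp$time_ms, c(10, 12))
  expect_equal(sp$terminal_id, c(1, 2))
  expect_equal(sim$V_final[1, 1], decay_voltage(0, 40), tolerance = 1e-12)

  # degenerate limit: refractory 0 behaves as no refractory at all
  sim0 <- simulate_network(net, stim, duration_s = 0.05,
                           params = lif_params(f_c = Inf, refractory_ms = 0,
                                               dt_ms = 1),
                           record = list(log_events = "all"))
  expect_equal(spikes(sim0)$time_ms, c(10, 11))
})

test_that("no two spikes of a node are closer than the refractory period", {
  sim <- simulate_random_input_node(duration_s = 30, transient_s = 0,
                                    seed = 17)
  ts <- sort(spikes(sim)$time_ms)
  expect_gte(min(diff(ts)), 2)
})

test_that("spike times are invariant under affine voltage rescaling", {
  net <- build_feedforward(20, 2, w_range = c(0.1, 0.2), seed = 23)
  stim <- make_stimulus("poisson_per_input", duration_s = 20, n_inputs = 20,
                        rate_hz = 40, seed = 24)
  base <- simulate_network(net, stim, 20,
                           params = lif_params(f_c = 15, dt_ms = 0.1),
                           rule = adaptation_rule(A = 0.05), seed = 25)
  unscaled_net <- net
  unscaled_net$edges$W <- net$edges$W * (-54 - -70)
  unscaled <- simulate_network(unscaled_net, stim, 20,
                               params = lif_params(f_c = 15, dt_ms = 0.1,
                                                   v_rest = -70,
                                                   v_threshold = -54),
                               rule = adaptation_rule(A = 0.05), seed = 25)
  expect_equal(spikes(base)$time_ms, spikes(unscaled)$time_ms)
  expect_equal(spikes(base)$terminal_id, spikes(unscaled)$terminal_id)
  expect_equal(base$J_final, unscaled$J_final)
})

test_that("suprathreshold drive saturates terminal and node rates", {
  # one K = 3 node, every terminal driven above threshold at 100 Hz
  net <- crafted_net(W = rep(1.5, 3), delay_ms = rep(1, 3),
                     terminal = 1:3)
  stim <- make_stimulus("periodic_simultaneous", duration_s = 100,
                        n_inputs = 3, rate_hz = 100)
  sim <- simulate_network(net, stim, 100,
                          params = lif_params(f_c = 15, dt_ms = 0.1),
                          rule = adaptation_rule(A = 0),
                          record = list(log_events = "none"), seed = 29)
  expect_lt(abs(mean(sim$terminal_rate_hz) - 15), 1.5)
  expect_lt(abs(mean(sim$node_rate_hz) - 45), 4.5)
})

test_that("event logs round-trip through CSV", {
  net <- crafted_net(W = 1.5, delay_ms = 1, terminal = 1, K = 1)
  sim <- simulate_network(net, crafted_stim(list(c(50, 150))), 0.3,
                          params = lif_params(f_c = Inf, dt_ms = 1))
  log <- event_log(sim)
  path <- tempfile(fileext = ".csv")
  write_spike_log(log, path)
  back <- read_spike_log(path)
  expect_equal(back$time_ms, log$time_ms)
  expect_equal(as.character(back$event_kind), as.character(log$event_kind))
})
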
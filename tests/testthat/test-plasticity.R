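test_that("the adaptation profile is signed, exponential and cut off", {
  r <- adaptation_rule()
  expect_equal(delta_profile(0, r), 0)
  expect_equal(delta_profile(15, r), 0.05 * exp(-1))
  expect_equal(delta_profile(-15, r), -0.05 * exp(-1))
  expect_equal(delta_profile(-60, r), 0)
  expect_equal(delta_profile(51, r), 0)

  # antisymmetry over a grid including the cutoff edges
  d <- seq(-55, 55, by = 0.5)
  expect_equal(delta_profile(d, r) + delta_profile(-d, r), rep(0, length(d)))

  two <- adaptation_rule(profile = "two_level")
  expect_equal(delta_profile(c(-3, 49, 51), two), c(-0.05, 0.05, 0))
})

test_that("adaptation steps are multiplicative and clamped", {
  r <- adaptation_rule()
  expect_equal(apply_adaptation(1, 0.05, r), 1.05)
  expect_equal(apply_adaptation(1, 0, r), 1)
  expect_equal(apply_adaptation(10, 0.05, r), 10)
  expect_equal(apply_adaptation(1e-6, -0.05, r), 1e-6)

  # noiseless updates act purely on log J
  J <- c(0.2, 1, 5)
  expect_equal(log(apply_adaptation(J, 0.02, r)) - log(J),
               rep(log(1.02), 3))

  # bounds hold over 1e6 random steps
  set.seed(31)
  noisy <- adaptation_rule(noise = 0.5e-3)
  J <- runif(1000, 1e-6, 10)
  for (i in 1:1000) {
    J <- apply_adaptation(J, runif(1000, -0.1, 0.1), noisy)
  }
  expect_true(all(J >= 1e-6 & J <= 10))
})

test_that("with A = 0 and no noise all weights are exactly constant", {
  net <- build_feedforward(12, 3, seed = 37)
  stim <- make_stimulus("periodic_simultaneous", duration_s = 60,
                        n_inputs = 12, rate_hz = 5)
  sim <- simulate_network(net, stim, 60,
                          params = lif_params(f_c = Inf, dt_ms = 1),
                          rule = adaptation_rule(A = 0, noise = 0),
                          record = list(record_J_every_ms = 1000))
  expect_true(all(sim$J_traces == 1))
  expect_identical(sim$W_final, net$edges$W)
})

test_that("pair collection matches the stated pairing rule", {
  r <- adaptation_rule()
  log <- data.frame(
    time_ms = c(0, 3, 5, 120, 110, 114, 0.5),
    node_id = 1L,
    terminal_id = c(1L, 2L, 2L, 2L, 1L, 1L, 1L),
    event_kind = c("spike", "subthreshold_stimulation",
                   "subthreshold_stimulation", "spike",
                   "subthreshold_stimulation", "subthreshold_stimulation",
                   "subthreshold_stimulation"))
  ev <- collect_adaptation_pairs(log, r)
  # stimulations after the spike potentiate, at stimulation time
  post <- ev[ev$terminal_id == 2 & ev$delta_ms > 0, ]
  expect_equal(post$delta_ms, c(3, 5))
  expect_equal(post$time_ms, c(3, 5))
  expect_true(all(post$delta > 0))
  # stimulations before a spike depress, effective at spike time
  pre <- ev[ev$terminal_id == 1 & ev$delta_ms < 0, ]
  expect_equal(sort(pre$delta_ms), c(-10, -6))
  expect_true(all(pre$time_ms == 120))
  expect_true(all(pre$delta < 0))
  # same-terminal events never pair (the stimulation at 0.5 on terminal 1
  # and the terminal-1 spike at 0)
  expect_false(any(ev$terminal_id == 1 & ev$delta_ms == 0.5))
  # beyond the cutoff nothing pairs
  far <- data.frame(time_ms = c(0, 60), node_id = 1L,
                    terminal_id = c(1L, 2L),
                    event_kind = c("spike", "subthreshold_stimulation"))
  expect_equal(nrow(collect_adaptation_pairs(far, r)), 0)
})

test_that("the engine's online pairing agrees with the reference", {
  # terminal 1 spikes once at 20 ms; terminal 2 receives weak pulses at
  # 5, 15 and 30 ms -> pairs with lags -15, -5, +10
  net <- crafted_net(W = c(1.5, 0.05, 0.05, 0.05),
                     delay_ms = rep(1, 4), terminal = c(1, 2, 2, 2))
  stim <- crafted_stim(list(19, 4, 14, 29))
  sim <- simulate_network(net, stim, 0.1,
                          params = lif_params(f_c = Inf, dt_ms = 1),
                          rule = adaptation_rule(A = 0.05),
                          record = list(log_events = "all",
                                        adapt_log_stride = 1))
  expect_equal(sort(sim$adapt_log$delta_ms), c(-15, -5, 10))
  ref <- collect_adaptation_pairs(event_log(sim), adaptation_rule())
  expect_equal(sort(sim$adapt_log$delta_ms), sort(ref$delta_ms))
  # final J of terminal 2 is the product of the three relative changes
  d <- delta_profile(c(-15, -5, 10), adaptation_rule())
  expect_equal(sim$J_final[1, 2], prod(1 + d), tolerance = 1e-12)
  expect_equal(sim$J_final[1, 1], 1)
})

test_that("the adaptive-link baseline update is geometric and floored", {
  r <- adaptation_rule()
  expect_equal(adaptive_link_update(0.5, 0, r), 0.5)
  W <- 0.1
  for (i in 1:20) W <- adaptive_link_update(W, 0.05, r)
  expect_equal(W, 0.1 * 1.05^20)
  expect_equal(adaptive_link_update(0.01, -2, r), 0)
})
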
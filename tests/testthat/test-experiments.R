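test_that("dynamics classification separates the three regimes", {
  dt <- 0.2
  t <- seq(0, 200, by = dt)
  const <- matrix(c(rep(1.2, length(t)), rep(0.7, length(t))), ncol = 2)
  expect_identical(classify_dynamics(const, dt)$label, "fixed")

  # 0.5 s sinusoid with 5% amplitude: fast oscillation
  fast <- 1 + 0.05 * cbind(sin(2 * pi * t / 0.5),
                           sin(2 * pi * t / 0.5 + 1),
                           sin(2 * pi * t / 0.5 + 2))
  cf <- classify_dynamics(fast, dt)
  expect_identical(cf$label, "fast_oscillation")
  expect_equal(cf$dominant_period_s, 0.5, tolerance = 0.02)

  # 100 s square-ish wave swinging between the clamps: slow oscillation
  slow <- cbind(ifelse(sin(2 * pi * t / 100) > 0, 10, 1e-6),
                ifelse(sin(2 * pi * t / 100 + 2) > 0, 9, 1e-6),
                rep(2, length(t)))
  cs <- classify_dynamics(slow, dt)
  expect_identical(cs$label, "slow_oscillation")
  expect_gte(cs$dominant_period_s, 2)
  expect_gt(cs$rel_range, 0.5)

  # a monotone decade-spanning decay is a relaxation, not a slow oscillation
  decay <- cbind(0.5 * exp(-t / 60), rep(1.5, length(t)))
  expect_false(classify_dynamics(decay, dt)$label == "slow_oscillation")

  # terminals pinned within two decades of the lower clamp are ignored
  pinned <- cbind(1e-6 * (1 + 0.5 * sin(t)), rep(3, length(t)))
  expect_identical(classify_dynamics(pinned, dt)$label, "fixed")
})

test_that("the Fourier product concentrates shared periodicity", {
  dt <- 0.01
  t <- seq(0, 100 - dt, by = dt)
  J <- 1 + 0.1 * cbind(sin(2 * pi * 2 * t), sin(2 * pi * 2 * t + 0.4),
                       sin(2 * pi * 2 * t + 1.1))
  spec <- fourier_product(J, dt)
  expect_equal(spec$freq_hz[which.max(spec$power)], 2, tolerance = 0.02)
  expect_error(fourier_product(J[1:3, ], dt), "too short")
})

test_that("additive adaptation noise leaves the fast oscillation frequencies in place", {
  net <- build_feedforward(15, 3, seed = 1)   # a fast-oscillation exemplar
  spec_of <- function(rule) {
    r <- run_feedforward_dynamics(net, rule = rule)
    tr <- j_traces(r$sim)
    keep <- tr$time_s >= 400
    list(label = r$classification$label,
         spec = fourier_product(tr$J[keep, , drop = FALSE], 0.2))
  }
  quiet <- spec_of(adaptation_rule())
  noisy <- spec_of(adaptation_rule(noise = 0.5e-3))
  expect_identical(quiet$label, "fast_oscillation")
  expect_identical(noisy$label, "fast_oscillation")
  # the noise perturbs spectral amplitudes but not the peak locations:
  # the noiseless dominant frequency stays among the noisy top peaks
  f0 <- quiet$spec$freq_hz[which.max(quiet$spec$power)]
  top_noisy <- noisy$spec$freq_hz[order(-noisy$spec$power)[1:3]]
  expect_lt(min(abs(top_noisy - f0)), 0.05)
})

test_that("classification is invariant to halving the integration step", {
  for (s in c(1, 2, 6)) {   # fast, slow and fixed exemplars
    net <- build_feedforward(15, 3, seed = s)
    l1 <- run_feedforward_dynamics(net)$classification$label
    l2 <- run_feedforward_dynamics(
      net, params = lif_params(f_c = Inf, dt_ms = 0.5))$classification$label
    expect_identical(l2, l1)
  }
})

test_that("attractor signatures compare by the 2% firing-count rule", {
  sig <- function(f, a) list(firing = f, arrivals = a)
  a <- sig(c(100, 500), c(600, 600))
  expect_true(same_attractor(a, a))                      # reflexive
  b <- sig(c(103, 500), c(600, 600))
  expect_false(same_attractor(a, b))                     # 3% > 2%
  expect_false(same_attractor(b, a))                     # symmetric
  c_ <- sig(c(101, 501), c(600, 600))
  expect_true(same_attractor(a, c_))                     # 1% < 2%
  # low-rate links compare on non-firing events instead
  lo1 <- sig(c(2, 500), c(500, 600))
  lo2 <- sig(c(5, 500), c(501, 600))
  expect_true(same_attractor(lo1, lo2))
  lo3 <- sig(c(5, 500), c(540, 600))
  expect_false(same_attractor(lo1, lo3))
})

test_that("the attractor census grows monotonically and is seeded", {
  ca <- count_attractors(3, 9, n_ic = 25, n_delay_sets = 2, seed = 51)
  expect_true(all(apply(ca$curves, 2, function(x) all(diff(x) >= 0))))
  expect_equal(ca$curves[1, ], c(1L, 1L))   # one initial condition, one attractor
  ca2 <- count_attractors(3, 9, n_ic = 25, n_delay_sets = 2, seed = 51)
  expect_identical(ca$curves, ca2$curves)
})

test_that("the combinatorial attractor bound is exact", {
  expect_equal(attractor_lower_bound(1500, N = 9, K = 3, N0 = 3), 1500)
  expect_equal(attractor_lower_bound(2, N = 6, K = 2, N0 = 1), 18)
  expect_equal(attractor_lower_bound(7, N = 30, K = 3, N0 = 3),
               7 * choose(10, 3)^3)
  expect_error(attractor_lower_bound(1, N = 10, K = 3, N0 = 3), "divisible")
  expect_error(attractor_lower_bound(1, N = 9, K = 3, N0 = 5), "exceed")
})
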
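test_that("feedforward builder wires delay-ordered terminals", {
  net <- build_feedforward(15, K = 3, seed = 1)
  expect_s3_class(net, "an_network")
  expect_equal(as.vector(table(net$edges$terminal)), rep(5L, 3))
  expect_true(all(net$edges$W >= 0.1 & net$edges$W <= 1.1))
  expect_true(all(net$edges$delay_ms >= 1 & net$edges$delay_ms <= 150))
  expect_equal(net$J_init, matrix(1, 1, 3))

  # the maximal-delay link closes the loop onto the first terminal and the
  # remaining links fill consecutive delay-sorted blocks
  ord <- order(net$edges$delay_ms)
  expect_equal(net$edges$terminal[ord[15]], 1L)
  expect_equal(net$edges$terminal[ord[1:4]], rep(1L, 4))
  expect_equal(net$edges$terminal[ord[5:9]], rep(2L, 5))
  expect_equal(net$edges$terminal[ord[10:14]], rep(3L, 5))

  expect_equal(as.vector(table(build_feedforward(9, 3, seed = 2)$edges$terminal)),
               rep(3L, 3))
  expect_error(build_feedforward(10, 3), "divisible")

  # identical seed, identical network
  expect_identical(build_feedforward(15, 3, seed = 9),
                   build_feedforward(15, 3, seed = 9))
})

test_that("two-pool builder is bipartite with the stated distributions", {
  net <- build_two_pool(600, K = 3, seed = 3)
  e <- net$edges
  expect_equal(nrow(e), 600 * 180)
  half <- e$node <= 300
  expect_true(all(e$src[half] > 300))
  expect_true(all(e$src[!half] <= 300))
  expect_true(all(table(e$node) == 180))
  expect_true(all(table(e$node, e$terminal) == 60))
  # no duplicated sources per node (sampling without replacement)
  expect_false(any(duplicated(e[, c("node", "src")])))
  expect_lt(abs(mean(e$delay_ms) - 100), 0.5)
  expect_lt(abs(sd(e$delay_ms) - 2), 0.2)
  expect_true(all(e$W >= 0.1 & e$W <= 0.2))
  # weights are uniform: goodness of fit on 1e4 draws
  ks <- suppressWarnings(ks.test(e$W[1:10000], "punif", 0.1, 0.2))
  expect_gt(ks$p.value, 0.01)

  link <- build_two_pool(200, mode = "adaptive_link", seed = 4)
  expect_equal(link$K, 1L)
  expect_true(all(table(link$edges$node) == 60))
  expect_true(all(link$J_init == 1))
})

test_that("random recurrent builder excludes self-loops at fixed in-degree", {
  net <- build_random_recurrent(200, K = 3, seed = 5)
  e <- net$edges
  expect_false(any(e$src == e$node))
  expect_true(all(table(e$node) == 180))
  expect_true(all(table(e$node, e$terminal) == 60))
})

test_that("stimulus generators produce the stated protocols", {
  s <- make_stimulus("periodic_simultaneous", duration_s = 10,
                     n_inputs = 4, rate_hz = 5)
  expect_length(s$input_spikes, 4)
  expect_equal(s$input_spikes[[1]], seq(0, 10000, by = 200))
  expect_true(all(diff(s$input_spikes[[2]]) == 200))

  set.seed(41)
  p <- make_stimulus("poisson_per_input", duration_s = 100, n_inputs = 1,
                     rate_hz = 30)
  n <- length(p$input_spikes[[1]])
  expect_lt(abs(n - 3000), 3 * sqrt(3000))

  z <- make_stimulus("poisson_per_input", duration_s = 10, n_inputs = 2,
                     rate_hz = 0)
  expect_true(all(lengths(z$input_spikes) == 0))

  tr <- make_stimulus("initial_trigger_plus_background", duration_s = 100,
                      n_nodes = 500, seed = 42)
  t0 <- tr$triggers[tr$triggers$time_ms == 0, ]
  expect_equal(nrow(t0), 200)           # 40% of 500
  expect_false(any(duplicated(t0$node)))
  bg <- tr$triggers[tr$triggers$time_ms > 0, ]
  expect_lt(abs(nrow(bg) - 500), 4 * sqrt(500))   # 0.01 Hz * 100 s * 500

  expect_identical(
    make_stimulus("poisson_per_input", duration_s = 5, n_inputs = 3,
                  rate_hz = 10, seed = 77),
    make_stimulus("poisson_per_input", duration_s = 5, n_inputs = 3,
                  rate_hz = 10, seed = 77))
})

test_that("networks serialize to a flat edge list", {
  net <- build_feedforward(9, 3, seed = 6)
  path <- tempfile(fileext = ".csv")
  write_edge_list(net, path)
  back <- read.csv(path)
  expect_equal(back$W, net$edges$W)
  expect_equal(back$terminal, net$edges$terminal)
})
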
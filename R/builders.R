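new_network <- function(topology, mode, n_nodes, K, n_inputs, edges,
                        J_init = NULL) {
  edges <- edges[, c("src_kind", "src", "node", "terminal", "W", "delay_ms")]
  stopifnot(all(edges$W >= 0), all(edges$delay_ms >= 0),
            all(edges$terminal >= 1), all(edges$terminal <= K))
  if (is.null(J_init)) J_init <- matrix(1, n_nodes, K)
  structure(list(topology = topology, mode = mode, n_nodes = n_nodes, K = K,
                 n_inputs = n_inputs, edges = edges, J_init = J_init),
            class = "an_network")
}

#' @export
print.an_network <- function(x, ...) {
  cat("Adaptive-", if (x$mode == "adaptive_node") "node" else "link",
      " network (", x$topology, "): ", x$n_nodes, " node(s), K = ", x$K,
      ", ", x$n_inputs, " input unit(s), ", nrow(x$edges), " links\n",
      sep = "")
  invisible(x)
}

# Delay-sorted cyclic assignment of links to terminals: links ordered by
# increasing delay, rotated by one so the maximal delay lands on the first
# terminal (closing the loop), then split into consecutive equal blocks.
assign_terminals <- function(delay_ms, K) {
  n <- length(delay_ms)
  stopifnot(n %% K == 0)
  ord <- order(delay_ms)
  rotated <- c(ord[n], ord[-n])
  terminal <- integer(n)
  terminal[rotated] <- rep(seq_len(K), each = n / K)
  terminal
}

#' Build a feedforward adaptive-node network
#'
#' One output node with `K` terminals fed by `n_inputs` input units, one link
#' per input. Weights are drawn uniformly from `w_range` and delays from
#' `delay_range` (ms) unless given explicitly. Links are ordered by
#' increasing delay and assigned to terminals in consecutive blocks of
#' `n_inputs / K`, with the maximal-delay link wrapped onto the first
#' terminal ("closing a loop"), so every terminal receives exactly
#' `n_inputs / K` links. Terminal weights start at `J = 1`.
#'
#' @param n_inputs Total number of input units `N`; must be divisible by `K`.
#' @param K Number of terminals (default 3).
#' @param w_range Uniform support of the link weights (default `c(0.1, 1.1)`).
#' @param delay_range Uniform support of the delays in ms (default
#'   `c(1, 150)`).
#' @param weights,delays Optional explicit vectors of length `n_inputs`
#'   (used e.g. to re-draw weights while keeping a fixed delay set).
#' @param seed Optional seed; the caller's RNG state is restored.
#' @return An `an_network` object.
#' @examples
#' net <- build_feedforward(15, K = 3, seed = 1)
#' table(net$edges$terminal)   # 5 links per terminal
#' @export
build_feedforward <- function(n_inputs, K = 3, w_range = c(0.1, 1.1),
                              delay_range = c(1, 150), weights = NULL,
                              delays = NULL, seed = NULL) {
  if (n_inputs %% K != 0)
    stop("n_inputs must be divisible by K")
  with_seed(seed, {
    if (is.null(weights)) weights <- runif(n_inputs, w_range[1], w_range[2])
    if (is.null(delays))  delays  <- runif(n_inputs, delay_range[1], delay_range[2])
  })
  stopifnot(length(weights) == n_inputs, length(delays) == n_inputs)
  edges <- data.frame(src_kind = "input", src = seq_len(n_inputs), node = 1L,
                      terminal = assign_terminals(delays, K),
                      W = weights, delay_ms = delays)
  new_network("feedforward", "adaptive_node", 1L, K, n_inputs, edges)
}

sample_recurrent_edges <- function(targets, source_pool, in_degree, K,
                                   w_range, delay_mean, delay_sd,
                                   exclude_self = FALSE) {
  per_term <- in_degree / K
  stopifnot(per_term == round(per_term))
  out <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    nd <- targets[i]
    pool <- if (exclude_self) setdiff(source_pool, nd) else source_pool
    if (in_degree > length(pool))
      stop("in_degree exceeds the available source pool")
    src <- sample(pool, in_degree)
    delay <- pmax(0.1, rnorm(in_degree, delay_mean, delay_sd))
    term <- if (K == 1) rep(1L, in_degree) else {
      # consecutive delay-sorted blocks, mirroring the feedforward ordering
      t <- integer(in_degree)
      t[order(delay)] <- rep(seq_len(K), each = per_term)
      t
    }
    out[[i]] <- data.frame(src_kind = "node", src = src, node = nd,
                           terminal = term,
                           W = runif(in_degree, w_range[1], w_range[2]),
                           delay_ms = delay)
  }
  do.call(rbind, out)
}

#' Build a two-pool recurrent network
#'
#' Two pools of `n_nodes / 2` nodes; every node receives `in_degree` inputs
#' from nodes sampled without replacement from the *other* pool. Weights are
#' uniform on `w_range` and delays normal with mean `delay_mean` and sd
#' `delay_sd` ms (truncated at 0.1 ms). In `"adaptive_node"` mode each node
#' has `K` terminals with adaptive multipliers `J`; in `"adaptive_link"`
#' mode the node is a single terminal with fixed `J = 1` and the individual
#' link weights adapt instead.
#'
#' @param n_nodes Total node count (even; default 1000).
#' @param K Terminals per node in adaptive-node mode (default 3).
#' @param in_degree Inputs per node; `in_degree / K` per terminal. The
#'   default gives 60 inputs per terminal (180 per node at K = 3, 60 per
#'   node in the single-terminal adaptive-link baseline); the per-terminal
#'   stimulation rate this produces is what sustains the saturated
#'   asynchronous state with a stationary log-normal weight distribution.
#' @param mode `"adaptive_node"` or `"adaptive_link"`.
#' @param w_range,delay_mean,delay_sd Weight and delay distributions.
#' @param seed Optional seed.
#' @return An `an_network` object.
#' @export
build_two_pool <- function(n_nodes = 1000, K = 3, in_degree = NULL,
                           mode = c("adaptive_node", "adaptive_link"),
                           w_range = c(0.1, 0.2), delay_mean = 100,
                           delay_sd = 2, seed = NULL) {
  mode <- match.arg(mode)
  if (n_nodes %% 2 != 0) stop("n_nodes must be even")
  if (mode == "adaptive_link") K <- 1L
  if (is.null(in_degree)) in_degree <- 60L * K
  half <- n_nodes / 2
  pool_a <- seq_len(half); pool_b <- half + seq_len(half)
  edges <- with_seed(seed, rbind(
    sample_recurrent_edges(pool_a, pool_b, in_degree, K, w_range,
                           delay_mean, delay_sd),
    sample_recurrent_edges(pool_b, pool_a, in_degree, K, w_range,
                           delay_mean, delay_sd)))
  new_network("two_pool", mode, as.integer(n_nodes), K, 0L, edges)
}

#' Build a random recurrent network
#'
#' Every node receives `in_degree` inputs from nodes sampled uniformly
#' without replacement (self-loops excluded), `in_degree / K` per terminal;
#' same weight/delay distributions as [build_two_pool()].
#'
#' @inheritParams build_two_pool
#' @return An `an_network` object.
#' @export
build_random_recurrent <- function(n_nodes = 1000, K = 3, in_degree = NULL,
                                   w_range = c(0.1, 0.2), delay_mean = 100,
                                   delay_sd = 2, seed = NULL) {
  if (is.null(in_degree)) in_degree <- 60L * K
  edges <- with_seed(seed,
    sample_recurrent_edges(seq_len(n_nodes), seq_len(n_nodes), in_degree, K,
                           w_range, delay_mean, delay_sd,
                           exclude_self = TRUE))
  new_network("random_recurrent", "adaptive_node", as.integer(n_nodes), K,
              0L, edges)
}

#' Generate a stimulation protocol
#'
#' @param kind `"periodic_simultaneous"`: all input units fire together at
#'   `rate_hz` (the feedforward protocol, e.g. 5 Hz);
#'   `"poisson_per_input"`: independent Poisson trains at `rate_hz` per
#'   input (the random-input protocol, e.g. 30 Hz);
#'   `"initial_trigger_plus_background"`: a random fraction of the nodes is
#'   stimulated above threshold at t = 0, plus independent Poisson
#'   above-threshold background per node (the recurrent protocol).
#' @param duration_s Protocol duration in seconds.
#' @param n_inputs Number of input units (input-driven kinds).
#' @param rate_hz Stimulation rate per input in Hz.
#' @param n_nodes Number of nodes (trigger kind).
#' @param trigger_fraction Fraction of nodes triggered at t = 0 (default
#'   0.4).
#' @param bg_rate_hz Background above-threshold stimulation rate per node in
#'   Hz (default 0.01).
#' @param trigger_pool Optional subset of nodes eligible for the initial
#'   trigger (e.g. one pool of a two-pool network).
#' @param seed Optional seed.
#' @return An `an_stimulus` object: a list with `input_spikes` (a list of
#'   spike-time vectors in ms, one per input unit) and `triggers` (data
#'   frame `time_ms`, `node`).
#' @export
make_stimulus <- function(kind = c("periodic_simultaneous",
                                   "poisson_per_input",
                                   "initial_trigger_plus_background"),
                          duration_s, n_inputs = 0, rate_hz = 0,
                          n_nodes = 0, trigger_fraction = 0.4,
                          bg_rate_hz = 0.01, trigger_pool = NULL,
                          seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(rate_hz >= 0, duration_s >= 0)
  dur_ms <- duration_s * 1000
  input_spikes <- rep(list(numeric(0)), n_inputs)
  triggers <- data.frame(time_ms = numeric(0), node = integer(0))
  with_seed(seed, {
    if (kind == "periodic_simultaneous" && rate_hz > 0 && n_inputs > 0) {
      times <- seq(0, dur_ms, by = 1000 / rate_hz)
      input_spikes <- rep(list(times), n_inputs)
    } else if (kind == "poisson_per_input" && rate_hz > 0 && n_inputs > 0) {
      input_spikes <- lapply(seq_len(n_inputs), function(i) {
        n_exp <- ceiling(rate_hz * duration_s + 6 * sqrt(rate_hz * duration_s)) + 10
        t <- cumsum(rexp(n_exp, rate_hz)) * 1000
        while (length(t) && t[length(t)] < dur_ms) {
          t <- c(t, t[length(t)] + cumsum(rexp(n_exp, rate_hz)) * 1000)
        }
        t[t <= dur_ms]
      })
    } else if (kind == "initial_trigger_plus_background") {
      pool <- if (is.null(trigger_pool)) seq_len(n_nodes) else trigger_pool
      n_trig <- round(trigger_fraction * length(pool))
      trig <- sample(pool, n_trig)
      bg_n <- if (bg_rate_hz > 0)
        rpois(n_nodes, bg_rate_hz * duration_s) else integer(n_nodes)
      bg <- data.frame(
        time_ms = runif(sum(bg_n), 0, dur_ms),
        node = rep(seq_len(n_nodes), bg_n))
      triggers <- rbind(data.frame(time_ms = 0, node = trig), bg)
      triggers <- triggers[order(triggers$time_ms), , drop = FALSE]
    }
  })
  structure(list(kind = kind, duration_s = duration_s,
                 input_spikes = input_spikes, triggers = triggers),
            class = "an_stimulus")
}

#' Write a network's edge list as CSV
#'
#' Flat serialization with columns `src_kind`, `src`, `node`, `terminal`,
#' `W`, `delay_ms`.
#'
#' @param network An `an_network`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  write.csv(network$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
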
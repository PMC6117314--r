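#' Run the random-input single-node experiment
#'
#' One adaptive node (`K` terminals, `inputs_per_terminal` links each, link
#' weights uniform on `[0.1, 0.2]`, `J` starting at 1) driven by independent
#' Poisson input trains at `rate_hz` per input, with response failures
#' (`f_c`), a node-wide refractory period and the pair-based adaptation rule
#' (amplitude `A`, additive noise). This is the minimal system in which the
#' stationary log-normal distribution of effective weights `W * J`, the
#' strong-before-weak spike ordering, and the restoring force all emerge.
#'
#' Input delays are drawn uniformly from `[1, 150]` ms; under independent
#' Poisson drive a fixed delay only shifts a train, so this choice does not
#' affect the statistics.
#'
#' @param K Terminals (default 2).
#' @param inputs_per_terminal Links per terminal (default 60).
#' @param rate_hz Poisson rate per input in Hz (default 30, i.e. `K * f_c`).
#' @param duration_s,transient_s Total simulated time and the transient
#'   excluded from all measurements (defaults 2500 and 200 s).
#' @param A Adaptation amplitude (default 0.1).
#' @param noise Additive adaptation noise half-width (default 0.5e-3).
#' @param f_c,refractory_ms,dt_ms Spike-generation parameters (defaults 15
#'   Hz, 2 ms, 0.1 ms).
#' @param sample_every_s Sampling interval of the per-link effective weights
#'   (default 1 s).
#' @param adapt_log_stride Keep every n-th adaptation event (default 2; the
#'   subsampling is unbiased for the force estimate and bounds memory).
#' @param seed Optional seed.
#' @return The `an_sim` object, with `transient_s` attached.
#' @export
simulate_random_input_node <- function(K = 2, inputs_per_terminal = 60,
                                       rate_hz = 30, duration_s = 2500,
                                       transient_s = 200, A = 0.1,
                                       noise = 0.5e-3, f_c = 15,
                                       refractory_ms = 2, dt_ms = 0.1,
                                       sample_every_s = 1,
                                       adapt_log_stride = 2, seed = NULL) {
  n <- K * inputs_per_terminal
  with_seed(seed, {
    net <- build_feedforward(n, K, w_range = c(0.1, 0.2),
                             delay_range = c(1, 150))
    stim <- make_stimulus("poisson_per_input", duration_s = duration_s,
                          n_inputs = n, rate_hz = rate_hz)
    sim <- simulate_network(
      net, stim, duration_s,
      params = lif_params(f_c = f_c, refractory_ms = refractory_ms,
                          dt_ms = dt_ms),
      rule = adaptation_rule(A = A, noise = noise),
      record = list(sample_weights_every_ms = sample_every_s * 1000,
                    sample_weights_from_ms = transient_s * 1000,
                    log_events = "spikes",
                    log_from_ms = transient_s * 1000,
                    adapt_log_stride = adapt_log_stride,
                    adapt_log_from_ms = transient_s * 1000,
                    count_from_ms = transient_s * 1000))
  })
  sim$transient_s <- transient_s
  sim
}

# Evenly thin a vector to at most max_points values.
thin_values <- function(x, max_points) {
  if (length(x) <= max_points) return(x)
  x[round(seq(1, length(x), length.out = max_points))]
}

#' Distribution of effective link weights
#'
#' Bins the effective weights `W * J` into `n_bins` equal bins on the log10
#' axis, fits a log-normal by maximum likelihood (mean and sd of the logs),
#' and reports a Lilliefors/Kolmogorov-Smirnov statistic for normality of
#' the logs. Because consecutive samples of the same link are strongly
#' autocorrelated, the goodness-of-fit test is run on an evenly thinned
#' subsample of at most `max_test_points` values.
#'
#' @param values Positive effective weights (pooled per-link samples).
#' @param n_bins Histogram bins on the log scale (default 100).
#' @param max_test_points Cap on the sample size entering the test (default
#'   500).
#' @return A list of class `weight_distribution`: `histogram` (data frame
#'   `log10_mid`, `count`, `density`), `meanlog`, `sdlog`, `mode` (on the
#'   natural scale), `ks_stat`, `ks_p`, `n`.
#' @export
effective_weight_distribution <- function(values, n_bins = 100,
                                          max_test_points = 500) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no effective-weight values supplied")
  if (any(values <= 0)) stop("effective weights must be positive")
  lv <- log(values)
  l10 <- log10(values)
  br <- seq(min(l10), max(l10), length.out = n_bins + 1)
  if (br[1] == br[n_bins + 1]) br <- br[1] + c(-0.5, 0.5) / n_bins * seq(0, n_bins)
  h <- hist(l10, breaks = br, plot = FALSE)
  meanlog <- mean(lv)
  sdlog <- sd(lv)
  test_vals <- thin_values(lv, max_test_points)
  ks <- if (length(unique(test_vals)) > 4 && sdlog > 0) {
    if (requireNamespace("nortest", quietly = TRUE)) {
      t <- nortest::lillie.test(test_vals)
      list(stat = unname(t$statistic), p = t$p.value)
    } else {
      t <- suppressWarnings(ks.test(test_vals, "pnorm", meanlog, sdlog))
      list(stat = unname(t$statistic), p = t$p.value)
    }
  } else list(stat = NA_real_, p = 0)
  structure(list(
    histogram = data.frame(log10_mid = h$mids, count = h$counts,
                           density = h$density),
    meanlog = meanlog, sdlog = sdlog,
    mode = 10^h$mids[which.max(h$counts)],
    ks_stat = ks$stat, ks_p = ks$p, n = length(values)),
    class = "weight_distribution")
}

#' @export
print.weight_distribution <- function(x, ...) {
  cat("Effective-weight distribution (n =", x$n, "): meanlog =",
      signif(x$meanlog, 4), ", sdlog =", signif(x$sdlog, 4),
      "\n  log-normal KS stat =", signif(x$ks_stat, 3),
      ", p =", signif(x$ks_p, 3), "\n")
  invisible(x)
}

#' Max/min ratio of each effective weight over a trailing window
#'
#' Measures how mobile individual effective weights are: the ratio of the
#' maximal to the minimal `W * J` of each link over the final `window_s`
#' seconds. Frozen weights give ratios of 1; vanished weights give infinite
#' ratios, which are capped at `cap` (the adaptive-link convention).
#'
#' @param sim An `an_sim` run with effective-weight sampling enabled.
#' @param window_s Trailing window in seconds (default 2).
#' @param cap Upper cap on the ratios (default 60).
#' @return Numeric vector of per-link ratios.
#' @export
max_min_ratio <- function(sim, window_s = 2, cap = 60) {
  if (!nrow(sim$wj_samples)) stop("no effective-weight samples recorded")
  keep <- sim$wj_times_s >= max(sim$wj_times_s) - window_s + 1e-9
  if (!any(keep)) stop("sampling grid does not cover the requested window")
  w <- sim$wj_samples[keep, , drop = FALSE]
  lo <- apply(w, 2, min)
  hi <- apply(w, 2, max)
  r <- ifelse(lo <= 0, Inf, hi / lo)
  pmin(r, cap)
}

#' Percentile classification of weak and strong effective weights
#'
#' Weak weights occupy the `[1%, 25%]` percentile band and strong weights
#' the `[75%, 99%]` band, so that 50% of the distribution lies between the
#' maximum of the weak and the minimum of the strong weights, 1% extreme
#' tails are excluded on each side, and each class holds 24% of the
#' distribution.
#'
#' @param values Effective weights (at least 100 values).
#' @return A list of class `strong_weak`: `weak_range`, `strong_range`
#'   (numeric length-2), `weak_frac`, `strong_frac` (realised fractions) and
#'   `n`.
#' @export
classify_strong_weak <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 100)
    stop("at least 100 values are required for stable percentile bands")
  q <- quantile(values, c(0.01, 0.25, 0.75, 0.99), names = FALSE)
  in_band <- function(lo, hi) mean(values >= lo & values <= hi)
  structure(list(weak_range = q[1:2], strong_range = q[3:4],
                 weak_frac = in_band(q[1], q[2]),
                 strong_frac = in_band(q[3], q[4]),
                 n = length(values)),
            class = "strong_weak")
}

#' Spontaneous temporal ordering of strong/weak spike pairs
#'
#' Scans consecutive spikes of the same node: a qualifying pair consists of
#' two spikes from distinct terminals separated by at most `window_ms`.
#' Each spike's terminal is classified strong or weak by its effective
#' weight at spike time (the terminal's `J` times its mean link weight)
#' against the percentile bands of `classification`; pairs whose terminals
#' are not one strong and one weak are left unclassified. `P_SW` is the
#' fraction of qualifying pairs with the strong spike first, `P_WS` the
#' reverse. With a 2 ms refractory period the dynamics spontaneously favour
#' strong-before-weak: `P_SW > P_WS`.
#'
#' @param sim An `an_sim` (or a spike data frame with columns `time_ms`,
#'   `node_id`, `terminal_id`, `effective_weight`).
#' @param classification A `strong_weak` object from
#'   [classify_strong_weak()].
#' @param window_ms Pair window in ms (default 5).
#' @param shuffle Randomly swap the within-pair order (label-shuffle null:
#'   `P_SW` and `P_WS` become exchangeable).
#' @return A list of class `pair_ordering`: `P_SW`, `P_WS`, `ratio`,
#'   `n_SW`, `n_WS`, `n_pairs` (all qualifying pairs), `z` (binomial
#'   z-score of the SW excess) and `undefined` (`TRUE` when no pair could
#'   be classified).
#' @export
spike_pair_ordering <- function(sim, classification, window_ms = 5,
                                shuffle = FALSE) {
  sp <- if (inherits(sim, "an_sim")) spikes(sim) else sim
  sp <- sp[order(sp$node_id, sp$time_ms), , drop = FALSE]
  n <- nrow(sp)
  empty <- structure(list(P_SW = NA_real_, P_WS = NA_real_,
                          ratio = NA_real_, n_SW = 0L, n_WS = 0L,
                          n_pairs = 0L, z = NA_real_, undefined = TRUE),
                     class = "pair_ordering")
  if (n < 2) return(empty)
  first <- seq_len(n - 1)
  ok <- sp$node_id[first] == sp$node_id[first + 1] &
    sp$terminal_id[first] != sp$terminal_id[first + 1] &
    (sp$time_ms[first + 1] - sp$time_ms[first]) <= window_ms
  first <- first[ok]
  if (!length(first)) return(empty)
  cls <- function(w) {
    out <- rep(NA_character_, length(w))
    out[w >= classification$weak_range[1] &
        w <= classification$weak_range[2]] <- "W"
    out[w >= classification$strong_range[1] &
        w <= classification$strong_range[2]] <- "S"
    out
  }
  a <- cls(sp$effective_weight[first])
  b <- cls(sp$effective_weight[first + 1])
  if (shuffle) {
    swap <- runif(length(first)) < 0.5
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  n_pairs <- length(first)
  n_sw <- sum(a == "S" & b == "W", na.rm = TRUE)
  n_ws <- sum(a == "W" & b == "S", na.rm = TRUE)
  if (n_sw + n_ws == 0) return(empty)
  z <- (n_sw - n_ws) / sqrt(n_sw + n_ws)
  structure(list(P_SW = n_sw / n_pairs, P_WS = n_ws / n_pairs,
                 ratio = if (n_ws > 0) n_sw / n_ws else Inf,
                 n_SW = n_sw, n_WS = n_ws, n_pairs = n_pairs, z = z,
                 undefined = FALSE),
            class = "pair_ordering")
}

#' @export
print.pair_ordering <- function(x, ...) {
  if (x$undefined) {
    cat("Pair ordering: undefined (no classifiable pairs)\n")
  } else {
    cat("Pair ordering over", x$n_pairs, "pairs: P_SW =",
        signif(x$P_SW, 4), ", P_WS =", signif(x$P_WS, 4),
        ", ratio =", signif(x$ratio, 4), ", z =", signif(x$z, 3), "\n")
  }
  invisible(x)
}

#' Restoring force on the terminal weights
#'
#' Bins logged adaptation events by the effective weight `W * J` of the
#' paired link at event time (bin width `bin`) and reports, per bin, the
#' mean relative change `(J+ - J) / <W*J>` with `<W*J>` the average bin
#' value, together with the per-bin standard deviation and count. In the
#' stationary state the force is positive below the distribution mode and
#' negative above it.
#'
#' @param adapt_log Adaptation-event data frame (`sim$adapt_log` of a run
#'   with `adapt_log_stride > 0`), columns `wj`, `J_before`, `J_after`.
#' @param bin Bin width on the `W * J` axis (default 0.05).
#' @return Data frame `wj_mid`, `n`, `force`, `sd` (empty bins absent),
#'   ordered by `wj_mid`.
#' @export
restoring_force <- function(adapt_log, bin = 0.05) {
  if (!nrow(adapt_log)) stop("adaptation log is empty")
  dj <- adapt_log$J_after - adapt_log$J_before
  idx <- floor(adapt_log$wj / bin)
  agg <- split(data.frame(dj = dj, wj = adapt_log$wj), idx)
  out <- do.call(rbind, lapply(agg, function(g) {
    m <- mean(g$wj)
    data.frame(wj_mid = m, n = nrow(g), force = mean(g$dj) / m,
               sd = if (nrow(g) > 1) sd(g$dj) / m else 0)
  }))
  out <- out[order(out$wj_mid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refractory-period sweep of the pair-ordering ratio
#'
#' Re-runs the random-input single-node experiment at each refractory
#' period and reports `P_SW / P_WS` together with diagnostics of the
#' effective-weight distribution (log-normal KS p-value, fraction of
#' effective weights above threshold, fraction of terminal weights at the
#' upper clamp). Below a critical refractory period the stationary
#' log-normal collapses: both strong and weak adaptation steps turn
#' positive and all effective weights are driven above threshold.
#'
#' @param rp_values_ms Refractory periods to test, in ms (each 0 or >=
#'   `dt_ms`).
#' @param duration_s,transient_s Per-run length and transient.
#' @param seed Base seed; run i uses `seed + i`.
#' @param ... Further arguments to [simulate_random_input_node()].
#' @return Data frame with one row per refractory period: `refractory_ms`,
#'   `P_SW`, `P_WS`, `ratio`, `z`, `ks_p`, `frac_above_threshold`,
#'   `frac_J_at_max`.
#' @export
refractory_sweep <- function(rp_values_ms, duration_s = 500,
                             transient_s = 100, seed = NULL, ...) {
  rows <- lapply(seq_along(rp_values_ms), function(i) {
    rp <- rp_values_ms[i]
    sim <- simulate_random_input_node(refractory_ms = rp,
                                      duration_s = duration_s,
                                      transient_s = transient_s,
                                      seed = if (is.null(seed)) NULL else seed + i,
                                      ...)
    wj <- as.vector(sim$wj_samples)
    dist <- effective_weight_distribution(wj)
    cl <- classify_strong_weak(wj)
    po <- spike_pair_ordering(sim, cl)
    late <- sim$wj_samples[nrow(sim$wj_samples), ]
    data.frame(refractory_ms = rp, P_SW = po$P_SW, P_WS = po$P_WS,
               ratio = po$ratio, z = po$z, ks_p = dist$ks_p,
               frac_above_threshold = mean(late >= 1),
               frac_J_at_max = mean(sim$J_final >=
                                      0.999 * sim$rule$j_bounds[2]))
  })
  do.call(rbind, rows)
}
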
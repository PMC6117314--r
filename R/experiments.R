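#' Element-wise product of terminal-weight magnitude spectra
#'
#' Removes the mean of each terminal-weight trace, takes the magnitude of
#' its discrete Fourier transform, and multiplies the spectra of the K
#' terminals on their common frequency grid. A frequency shared by all
#' terminals survives the product; incoherent fluctuations are suppressed.
#'
#' @param J Matrix of terminal-weight traces (rows = samples, columns =
#'   terminals), equally spaced in time.
#' @param dt_s Sampling interval in seconds.
#' @return Data frame with `freq_hz` and `power` (product of magnitude
#'   spectra), positive frequencies up to Nyquist.
#' @export
fourier_product <- function(J, dt_s) {
  J <- as.matrix(J)
  n <- nrow(J)
  if (n < 4) stop("traces too short for a spectrum")
  mags <- apply(J, 2, function(x) Mod(fft(x - mean(x))))
  prod_spec <- apply(mags, 1, prod)
  half <- seq(2, floor(n / 2) + 1)
  data.frame(freq_hz = (half - 1) / (n * dt_s), power = prod_spec[half])
}

#' Classify the stationary dynamics of terminal weights
#'
#' Three regimes are distinguished on a post-transient window of the
#' `J_i(t)` traces: `fixed` when every terminal's coefficient of variation
#' is below `eps_fix`; otherwise `fast_oscillation` versus
#' `slow_oscillation` by the dominant period of the Fourier-product
#' spectrum, with the slow class requiring both a dominant period of at
#' least `period_boundary_s` and a relative amplitude range above
#' `range_frac` of the maximal weight (slow oscillations swing between the
#' weight clamps with long plateaus; fast ones are small fluctuations about
#' a mean).
#'
#' @param J Matrix of terminal-weight traces (post-transient; rows =
#'   samples).
#' @param dt_s Sampling interval in seconds.
#' @param eps_fix Coefficient-of-variation threshold for `fixed` (1e-3).
#' @param period_boundary_s Fast/slow dominant-period boundary in seconds
#'   (2).
#' @param range_frac Per-terminal relative amplitude range
#'   `(max - min)/max` required for `slow_oscillation` (0.5).
#' @param negligible Terminals whose weight never exceeds this value over
#'   the window (default 1e-4, i.e. within two orders of magnitude of the
#'   lower clamp) are treated as practically vanished: their relative
#'   fluctuations at the clamp are meaningless and they are excluded from
#'   the variability, range and spectral measures.
#' @return A list of class `dynamics_class`: `label`, `dominant_period_s`
#'   (`NA` for fixed), `cv` (per terminal; `NA` for vanished terminals),
#'   `rel_range` (largest per-terminal relative range), and `indeterminate`
#'   (`TRUE` when the window is shorter than 4 dominant periods).
#' @export
classify_dynamics <- function(J, dt_s, eps_fix = 1e-3,
                              period_boundary_s = 2, range_frac = 0.5,
                              negligible = 1e-4) {
  J <- as.matrix(J)
  active <- apply(J, 2, max) > negligible
  cv <- rep(NA_real_, ncol(J))
  cv[active] <- apply(J[, active, drop = FALSE], 2, function(x) {
    m <- mean(x)
    if (m == 0) 0 else sd(x) / abs(m)
  })
  out <- list(cv = cv, dominant_period_s = NA_real_, rel_range = NA_real_,
              indeterminate = FALSE)
  osc <- active & !is.na(cv) & cv >= eps_fix
  if (!any(osc)) {
    out$label <- "fixed"
    class(out) <- "dynamics_class"
    return(out)
  }
  # constant terminals carry no signal: the product spectrum is taken over
  # the oscillating terminals only
  spec <- fourier_product(J[, osc, drop = FALSE], dt_s)
  f0 <- spec$freq_hz[which.max(spec$power)]
  period <- 1 / f0
  Josc <- J[, osc, drop = FALSE]
  rng_k <- apply(Josc, 2, function(x) (max(x) - min(x)) / max(x))
  # a slow oscillation must turn around within the window; a monotone
  # large-amplitude trend is an unresolved relaxation, not an oscillation
  turns <- apply(Josc, 2, function(x)
    abs(suppressWarnings(stats::cor(x, seq_along(x),
                                    method = "spearman"))) < 0.98)
  turns[is.na(turns)] <- FALSE
  out$dominant_period_s <- period
  out$rel_range <- max(rng_k)
  out$indeterminate <- nrow(J) * dt_s < 4 * period
  out$label <- if (period >= period_boundary_s &&
                   any(rng_k > range_frac & turns))
    "slow_oscillation" else "fast_oscillation"
  class(out) <- "dynamics_class"
  out
}

#' @export
print.dynamics_class <- function(x, ...) {
  cat("Dynamics:", x$label)
  if (!is.na(x$dominant_period_s))
    cat(" (dominant period", signif(x$dominant_period_s, 3), "s)")
  if (isTRUE(x$indeterminate)) cat(" [indeterminate: window < 4 periods]")
  cat("\n")
  invisible(x)
}

# One feedforward classification run with the standard protocol:
# simultaneous periodic stimulation, unbounded f_c, eta = 0, dt = 1 ms.
# Terminal weights are sampled stroboscopically, once per stimulation round,
# so that the stimulus-locked within-round ripple of J (present even at a
# fixed point of the round-to-round map) does not register as an
# oscillation; the classification then acts on the round map itself.
run_feedforward_dynamics <- function(net, duration_s = 600, window_s = 200,
                                     rate_hz = 5, record_every_ms = NULL,
                                     rule = adaptation_rule(),
                                     params = lif_params(f_c = Inf,
                                                         dt_ms = 1)) {
  if (is.null(record_every_ms)) record_every_ms <- 1000 / rate_hz
  stim <- make_stimulus("periodic_simultaneous", duration_s = duration_s,
                        n_inputs = net$n_inputs, rate_hz = rate_hz)
  sim <- simulate_network(net, stim, duration_s, params = params,
                          rule = rule,
                          record = list(record_J_every_ms = record_every_ms,
                                        log_events = "none",
                                        count_from_ms =
                                          (duration_s - window_s) * 1000))
  tr <- j_traces(sim)
  keep <- tr$time_s >= duration_s - window_s
  list(sim = sim,
       classification = classify_dynamics(tr$J[keep, , drop = FALSE],
                                          record_every_ms / 1000))
}

#' Fraction of oscillatory outcomes over random feedforward configurations
#'
#' Samples `n_samples` feedforward networks (fresh uniform weights and
#' delays per sample), runs each under simultaneous periodic stimulation
#' with unbounded `f_c` and no adaptation noise, classifies the terminal
#' weight dynamics with [classify_dynamics()], and returns the class
#' fractions with binomial standard errors.
#'
#' @param K Terminals (default 3).
#' @param n_inputs Total inputs `N` (divisible by `K`).
#' @param n_samples Number of random configurations.
#' @param seed Seed for the whole sweep.
#' @param duration_s,window_s Simulated time and classification window per
#'   sample (seconds). The default excludes a 400 s transient: the class
#'   fractions are insensitive to further lengthening, while shorter
#'   transients let unfinished relaxations register as slow oscillations.
#' @param rate_hz Stimulation rate (default 5).
#' @param rule Adaptation rule (default noiseless exponential, A = 0.05).
#' @return A list with `fractions` (named: fixed, fast_oscillation,
#'   slow_oscillation, oscillating), `se` (binomial standard errors),
#'   `labels` (per sample) and the arguments used.
#' @export
oscillation_fraction <- function(K = 3, n_inputs, n_samples, seed = NULL,
                                 duration_s = 600, window_s = 200,
                                 rate_hz = 5, rule = adaptation_rule()) {
  stopifnot(n_samples >= 1)
  labels <- with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      net <- build_feedforward(n_inputs, K)
      run_feedforward_dynamics(net, duration_s, window_s, rate_hz,
                               rule = rule)$classification$label
    }, character(1))
  })
  lv <- c("fixed", "fast_oscillation", "slow_oscillation")
  frac <- table(factor(labels, levels = lv)) / n_samples
  frac <- c(as.vector(frac), sum(frac[2:3]))
  names(frac) <- c(lv, "oscillating")
  se <- sqrt(frac * (1 - frac) / n_samples)
  list(fractions = frac, se = se, labels = labels, K = K,
       n_inputs = n_inputs, n_samples = n_samples)
}

#' Compare two attractor signatures
#'
#' Two runs (with identical delays and equal observation windows) share an
#' attractor when every link's firing count differs by less than `tol`
#' (relative to the larger count). Links whose firing counts fall below
#' `low_rate_floor` in either run are compared on their non-firing events
#' (arrivals that evoked no spike) instead, since relative differences are
#' meaningless near zero counts.
#'
#' @param sig_a,sig_b Signatures: lists with per-link `firing` and
#'   `arrivals` counts (as produced by [attractor_signature()]).
#' @param tol Relative tolerance (default 0.02).
#' @param low_rate_floor Minimal firing count for the direct comparison
#'   (default 10).
#' @return `TRUE` or `FALSE`.
#' @export
same_attractor <- function(sig_a, sig_b, tol = 0.02, low_rate_floor = 10) {
  stopifnot(length(sig_a$firing) == length(sig_b$firing))
  rel <- function(a, b) {
    m <- pmax(a, b)
    d <- abs(a - b)
    ifelse(m == 0, 0, d / m)
  }
  low <- sig_a$firing < low_rate_floor | sig_b$firing < low_rate_floor
  r <- rel(sig_a$firing, sig_b$firing)
  nf_a <- sig_a$arrivals - sig_a$firing
  nf_b <- sig_b$arrivals - sig_b$firing
  r[low] <- rel(nf_a, nf_b)[low]
  all(r < tol)
}

#' Attractor signature of a simulation
#'
#' Per-link firing counts (arrivals whose step coincided with a spike of the
#' link's terminal) and total arrivals over the counting window.
#'
#' @param sim An `an_sim`.
#' @return A list with `firing` and `arrivals` vectors (one entry per link).
#' @export
attractor_signature <- function(sim) {
  list(firing = sim$edge_firing, arrivals = sim$edge_arrivals)
}

# Greedy representative clustering: the first-seen signature anchors a
# cluster; each new signature joins the first matching representative.
cluster_signatures <- function(sigs, tol = 0.02, low_rate_floor = 10) {
  reps <- list()
  assignment <- integer(length(sigs))
  counts <- integer(0)
  for (i in seq_along(sigs)) {
    hit <- 0L
    for (r in seq_along(reps)) {
      if (same_attractor(sigs[[i]], reps[[r]], tol, low_rate_floor)) {
        hit <- r
        break
      }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- sigs[[i]]
      hit <- length(reps)
      counts <- c(counts, 0L)
    }
    counts[hit] <- counts[hit] + 1L
    assignment[i] <- hit
  }
  list(n_clusters = length(reps), assignment = assignment, sizes = counts)
}

#' Census of dynamical attractors in a feedforward network
#'
#' For each of `n_delay_sets` fixed delay sets, runs `n_ic` simulations with
#' freshly sampled random link weights, extracts per-link firing signatures
#' over the observation window, and clusters them greedily with
#' [same_attractor()]. Because clusters only accumulate, the count after the
#' first `m` initial conditions is non-decreasing in `m`; the running curve
#' is returned for each delay set.
#'
#' @param K,n_inputs Network shape (defaults 3 and 9: three inputs per
#'   terminal).
#' @param n_ic Random initial weight conditions per delay set.
#' @param n_delay_sets Independent fixed-delay samples (default 10).
#' @param seed Seed for the whole census.
#' @param duration_s,window_s Simulated time and counting window per run.
#' @param rate_hz Stimulation rate (default 5).
#' @param tol,low_rate_floor Passed to [same_attractor()].
#' @return A list with `mean_count`, `sd_count` (across delay sets, at
#'   `n_ic`), `curves` (matrix `n_ic` x `n_delay_sets` of running cluster
#'   counts) and the arguments.
#' @export
count_attractors <- function(K = 3, n_inputs = 9, n_ic, n_delay_sets = 10,
                             seed = NULL, duration_s = 300, window_s = 100,
                             rate_hz = 5, tol = 0.02, low_rate_floor = 10) {
  stopifnot(n_ic >= 1, n_delay_sets >= 1)
  curves <- matrix(0L, n_ic, n_delay_sets)
  with_seed(seed, {
    for (d in seq_len(n_delay_sets)) {
      delays <- runif(n_inputs, 1, 150)
      sigs <- vector("list", n_ic)
      for (i in seq_len(n_ic)) {
        net <- build_feedforward(n_inputs, K, delays = delays)
        r <- run_feedforward_dynamics(net, duration_s, window_s, rate_hz)
        sigs[[i]] <- attractor_signature(r$sim)
      }
      reps <- list()
      for (i in seq_len(n_ic)) {
        hit <- FALSE
        for (rp in reps) {
          if (same_attractor(sigs[[i]], rp, tol, low_rate_floor)) {
            hit <- TRUE
            break
          }
        }
        if (!hit) reps[[length(reps) + 1L]] <- sigs[[i]]
        curves[i, d] <- length(reps)
      }
    }
  })
  final <- curves[n_ic, ]
  list(mean_count = mean(final), sd_count = if (n_delay_sets > 1) sd(final) else 0,
       curves = curves, K = K, n_inputs = n_inputs, n_ic = n_ic,
       n_delay_sets = n_delay_sets)
}

#' Combinatorial lower bound on the number of attractors
#'
#' With `A_N0` attractors measured at `N0` active inputs per terminal, a
#' network with `N` inputs and `K` terminals admits at least
#' `A_N0 * choose(N/K, N0)^K` attractors: each terminal can activate any
#' `N0`-subset of its `N/K` links, and each choice inherits the measured
#' attractor multiplicity. For `K = 3`, `N0 = 3` the bound grows as `N^9`.
#'
#' @param A_N0 Attractor count at `N0` inputs per terminal.
#' @param N Total inputs.
#' @param K Terminals.
#' @param N0 Active inputs per terminal (`N0 <= N/K`).
#' @return The lower bound (numeric; can be astronomically large).
#' @examples
#' attractor_lower_bound(1500, N = 9, K = 3, N0 = 3)   # 1500
#' attractor_lower_bound(2, N = 6, K = 2, N0 = 1)      # 18
#' @export
attractor_lower_bound <- function(A_N0, N, K, N0) {
  if (N %% K != 0) stop("N must be divisible by K")
  if (N0 > N / K) stop("N0 must not exceed N/K")
  stopifnot(A_N0 >= 0, N0 >= 0)
  A_N0 * choose(N / K, N0)^K
}
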
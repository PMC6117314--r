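#' Signed adaptation profile
#'
#' Relative change `delta` as a function of the pair lag
#' `Delta = t_sub - t_spike` (ms). The exponential profile is
#' `A * exp(-|Delta|/tau) * sign(Delta)`; the two-level profile is a step of
#' height `A` sharing the exponential's extremes. Both are odd in `Delta`
#' and vanish beyond the cutoff.
#'
#' @param delta_ms Time lag(s) in ms (vectorised).
#' @param rule An [adaptation_rule()].
#' @return Relative change(s) `delta`, same length as `delta_ms`.
#' @examples
#' delta_profile(15)    # 0.05 * exp(-1)
#' delta_profile(-60)   # beyond the 50 ms cutoff: 0
#' @export
delta_profile <- function(delta_ms, rule = adaptation_rule()) {
  mag <- if (rule$profile == "exponential") {
    rule$A * exp(-abs(delta_ms) / rule$tau_ms)
  } else {
    rep(rule$A, length(delta_ms))
  }
  out <- mag * sign(delta_ms)
  out[abs(delta_ms) > rule$cutoff_ms] <- 0
  out
}

#' Apply one adaptation step to a terminal weight
#'
#' `J+ = clamp(J * (1 + delta) + eta)` with `eta` drawn uniformly from
#' `[-noise, noise]` (redrawn independently per event; 0 when noise is
#' disabled). The clamp keeps `J` inside `rule$j_bounds`.
#'
#' @param J Current terminal weight(s).
#' @param delta Relative change(s), typically from [delta_profile()].
#' @param rule An [adaptation_rule()].
#' @return Updated weight(s).
#' @examples
#' apply_adaptation(1, 0.05)    # 1.05
#' apply_adaptation(10, 0.05)   # clamped at the upper bound 10
#' @export
apply_adaptation <- function(J, delta, rule = adaptation_rule()) {
  eta <- if (rule$noise > 0) runif(length(J), -rule$noise, rule$noise) else 0
  pmin(rule$j_bounds[2], pmax(rule$j_bounds[1], J * (1 + delta) + eta))
}

#' Enumerate adaptation pairs from an event log
#'
#' Reference implementation of the pairing rule: every sub-threshold
#' stimulation via terminal i pairs with every evoked spike from a
#' *different* terminal of the same node when `|t_sub - t_spike|` is within
#' the cutoff. Each pair adapts `J_i` with lag `Delta = t_sub - t_spike`,
#' and takes effect at the later of the two event times (post-spike
#' stimulations adapt at stimulation time, pre-spike stimulations at spike
#' time). The compiled engine performs the same pairing online; this
#' function exists for inspection and testing on small logs.
#'
#' @param log Event-log data frame (columns `time_ms`, `node_id`,
#'   `terminal_id`, `event_kind`) containing `spike` and
#'   `subthreshold_stimulation` records.
#' @param rule An [adaptation_rule()].
#' @param same_terminal_pairs Pair stimulations with spikes of the same
#'   terminal too (`TRUE` only for the adaptive-link baseline, where pairing
#'   is per link against all node spikes).
#' @return Data frame of adaptation events: `time_ms` (when the step takes
#'   effect), `node_id`, `terminal_id` (adapted terminal), `delta_ms` (lag)
#'   and `delta` (relative change), ordered by `time_ms`.
#' @export
collect_adaptation_pairs <- function(log, rule = adaptation_rule(),
                                     same_terminal_pairs = FALSE) {
  spikes <- log[log$event_kind == "spike", , drop = FALSE]
  stims  <- log[log$event_kind == "subthreshold_stimulation", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(stims))) {
    s <- stims[i, ]
    cand <- spikes[spikes$node_id == s$node_id, , drop = FALSE]
    if (!same_terminal_pairs)
      cand <- cand[cand$terminal_id != s$terminal_id, , drop = FALSE]
    lag <- s$time_ms - cand$time_ms
    keep <- abs(lag) <= rule$cutoff_ms & lag != 0
    if (!any(keep)) next
    lag <- lag[keep]
    out[[length(out) + 1L]] <- data.frame(
      time_ms = pmax(s$time_ms, cand$time_ms[keep]),
      node_id = s$node_id, terminal_id = s$terminal_id,
      delta_ms = lag, delta = delta_profile(lag, rule))
  }
  if (!length(out)) {
    return(data.frame(time_ms = numeric(), node_id = integer(),
                      terminal_id = integer(), delta_ms = numeric(),
                      delta = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$time_ms, res$terminal_id, res$delta_ms), , drop = FALSE]
}

#' Adaptive-link baseline update
#'
#' The classical counterpart of the nodal rule: the same relative change is
#' applied to an individual link weight, `W+ = W * (1 + delta) + eta`,
#' clamped below at 0 (link weights may vanish; the `[1e-6, 10]` clamp
#' applies only to terminal weights).
#'
#' @param W Current link weight(s).
#' @param delta Relative change(s).
#' @param rule An [adaptation_rule()] (supplies the noise amplitude).
#' @return Updated link weight(s).
#' @export
adaptive_link_update <- function(W, delta, rule = adaptation_rule()) {
  eta <- if (rule$noise > 0) runif(length(W), -rule$noise, rule$noise) else 0
  pmax(0, W * (1 + delta) + eta)
}
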
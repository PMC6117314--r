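#' Simulate an adaptive-node network
#'
#' Runs the compiled fixed-step engine: per step, all terminal voltages decay
#' by the exact factor `exp(-dt/T)`, the pulses binned to that step are
#' delivered (`V <- V + J * W`), threshold crossings are resolved (highest
#' voltage first, ties to the lowest terminal index) with response failures
#' per [spike_probability()], the node-wide refractory bookkeeping is
#' enforced, and unconsumed arrivals become sub-threshold stimulation events
#' that drive the pair-based adaptation of [adaptation_rule()]. Spikes
#' emitted by nodes schedule future pulses on their outgoing links after the
#' link delays.
#'
#' @param network An `an_network` from [build_feedforward()],
#'   [build_two_pool()] or [build_random_recurrent()].
#' @param stimulus An `an_stimulus` from [make_stimulus()] (or `NULL` for
#'   none).
#' @param duration_s Simulated time in seconds.
#' @param params A [lif_params()].
#' @param rule An [adaptation_rule()]; use `A = 0, noise = 0` to freeze all
#'   weights.
#' @param record A list overriding recording defaults:
#'   `record_J_every_ms` (0 = off) and `record_nodes` (terminal-weight
#'   traces), `sample_weights_every_ms` / `sample_weights_from_ms` (per-link
#'   effective weights `W * J`), `log_events` (`"none"`, `"spikes"`,
#'   `"failures"`, `"all"`) and `log_from_ms`, `adapt_log_stride` (0 = off;
#'   n = keep every n-th adaptation event) and `adapt_log_from_ms`,
#'   `count_from_ms` (start of the per-link / per-node counting window).
#' @param seed Optional seed applied for the whole run (engine randomness:
#'   response failures and adaptation noise).
#' @return An object of class `an_sim`: a list with
#'   `events` (data frame `time_ms`, `node_id`, `terminal_id`, `event_kind`,
#'   `effective_weight`), `adapt_log`, `J_traces` (+ `J_times_s`,
#'   `trace_nodes`), `wj_samples` (+ `wj_times_s`), `J_final`, `V_final`,
#'   `W_final`, per-link counters `edge_arrivals` / `edge_firing`, spike
#'   counters and rates over the counting window, and the run configuration.
#' @examples
#' net <- build_feedforward(15, K = 3, seed = 1)
#' stim <- make_stimulus("periodic_simultaneous", duration_s = 5,
#'                       n_inputs = 15, rate_hz = 5)
#' sim <- simulate_network(net, stim, duration_s = 5,
#'                         params = lif_params(f_c = Inf, dt_ms = 1),
#'                         record = list(record_J_every_ms = 100))
#' sim$n_spikes
#' @export
simulate_network <- function(network, stimulus = NULL, duration_s,
                             params = lif_params(),
                             rule = adaptation_rule(),
                             record = list(), seed = NULL) {
  stopifnot(inherits(network, "an_network"), duration_s > 0)
  if (is.null(stimulus)) {
    stimulus <- list(input_spikes = rep(list(numeric(0)), network$n_inputs),
                     triggers = data.frame(time_ms = numeric(0),
                                           node = integer(0)))
  }
  if (length(stimulus$input_spikes) != network$n_inputs)
    stop("stimulus has ", length(stimulus$input_spikes),
         " input trains but the network has ", network$n_inputs,
         " input units")
  if (params$refractory_ms > 0 && params$refractory_ms < params$dt_ms)
    stop("refractory_ms must be 0 or >= dt_ms")

  rec <- list(record_J_every_ms = 0, record_nodes = NULL,
              sample_weights_every_ms = 0, sample_weights_from_ms = 0,
              log_events = "spikes", log_from_ms = 0,
              adapt_log_stride = 0, adapt_log_from_ms = 0,
              count_from_ms = 0)
  rec[names(record)] <- record
  if (is.null(rec$record_nodes)) rec$record_nodes <- 1L
  log_level <- match(match.arg(rec$log_events,
                               c("none", "spikes", "failures", "all")),
                     c("none", "spikes", "failures", "all")) - 1L

  # affine voltage rescaling: simulate on the scaled axis
  v_span <- params$v_threshold - params$v_rest
  edges <- network$edges
  net_cpp <- list(
    n_nodes = network$n_nodes, K = network$K,
    mode = if (network$mode == "adaptive_link") 1L else 0L,
    src_kind = as.integer(edges$src_kind == "node"),
    src = as.integer(edges$src) - 1L,
    node = as.integer(edges$node) - 1L,
    term = as.integer(edges$terminal) - 1L,
    W = edges$W / v_span, delay_ms = edges$delay_ms,
    J_init = network$J_init, n_inputs = network$n_inputs)
  stim_cpp <- list(input_spikes = stimulus$input_spikes,
                   trigger_times = as.numeric(stimulus$triggers$time_ms),
                   trigger_nodes = as.integer(stimulus$triggers$node) - 1L)
  par_cpp <- list(
    duration_ms = duration_s * 1000, dt = params$dt_ms, T_ms = params$T_ms,
    refractory_ms = params$refractory_ms,
    f_c = if (is.infinite(params$f_c)) -1 else params$f_c,
    A = rule$A, tau_adapt = rule$tau_ms, cutoff_ms = rule$cutoff_ms,
    profile = if (rule$profile == "exponential") 0L else 1L,
    noise_amp = rule$noise, j_min = rule$j_bounds[1],
    j_max = rule$j_bounds[2], w_min = 0, w_max = Inf)
  rec_cpp <- list(
    record_J_every_ms = rec$record_J_every_ms,
    record_nodes = as.integer(rec$record_nodes) - 1L,
    sample_weights_every_ms = rec$sample_weights_every_ms,
    sample_weights_from_ms = rec$sample_weights_from_ms,
    log_level = log_level, log_from_ms = rec$log_from_ms,
    adapt_log_stride = as.integer(rec$adapt_log_stride),
    adapt_log_from_ms = rec$adapt_log_from_ms,
    count_from_ms = rec$count_from_ms)

  raw <- with_seed(seed, run_network_cpp(net_cpp, stim_cpp, par_cpp, rec_cpp))

  kinds <- c("spike", "subthreshold_stimulation", "crossing_failure")
  events <- data.frame(time_ms = raw$events$time_ms,
                       node_id = raw$events$node + 1L,
                       terminal_id = raw$events$terminal + 1L,
                       event_kind = factor(kinds[raw$events$kind + 1L],
                                           levels = kinds),
                       effective_weight = raw$events$wj)
  adapt_log <- data.frame(time_ms = raw$adapt_log$time_ms,
                          node_id = raw$adapt_log$node + 1L,
                          terminal_id = raw$adapt_log$terminal + 1L,
                          link_id = raw$adapt_log$edge + 1L,
                          delta_ms = raw$adapt_log$delta_ms,
                          J_before = raw$adapt_log$j_before,
                          J_after = raw$adapt_log$j_after,
                          wj = raw$adapt_log$wj)
  # rescale recorded effective weights back to the caller's voltage units
  events$effective_weight <- events$effective_weight * v_span
  adapt_log$wj <- adapt_log$wj * v_span

  window_s <- duration_s - rec$count_from_ms / 1000
  structure(list(
    events = events, adapt_log = adapt_log,
    J_times_s = raw$J_times_ms / 1000, J_traces = raw$J_traces,
    trace_nodes = rec$record_nodes,
    wj_times_s = raw$wj_times_ms / 1000,
    wj_samples = raw$wj_samples * v_span,
    J_final = raw$J_final, V_final = raw$V_final,
    W_final = raw$W_final * v_span,
    edge_arrivals = raw$edge_arrivals, edge_firing = raw$edge_firing,
    node_spikes = raw$node_spikes, terminal_spikes = raw$terminal_spikes,
    node_rate_hz = raw$node_spikes / window_s,
    terminal_rate_hz = raw$terminal_spikes / window_s,
    n_failures = raw$n_failures, n_spikes = raw$n_spikes,
    count_window_s = window_s, duration_s = duration_s,
    K = network$K, n_nodes = network$n_nodes, mode = network$mode,
    params = params, rule = rule),
    class = "an_sim")
}

#' @export
print.an_sim <- function(x, ...) {
  cat("Simulation of", x$n_nodes, "node(s) for", x$duration_s, "s:",
      x$n_spikes, "spikes,", x$n_failures, "response failures\n")
  cat("Mean node rate over counting window:",
      signif(mean(x$node_rate_hz), 4), "Hz\n")
  invisible(x)
}

#' Extract spike records from a simulation
#'
#' @param sim An `an_sim` object.
#' @return The `spike` rows of the event log.
#' @export
spikes <- function(sim) {
  sim$events[sim$events$event_kind == "spike", , drop = FALSE]
}

#' Terminal-weight traces of a simulation
#'
#' @param sim An `an_sim` run with `record_J_every_ms > 0`.
#' @param node Which recorded node to extract (default the first).
#' @return A list with `time_s` and `J` (matrix, one column per terminal).
#' @export
j_traces <- function(sim, node = NULL) {
  if (!nrow(sim$J_traces)) stop("no terminal-weight traces were recorded")
  if (is.null(node)) node <- sim$trace_nodes[1]
  i <- match(node, sim$trace_nodes)
  if (is.na(i)) stop("node ", node, " was not recorded")
  cols <- (i - 1) * sim$K + seq_len(sim$K)
  list(time_s = sim$J_times_s, J = sim$J_traces[, cols, drop = FALSE])
}

#' Event log of a simulation in serializable form
#'
#' @param sim An `an_sim`.
#' @return The event data frame (see [write_spike_log()] for the format).
#' @export
event_log <- function(sim) sim$events
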
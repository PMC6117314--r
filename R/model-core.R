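#' State of a single dendritic terminal
#'
#' A small container used by the scalar reference operations (the compiled
#' engine keeps its own flat state). Voltages are on the scaled axis
#' (rest 0, threshold 1).
#'
#' @param voltage Current scaled membrane voltage.
#' @param J Terminal weight multiplier (initially 1).
#' @param time_of_last_crossing Time (ms) of the last threshold crossing,
#'   successful or failed; `-Inf` until the first crossing so that the first
#'   one always yields a spike.
#' @param time_of_last_spike Time (ms) of the last emitted spike.
#' @param previous_voltage Voltage immediately before the current step's
#'   pulses, used for the response-failure rollback.
#' @return An object of class `terminal_state`.
#' @export
terminal_state <- function(voltage = 0, J = 1,
                           time_of_last_crossing = -Inf,
                           time_of_last_spike = -Inf,
                           previous_voltage = voltage) {
  structure(list(voltage = voltage, J = J,
                 time_of_last_crossing = time_of_last_crossing,
                 time_of_last_spike = time_of_last_spike,
                 previous_voltage = previous_voltage),
            class = "terminal_state")
}

#' Exact leak of the membrane voltage
#'
#' Decays a voltage toward rest over an interval using the closed-form
#' solution `V_rest + (V - V_rest) * exp(-dt/T)` of the leaky
#' integrate-and-fire equation; this is the same factor the engine applies
#' per step, so the leak carries no step-size bias.
#'
#' @param V Voltage (scaled; rest = 0) or vector of voltages.
#' @param dt_ms Elapsed time in ms, must be non-negative.
#' @param params A [lif_params()] object.
#' @return Decayed voltage(s).
#' @examples
#' decay_voltage(1, 20)          # one time constant: exp(-1)
#' @export
decay_voltage <- function(V, dt_ms, params = lif_params()) {
  if (any(dt_ms < 0)) stop("dt_ms must be non-negative")
  V * exp(-dt_ms / params$T_ms)
}

#' Deliver an instantaneous input pulse to a terminal
#'
#' Adds `J * W` to the voltage (delta-function input, delays already applied
#' by the scheduler) after recording the pre-pulse voltage for a possible
#' response-failure rollback.
#'
#' @param state A [terminal_state()].
#' @param W Link weight of the arriving pulse.
#' @return The updated `terminal_state`.
#' @export
deliver_pulse <- function(state, W) {
  state$previous_voltage <- state$voltage
  state$voltage <- state$voltage + state$J * W
  state
}

#' Spike probability of a threshold crossing
#'
#' A crossing at time `t` emits a spike with probability
#' `min(1, dt_cross * f_c)` where `dt_cross` is the time since the
#' terminal's last crossing (ms, converted to seconds against `f_c` in Hz).
#' This caps a terminal's stationary firing rate at `f_c`.
#'
#' @param dt_cross_ms Time since the last crossing in ms.
#' @param params A [lif_params()].
#' @return Probability in `[0, 1]`.
#' @export
spike_probability <- function(dt_cross_ms, params = lif_params()) {
  if (is.infinite(params$f_c)) return(rep(1, length(dt_cross_ms)))
  pmin(1, pmax(0, dt_cross_ms * params$f_c / 1000))
}

#' Resolve one threshold crossing of a terminal
#'
#' Scalar reference implementation of the crossing outcome: with probability
#' [spike_probability()] the terminal spikes (voltage reset to rest), else a
#' response failure occurs and the voltage is set back to its pre-pulse
#' value. Either way the crossing clock is restarted at `t`.
#'
#' @param state A [terminal_state()] with `voltage >= 1`.
#' @param t_ms Current time in ms.
#' @param params A [lif_params()].
#' @return List with `state` (updated) and `outcome` (`"spike"` or
#'   `"failure"`).
#' @export
attempt_spike <- function(state, t_ms, params = lif_params()) {
  if (state$voltage < 1) stop("attempt_spike() called below threshold")
  p <- spike_probability(t_ms - state$time_of_last_crossing, params)
  state$time_of_last_crossing <- t_ms
  if (p >= 1 || runif(1) < p) {
    state$voltage <- 0
    state$time_of_last_spike <- t_ms
    list(state = state, outcome = "spike")
  } else {
    state$voltage <- state$previous_voltage
    list(state = state, outcome = "failure")
  }
}

#' Write or read a spike/event log as CSV
#'
#' The event log of [simulate_network()] is a data frame with columns
#' `time_ms`, `node_id`, `terminal_id`, `event_kind`
#' (`spike`, `subthreshold_stimulation`, `crossing_failure`) and
#' `effective_weight` (`W * J` context at event time).
#'
#' @param log Event-log data frame.
#' @param path File path.
#' @return `write_spike_log()` returns `path` invisibly; `read_spike_log()`
#'   returns the data frame.
#' @export
write_spike_log <- function(log, path) {
  stopifnot(all(c("time_ms", "node_id", "terminal_id", "event_kind",
                  "effective_weight") %in% names(log)))
  write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_log
#' @export
read_spike_log <- function(path) {
  log <- read.csv(path, stringsAsFactors = FALSE)
  log$event_kind <- factor(log$event_kind,
                           levels = c("spike", "subthreshold_stimulation",
                                      "crossing_failure"))
  log
}
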
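#' Membrane and spike-generation parameters
#'
#' Bundles the leaky integrate-and-fire constants used by the simulation
#' engine. Voltages are handled internally on the scaled axis where the
#' resting potential is 0 and the threshold is 1; supplying an unscaled pair
#' (`v_rest`, `v_threshold`), e.g. -70 mV / -54 mV, makes [simulate_network()]
#' divide link weights by `v_threshold - v_rest`, which reproduces the scaled
#' run exactly (the model is invariant under affine voltage rescaling).
#'
#' @param T_ms Membrane time constant in ms (default 20).
#' @param refractory_ms Node-wide refractory period in ms (default 2). During
#'   this window the terminal that evoked the spike ignores incoming
#'   stimulations entirely; sibling terminals keep integrating but threshold
#'   checks are suspended until the window ends.
#' @param f_c Maximal stationary firing frequency of a terminal in Hz
#'   (default 15). A threshold crossing emits a spike with probability
#'   `min(1, dt_cross * f_c)`, `dt_cross` the time since the terminal's last
#'   crossing; use `Inf` to disable response failures.
#' @param dt_ms Integration step in ms: 1 for the feedforward experiments,
#'   0.1 for recurrent and random-input runs.
#' @param v_rest,v_threshold Optional unscaled resting/threshold potentials.
#' @return An object of class `lif_params`.
#' @examples
#' lif_params()                  # recurrent-network defaults
#' lif_params(f_c = Inf, dt_ms = 1)  # feedforward: failures excluded
#' @export
lif_params <- function(T_ms = 20, refractory_ms = 2, f_c = 15, dt_ms = 0.1,
                       v_rest = 0, v_threshold = 1) {
  stopifnot(T_ms > 0, refractory_ms >= 0, dt_ms > 0,
            is.infinite(f_c) || f_c > 0, v_threshold > v_rest)
  structure(list(T_ms = T_ms, refractory_ms = refractory_ms, f_c = f_c,
                 dt_ms = dt_ms, v_rest = v_rest, v_threshold = v_threshold),
            class = "lif_params")
}

#' Terminal adaptation rule
#'
#' Defines the pair-based update of the terminal weights `J`. For every pair
#' of a sub-threshold stimulation via terminal i and an evoked spike from a
#' different terminal of the same node, `J_i` is multiplied by `1 + delta`
#' plus additive noise, where `delta` depends on the time lag
#' `Delta = t_sub - t_spike`:
#' exponential profile `A * exp(-|Delta|/tau) * sign(Delta)`, or the
#' simplified two-level profile `A * sign(Delta)`; both vanish beyond the
#' cutoff.
#'
#' @param A Adaptation amplitude (0.05 default; 0.1 for the random-input
#'   single-node experiment).
#' @param tau_ms Exponential decay constant of the profile in ms (15).
#' @param cutoff_ms Pairing window in ms (50); lags beyond it adapt nothing.
#' @param profile `"exponential"` or `"two_level"`.
#' @param noise Half-width of the additive uniform noise `eta` drawn per
#'   adaptation event from `[-noise, noise]`; the classical value is
#'   `0.5e-3`, use 0 to disable.
#' @param j_bounds Clamp for terminal weights, default `c(1e-6, 10)`.
#' @return An object of class `adaptation_rule`.
#' @examples
#' adaptation_rule()                          # noiseless default
#' adaptation_rule(A = 0.1, noise = 0.5e-3)   # random-input configuration
#' @export
adaptation_rule <- function(A = 0.05, tau_ms = 15, cutoff_ms = 50,
                            profile = c("exponential", "two_level"),
                            noise = 0, j_bounds = c(1e-6, 10)) {
  profile <- match.arg(profile)
  stopifnot(A >= 0, tau_ms > 0, cutoff_ms >= 0, noise >= 0,
            length(j_bounds) == 2, j_bounds[1] > 0, j_bounds[1] < j_bounds[2])
  structure(list(A = A, tau_ms = tau_ms, cutoff_ms = cutoff_ms,
                 profile = profile, noise = noise, j_bounds = j_bounds),
            class = "adaptation_rule")
}

#' @export
print.lif_params <- function(x, ...) {
  cat("LIF parameters: T =", x$T_ms, "ms, refractory =", x$refractory_ms,
      "ms, f_c =", if (is.infinite(x$f_c)) "unbounded" else paste(x$f_c, "Hz"),
      ", dt =", x$dt_ms, "ms\n")
  invisible(x)
}

#' @export
print.adaptation_rule <- function(x, ...) {
  cat("Adaptation rule:", x$profile, "profile, A =", x$A,
      ", tau =", x$tau_ms, "ms, cutoff =", x$cutoff_ms, "ms, noise = ",
      x$noise, "\n  J bounds [", x$j_bounds[1], ",", x$j_bounds[2], "]\n")
  invisible(x)
}
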
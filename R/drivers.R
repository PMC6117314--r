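experiment_defaults <- function(name) {
  switch(name,
    feedforward_dynamics = list(
      K = 3, n_inputs = 15, rate_hz = 5, duration_s = 600, window_s = 200,
      A = 0.05, noise = 0, profile = "exponential", f_c = Inf,
      refractory_ms = 2, dt_ms = 1),
    oscillation_fraction = list(
      K = 3, n_inputs = 9, n_samples = 500, rate_hz = 5, duration_s = 600,
      window_s = 200, A = 0.05, noise = 0, dt_ms = 1),
    attractor_census = list(
      K = 3, n_inputs = 9, n_ic = 200, n_delay_sets = 10, rate_hz = 5,
      duration_s = 300, window_s = 100, dt_ms = 1),
    two_pool = list(
      n_nodes = 1000, K = 3, in_degree = NULL, mode = "adaptive_node",
      duration_s = 50, A = 0.05, noise = 0.5e-3, f_c = 15,
      refractory_ms = 2, dt_ms = 0.1, trigger_fraction = 0.4,
      bg_rate_hz = 0.01, sample_every_s = 1),
    random_recurrent = list(
      n_nodes = 1000, K = 3, in_degree = 180, duration_s = 50, A = 0.05,
      noise = 0.5e-3, f_c = 15, refractory_ms = 2, dt_ms = 0.1,
      trigger_fraction = 0.4, bg_rate_hz = 0.01, sample_every_s = 1),
    single_node_lognormal = list(
      K = 2, inputs_per_terminal = 60, rate_hz = 30, duration_s = 2500,
      transient_s = 200, A = 0.1, noise = 0.5e-3, f_c = 15,
      refractory_ms = 2, dt_ms = 0.1),
    refractory_sweep = list(
      rp_values_ms = c(0, 0.4, 1, 2, 3), duration_s = 500,
      transient_s = 100, A = 0.1, noise = 0.5e-3, dt_ms = 0.1),
    stop("unknown experiment: ", name))
}

#' Build an experiment configuration
#'
#' Returns the configuration of one of the canonical experiments with its
#' standard parameters, optionally overridden. Configurations round-trip
#' through YAML ([write_config()] / [read_config()]).
#'
#' @param experiment One of `"feedforward_dynamics"`,
#'   `"oscillation_fraction"`, `"attractor_census"`, `"two_pool"`,
#'   `"random_recurrent"`, `"single_node_lognormal"`,
#'   `"refractory_sweep"`.
#' @param seed Master seed; every random quantity of the run derives from
#'   it.
#' @param scale Uniform shrink factor applied to node counts, durations and
#'   sample counts (e.g. `scale = 0.1` for desk-sized runs).
#' @param ... Parameter overrides.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(experiment, seed = 1, scale = 1, ...) {
  cfg <- experiment_defaults(experiment)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown parameter(s) for ", experiment, ": ",
         paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (scale != 1) {
    for (f in intersect(c("n_nodes", "n_samples", "n_ic", "n_delay_sets"),
                        names(cfg)))
      cfg[[f]] <- max(1, round(cfg[[f]] * scale))
    if ("n_nodes" %in% names(cfg) && cfg$n_nodes %% 2 == 1)
      cfg$n_nodes <- cfg$n_nodes + 1
    for (f in intersect(c("duration_s", "transient_s", "window_s"),
                        names(cfg)))
      cfg[[f]] <- cfg[[f]] * scale
  }
  structure(c(list(experiment = experiment, seed = seed, scale = scale),
              cfg),
            class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' Report-only checks: divisibility of inputs by terminals, bounds, time
#' step versus refractory compatibility, and warnings when a parameter
#' deviates from the standard value for that experiment.
#'
#' @param config An `experiment_config` (or plain list with the same
#'   fields).
#' @return Data frame with columns `level` (`"error"`/`"warning"`/`"ok"`)
#'   and `message`.
#' @export
validate_config <- function(config) {
  msgs <- list()
  add <- function(level, message)
    msgs[[length(msgs) + 1L]] <<- data.frame(level = level, message = message)
  ref <- experiment_defaults(config$experiment)
  if (!is.null(config$n_inputs) && !is.null(config$K) &&
      config$n_inputs %% config$K != 0)
    add("error", sprintf("n_inputs = %d is not divisible by K = %d",
                         config$n_inputs, config$K))
  if (!is.null(config$in_degree) && !is.null(config$K) &&
      config$in_degree %% config$K != 0)
    add("error", sprintf("in_degree = %d is not divisible by K = %d",
                         config$in_degree, config$K))
  if (!is.null(config$refractory_ms) && !is.null(config$dt_ms)) {
    if (config$refractory_ms > 0 && config$refractory_ms < config$dt_ms)
      add("error", "refractory_ms must be 0 or at least dt_ms")
    if (config$refractory_ms > 0 && config$refractory_ms < 0.4)
      add("warning",
          "refractory period below 0.4 ms, the minimal value at which the stationary log-normal was characterised")
  }
  if (!is.null(config$duration_s) && config$duration_s <= 0)
    add("error", "duration_s must be positive")
  if (!is.null(config$in_degree) && !is.null(config$n_nodes)) {
    pool <- if (identical(config$experiment, "two_pool"))
      config$n_nodes / 2 else config$n_nodes - 1
    if (config$in_degree > pool)
      add("error", sprintf("in_degree = %d exceeds the available %d source nodes",
                           config$in_degree, pool))
  }
  if (identical(config$experiment, "random_recurrent") &&
      is.null(config$in_degree) && !is.null(config$n_nodes) &&
      !is.null(config$K) && 60 * config$K > config$n_nodes - 1)
    add("error", sprintf("default in_degree %d exceeds the available %d source nodes",
                         60 * config$K, config$n_nodes - 1))
  for (f in setdiff(names(ref), c("rp_values_ms"))) {
    if (!is.null(config[[f]]) && !identical(config[[f]], ref[[f]]) &&
        is.numeric(config[[f]]) && is.numeric(ref[[f]]) &&
        !isTRUE(all.equal(config[[f]], ref[[f]])))
      add("warning", sprintf("%s = %s deviates from the standard value %s",
                             f, format(config[[f]]), format(ref[[f]])))
  }
  if (!length(msgs)) add("ok", "configuration is valid")
  out <- do.call(rbind, msgs)
  rownames(out) <- NULL
  out
}

#' Write / read an experiment configuration
#'
#' @param config An `experiment_config`.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the configuration.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(x$rp_values_ms)) x$rp_values_ms <- as.numeric(x$rp_values_ms)
  structure(x, class = "experiment_config")
}

write_outputs <- function(outdir, config, summary, tables = list()) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(outdir, "config.yaml"))
  summary$package_version <- as.character(utils::packageVersion("adaptivenodes"))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(tables))
    write.csv(tables[[nm]], file.path(outdir, paste0(nm, ".csv")),
              row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Run a canonical experiment
#'
#' Executes one named experiment with its standard parameters (see
#' [experiment_config()]), writing a provenance record (`config.yaml`), a
#' `summary.json` and tidy CSV tables to `outdir` when given. The same
#' configuration and seed always reproduce identical outputs.
#'
#' @param config An `experiment_config`, or an experiment name (then
#'   `seed`, `scale`, `...` build the configuration).
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param seed,scale,... Used only when `config` is a name.
#' @return The experiment's result list, invisibly. Components depend on
#'   the experiment (classification, fractions, census, rates, fits,
#'   ordering statistics or sweep table).
#' @export
run_experiment <- function(config, outdir = NULL, seed = 1, scale = 1, ...) {
  if (is.character(config))
    config <- experiment_config(config, seed = seed, scale = scale, ...)
  rep <- validate_config(config)
  if (any(rep$level == "error"))
    stop("invalid configuration:\n  ",
         paste(rep$message[rep$level == "error"], collapse = "\n  "))
  cfg <- config
  res <- switch(cfg$experiment,
    feedforward_dynamics = {
      net <- build_feedforward(cfg$n_inputs, cfg$K, seed = cfg$seed)
      r <- run_feedforward_dynamics(
        net, cfg$duration_s, cfg$window_s, cfg$rate_hz,
        rule = adaptation_rule(A = cfg$A, noise = cfg$noise,
                               profile = cfg$profile),
        params = lif_params(f_c = cfg$f_c,
                            refractory_ms = cfg$refractory_ms,
                            dt_ms = cfg$dt_ms))
      tr <- j_traces(r$sim)
      traces <- data.frame(time_s = tr$time_s, tr$J)
      names(traces) <- c("time_s", paste0("J", seq_len(cfg$K)))
      write_outputs(outdir, cfg,
                    list(label = r$classification$label,
                         dominant_period_s = r$classification$dominant_period_s),
                    list(j_traces = traces,
                         edge_list = net$edges))
      list(classification = r$classification, sim = r$sim, network = net)
    },
    oscillation_fraction = {
      r <- oscillation_fraction(cfg$K, cfg$n_inputs, cfg$n_samples,
                                seed = cfg$seed,
                                duration_s = cfg$duration_s,
                                window_s = cfg$window_s,
                                rate_hz = cfg$rate_hz,
                                rule = adaptation_rule(A = cfg$A,
                                                       noise = cfg$noise))
      write_outputs(outdir, cfg,
                    list(fractions = as.list(r$fractions)),
                    list(labels = data.frame(sample = seq_along(r$labels),
                                             label = r$labels)))
      r
    },
    attractor_census = {
      r <- count_attractors(cfg$K, cfg$n_inputs, cfg$n_ic,
                            cfg$n_delay_sets, seed = cfg$seed,
                            duration_s = cfg$duration_s,
                            window_s = cfg$window_s, rate_hz = cfg$rate_hz)
      write_outputs(outdir, cfg,
                    list(mean_count = r$mean_count, sd_count = r$sd_count),
                    list(curves = data.frame(n_ic = seq_len(cfg$n_ic),
                                             r$curves)))
      r
    },
    two_pool = ,
    random_recurrent = {
      net <- if (cfg$experiment == "two_pool") {
        build_two_pool(cfg$n_nodes, cfg$K, cfg$in_degree, mode = cfg$mode,
                       seed = cfg$seed)
      } else {
        build_random_recurrent(cfg$n_nodes, cfg$K, cfg$in_degree,
                               seed = cfg$seed)
      }
      stim <- make_stimulus("initial_trigger_plus_background",
                            duration_s = cfg$duration_s,
                            n_nodes = cfg$n_nodes,
                            trigger_fraction = cfg$trigger_fraction,
                            bg_rate_hz = cfg$bg_rate_hz,
                            seed = cfg$seed + 1)
      half <- cfg$duration_s / 2
      sim <- simulate_network(
        net, stim, cfg$duration_s,
        params = lif_params(f_c = cfg$f_c,
                            refractory_ms = cfg$refractory_ms,
                            dt_ms = cfg$dt_ms),
        rule = adaptation_rule(A = cfg$A, noise = cfg$noise),
        seed = cfg$seed + 2,
        record = list(sample_weights_every_ms = cfg$sample_every_s * 1000,
                      log_events = "spikes",
                      count_from_ms = half * 1000))
      dist <- effective_weight_distribution(
        sim$wj_samples[sim$wj_times_s >= half, , drop = FALSE])
      write_outputs(outdir, cfg,
                    list(mean_node_rate_hz = mean(sim$node_rate_hz),
                         mean_terminal_rate_hz = mean(sim$terminal_rate_hz),
                         meanlog = dist$meanlog, sdlog = dist$sdlog,
                         ks_p = dist$ks_p),
                    list(spikes = spikes(sim),
                         wj_histogram = dist$histogram))
      list(sim = sim, network = net, distribution = dist)
    },
    single_node_lognormal = {
      sim <- simulate_random_input_node(
        K = cfg$K, inputs_per_terminal = cfg$inputs_per_terminal,
        rate_hz = cfg$rate_hz, duration_s = cfg$duration_s,
        transient_s = cfg$transient_s, A = cfg$A, noise = cfg$noise,
        f_c = cfg$f_c, refractory_ms = cfg$refractory_ms,
        dt_ms = cfg$dt_ms, seed = cfg$seed)
      wj <- as.vector(sim$wj_samples)
      dist <- effective_weight_distribution(wj)
      cl <- classify_strong_weak(wj)
      po <- spike_pair_ordering(sim, cl)
      force <- restoring_force(sim$adapt_log)
      write_outputs(outdir, cfg,
                    list(meanlog = dist$meanlog, sdlog = dist$sdlog,
                         ks_p = dist$ks_p, P_SW = po$P_SW, P_WS = po$P_WS,
                         ratio = po$ratio),
                    list(force_curve = force,
                         wj_histogram = dist$histogram))
      list(sim = sim, distribution = dist, classification = cl,
           ordering = po, force = force)
    },
    refractory_sweep = {
      r <- refractory_sweep(cfg$rp_values_ms, duration_s = cfg$duration_s,
                            transient_s = cfg$transient_s, seed = cfg$seed,
                            A = cfg$A, noise = cfg$noise,
                            dt_ms = cfg$dt_ms)
      write_outputs(outdir, cfg, list(n_points = nrow(r)),
                    list(sweep = r))
      r
    })
  invisible(res)
}
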
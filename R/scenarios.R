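#' Named experiment definition
#'
#' A scenario maps a name to configuration overrides and a replicate plan.
#' The built-in names cover the figure-level experiments: the baseline run,
#' the uniform-pretreatment control, density and MOI sweeps, the
#' threshold-fraction sweep, the simultaneous-secretion control, and the
#' large-population size check.
#'
#' @param name One of `"baseline"`, `"pretreatment"`, `"density_sweep"`,
#'   `"moi_sweep"`, `"threshold_sweep"`, `"simultaneous_secretion"`,
#'   `"size_check"`.
#' @param overrides Named list of [sim_config()] arguments applied on top of
#'   the scenario's own presets (rate overrides under a `rates` list).
#' @param replicates Number of replicate seeds (>= 1, default 10).
#' @param seeds Optional explicit seed vector (length `replicates`).
#' @return An object of class `ifn_scenario`.
#' @export
scenario_spec <- function(name = c("baseline", "pretreatment",
                                   "density_sweep", "moi_sweep",
                                   "threshold_sweep",
                                   "simultaneous_secretion", "size_check"),
                          overrides = list(), replicates = 10L,
                          seeds = NULL) {
  name <- match.arg(name)
  if (replicates < 1) stop("'replicates' must be >= 1")
  if (is.null(seeds)) seeds <- seq_len(replicates)
  if (length(seeds) != replicates)
    stop("'seeds' must have length 'replicates'")
  known <- names(formals(sim_config))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown))
    stop("unknown override field(s): ", paste(unknown, collapse = ", "))
  structure(list(name = name, overrides = overrides,
                 replicates = as.integer(replicates),
                 seeds = as.integer(seeds)),
            class = "ifn_scenario")
}

# expand a scenario into its list of variant configurations (without seeds)
scenario_variants <- function(spec, base = sim_config()) {
  stopifnot(inherits(spec, "ifn_scenario"), inherits(base, "ifn_config"))
  presets <- switch(spec$name,
    baseline = list(list()),
    pretreatment = list(list(moi = 0, pretreat_amount = 1200,
                             scenario = "pretreatment")),
    # density varied by scaling lattice area at fixed cell count, keeping
    # the Fano sample size constant across densities
    density_sweep = list(
      list(grid_nx = 80L, grid_ny = 80L, scenario = "density_quarter"),
      list(scenario = "density_baseline"),
      list(grid_nx = 20L, grid_ny = 20L, scenario = "density_4x")),
    moi_sweep = list(
      list(moi = 0.5, threshold_fraction = 0.10, scenario = "moi_0.5"),
      list(moi = 2.0, threshold_fraction = 0.10, scenario = "moi_2.0")),
    threshold_sweep = list(
      list(threshold_fraction = 0.05, scenario = "threshold_0.05"),
      list(threshold_fraction = 0.10, scenario = "threshold_0.10"),
      list(threshold_fraction = 0.475, scenario = "threshold_0.475")),
    simultaneous_secretion = list(list(scenario = "simultaneous_secretion")),
    size_check = list(list(n_cells = 1050L, grid_nx = 89L, grid_ny = 89L,
                           scenario = "size_check")))
  lapply(presets, function(p) {
    args <- utils::modifyList(p, spec$overrides)
    modify_config(base, args)
  })
}

#' Apply a named list of overrides to a configuration
#'
#' Non-rate fields are replaced directly; entries of a `rates` sub-list are
#' merged into the existing rate table. Unknown fields are rejected before
#' any computation.
#'
#' @param config An [sim_config()].
#' @param overrides Named list of [sim_config()] arguments, optionally with a
#'   `rates` list of [rate_table()] arguments.
#' @return A new validated `ifn_config`.
#' @export
modify_config <- function(config, overrides) {
  stopifnot(inherits(config, "ifn_config"))
  args <- unclass(config)
  if (!is.null(overrides$rates)) {
    args$rates <- do.call(rate_table,
                          utils::modifyList(unclass(args$rates)[names(formals(rate_table))],
                                            overrides$rates))
    overrides$rates <- NULL
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown))
    stop("unknown override field(s): ", paste(unknown, collapse = ", "))
  args <- utils::modifyList(args, overrides)
  do.call(sim_config, args[names(args) %in% known])
}

#' Switch a configuration to the simultaneous-secretion control
#'
#' Bypasses the stochastic enhanceosome assembly: every infected cell is
#' switched to the transcribing state at a single onset time and the
#' enhanceosome channels are frozen from then on; all other channels are
#' unchanged. The default onset is the median first-activation time of a
#' baseline run with the same configuration and seed, computed here and
#' reported via `message()`.
#'
#' @param config A baseline-compatible [sim_config()].
#' @param onset_h Onset time in hours; `NULL` (default) computes the
#'   baseline median activation time.
#' @return The modified configuration.
#' @export
simultaneous_secretion_mode <- function(config, onset_h = NULL) {
  stopifnot(inherits(config, "ifn_config"))
  if (is.null(onset_h)) {
    base <- modify_config(config, list(simultaneous_onset_h = NA_real_,
                                       scenario = "baseline"))
    sim <- run_simulation(base)
    onset_h <- stats::median(sim$first_on_s, na.rm = TRUE) / 3600
    if (!is.finite(onset_h))
      stop("no cell activated in the baseline run; supply 'onset_h'")
    message(sprintf(
      "simultaneous-secretion onset = baseline median activation time, %.2f h",
      onset_h))
  }
  modify_config(config, list(simultaneous_onset_h = onset_h,
                             scenario = "simultaneous_secretion"))
}

#' Run a scenario with replicates and write a self-describing run directory
#'
#' Executes [run_simulation()] for every variant configuration and replicate
#' seed, then writes per-variant config echoes (readable back with
#' [read_sim_config()]), a tidy observables CSV (columns `scenario`, `seed`,
#' `time_s`, `metric`, `value`), and a `summary.json` with the per-run and
#' replicate-averaged regression summaries. The echoed config plus seed list
#' regenerate the outputs exactly.
#'
#' @param spec An [scenario_spec()].
#' @param base Base configuration the overrides are applied to.
#' @param out_dir Output directory; `NULL` skips all file output.
#' @param quiet Suppress progress messages.
#' @return List with `runs` (list of `ifn_sim`), `summaries` (data frame,
#'   one row per run), and `means` (data frame, one row per variant).
#' @export
run_scenario <- function(spec, base = sim_config(), out_dir = NULL,
                         quiet = FALSE) {
  variants <- scenario_variants(spec, base)
  if (spec$name == "simultaneous_secretion")
    variants <- lapply(variants, simultaneous_secretion_mode)
  runs <- list()
  rows <- list()
  for (v in seq_along(variants)) {
    for (s in seq_along(spec$seeds)) {
      cfg <- modify_config(variants[[v]], list(seed = spec$seeds[s]))
      if (!quiet)
        message(sprintf("[%s] variant %s seed %d", spec$name,
                        cfg$scenario, cfg$seed))
      sim <- run_simulation(cfg)
      runs[[length(runs) + 1L]] <- sim
      rows[[length(rows) + 1L]] <-
        c(list(scenario = cfg$scenario, seed = cfg$seed),
          summarize_sim(sim))
    }
  }
  summaries <- do.call(rbind, lapply(rows, as.data.frame))
  num <- vapply(summaries, is.numeric, TRUE)
  num["seed"] <- FALSE
  means <- stats::aggregate(summaries[num],
                            by = list(scenario = summaries$scenario), mean)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (v in seq_along(variants))
      write_sim_config(variants[[v]],
                       file.path(out_dir, sprintf("config_%s.txt",
                                                  variants[[v]]$scenario)))
    obs <- do.call(rbind, lapply(runs, function(sim) {
      s <- sim$series
      long <- stats::reshape(
        s, direction = "long",
        varying = setdiff(names(s), c("time_s", "time_h")),
        v.names = "value", timevar = "metric",
        times = setdiff(names(s), c("time_s", "time_h")))
      data.frame(scenario = sim$config$scenario, seed = sim$config$seed,
                 time_s = long$time_s, metric = long$metric,
                 value = long$value, row.names = NULL)
    }))
    utils::write.csv(obs, file.path(out_dir, "observables.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(scenario = spec$name, seeds = spec$seeds,
           runs = summaries, means = means),
      file.path(out_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(runs = runs, summaries = summaries, means = means)
}

#' One-parameter sensitivity sweep
#'
#' Scales a single rate constant (or numeric configuration field) by each
#' factor and reports how the Fano peak and the expressing fraction move.
#'
#' @param base Base [sim_config()].
#' @param parameter Name of a [rate_table()] entry or numeric `sim_config()`
#'   field.
#' @param factors Numeric multipliers (e.g. `c(1/4, 1, 4)`).
#' @param seeds Replicate seeds per factor (default 1:3).
#' @return Data frame with one row per factor: replicate-averaged Fano peak
#'   height and time, 11 h Fano, and 11 h expressing fraction.
#' @export
sensitivity_sweep <- function(base = sim_config(), parameter, factors,
                              seeds = 1:3) {
  stopifnot(inherits(base, "ifn_config"))
  in_rates <- parameter %in% names(base$rates)
  if (!in_rates &&
      !(parameter %in% names(base) && is.numeric(base[[parameter]])))
    stop("unknown parameter: ", parameter)
  out <- lapply(factors, function(f) {
    ov <- if (in_rates)
      list(rates = stats::setNames(list(base$rates[[parameter]] * f),
                                   parameter))
    else stats::setNames(list(base[[parameter]] * f), parameter)
    cfg <- modify_config(base, c(ov, list(
      scenario = sprintf("%s_x%g", parameter, f))))
    sums <- lapply(seeds, function(s)
      summarize_sim(run_simulation(modify_config(cfg, list(seed = s)))))
    data.frame(parameter = parameter, factor = f,
               fano_peak = mean(vapply(sums, `[[`, 0, "fano_peak")),
               fano_peak_time_h = mean(vapply(sums, `[[`, 0,
                                              "fano_peak_time_h")),
               fano_11h = mean(vapply(sums, `[[`, 0, "fano_at_ref")),
               frac_expressing_11h = mean(vapply(
                 sums, `[[`, 0, "frac_expressing_at_ref")))
  })
  do.call(rbind, out)
}
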
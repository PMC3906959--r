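#' Stochastic rate constants for the cellular reaction network
#'
#' Builds the table of per-reaction stochastic rate constants used by the
#' simulator. All rates are per second (first-order) or per molecule per
#' second (bimolecular), on the copy-number scale of a single cell / lattice
#' box. The defaults are a calibrated, frozen set chosen so the baseline
#' scenario reproduces the anchor behaviors of the modeled system: first
#' IFN-beta mRNA 3-4 h post-infection, about half of the infected cells
#' expressing by 11 h, a population DDX58 Fano factor exceeding 50 by 7 h and
#' near 100 at 11 h, and cytokine spatial homogenization between 6 and 11 h.
#'
#' @param k_f1 First enhanceosome binding step forward rate (1/s); step i has
#'   forward rate `k_f1 * coop^(i-1)`, scaled by the RIG-I response.
#' @param coop Cooperativity factor (> 1) between successive binding steps.
#' @param k_b1,k_b2,k_b3,k_b4 Enhanceosome step unbinding rates (1/s).
#' @param k_act Activation rate from the fully assembled enhanceosome to the
#'   transcribing gene state (1/s).
#' @param k_deact Deactivation rate from transcribing back to the fully
#'   disassembled state (1/s).
#' @param v_ifnb_low,v_ifnb_high IFN-beta transcription rates (mRNA/s) before
#'   and after receptor-driven upregulation (IRF-3 to IRF-7 exchange,
#'   coarse-grained as a Hill function of bound IFNAR).
#' @param d_ifnb IFN-beta mRNA degradation rate (1/s).
#' @param k_sec Secretion rate per IFN-beta mRNA (protein/s); translation and
#'   export are fused into a single step.
#' @param k_on_r IFNAR binding rate (1/(molecule s)); acts on the product of
#'   free cytokine in the cell's box and free receptors.
#' @param k_off_r IFNAR unbinding rate (1/s).
#' @param k_g_off DDX58 gene active-to-basal switch rate (1/s); the
#'   basal-to-active rate is `k_g_off * (B/Bstar)^2` with B the bound-IFNAR
#'   count, so occupancy of the active state is 1/2 at the threshold.
#' @param v_dx_basal,v_dx_active DDX58 transcription rates (mRNA/s) in the
#'   basal and active gene states.
#' @param d_dx DDX58 mRNA degradation rate (1/s).
#' @param k_tr_rig RIG-I translation rate per DDX58 mRNA (protein/(mRNA s)).
#' @param d_rig RIG-I protein degradation rate (1/s).
#' @param K_rig,h_rig Hill constant (molecules) and coefficient of the RIG-I
#'   response scaling the enhanceosome forward rates.
#' @param h_irf7 Hill coefficient of the bound-IFNAR dependence of the
#'   IFN-beta transcription rate (half point is the receptor threshold).
#' @param d_ext Extracellular cytokine degradation rate (1/s); default 0.
#'
#' @return An object of class `ifn_rates` (named list).
#' @export
#' @examples
#' r <- rate_table()
#' r$k_f1
rate_table <- function(k_f1 = 2.06e-4, coop = 1.3, k_b1 = 5e-5, k_b2 = 5e-5,
                       k_b3 = 5e-5, k_b4 = 5e-5, k_act = 5e-3,
                       k_deact = 1e-4, v_ifnb_low = 0.012, v_ifnb_high = 1.0,
                       d_ifnb = 1e-4, k_sec = 0.03, k_on_r = 3e-6,
                       k_off_r = 2.5e-3, k_g_off = 3.5e-4, v_dx_basal = 5e-4,
                       v_dx_active = 0.09, d_dx = 5e-5, k_tr_rig = 1e-3,
                       d_rig = 1e-4, K_rig = 140, h_rig = 2, h_irf7 = 4,
                       d_ext = 0) {
  r <- list(k_f1 = k_f1, coop = coop, k_b1 = k_b1, k_b2 = k_b2, k_b3 = k_b3,
            k_b4 = k_b4, k_act = k_act, k_deact = k_deact,
            v_ifnb_low = v_ifnb_low, v_ifnb_high = v_ifnb_high,
            d_ifnb = d_ifnb, k_sec = k_sec, k_on_r = k_on_r,
            k_off_r = k_off_r, k_g_off = k_g_off, v_dx_basal = v_dx_basal,
            v_dx_active = v_dx_active, d_dx = d_dx, k_tr_rig = k_tr_rig,
            d_rig = d_rig, K_rig = K_rig, h_rig = h_rig, h_irf7 = h_irf7,
            d_ext = d_ext)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("rate '", nm, "' must be a single non-negative number")
  }
  if (r$coop < 1) stop("'coop' must be >= 1 (cooperative assembly)")
  if (r$v_dx_active <= r$v_dx_basal)
    stop("'v_dx_active' must exceed 'v_dx_basal'")
  if (r$v_ifnb_high < r$v_ifnb_low)
    stop("'v_ifnb_high' must be >= 'v_ifnb_low'")
  structure(r, class = "ifn_rates")
}

#' @export
print.ifn_rates <- function(x, ...) {
  cat("<ifn_rates> stochastic rate constants (1/s unless noted)\n")
  print(unlist(x))
  invisible(x)
}

# pack a rate table into the fixed-order numeric vector the engine expects
pack_rates <- function(rates) {
  stopifnot(inherits(rates, "ifn_rates"))
  as.numeric(unlist(rates[c("k_f1", "coop", "k_b1", "k_b2", "k_b3", "k_b4",
                            "k_act", "k_deact", "v_ifnb_low", "v_ifnb_high",
                            "d_ifnb", "k_sec", "k_on_r", "k_off_r",
                            "k_g_off", "v_dx_basal", "v_dx_active", "d_dx",
                            "k_tr_rig", "d_rig", "K_rig", "h_rig", "h_irf7",
                            "d_ext")]))
}

#' Enhanceosome forward rates implied by a rate table
#'
#' Cooperative sequential binding: step i has forward rate
#' `k_f1 * coop^(i-1)`, non-decreasing in i.
#'
#' @param rates An [rate_table()] object.
#' @return Numeric vector of length 4.
#' @export
enh_forward_rates <- function(rates) {
  stopifnot(inherits(rates, "ifn_rates"))
  rates$k_f1 * rates$coop^(0:3)
}

#' Simulation configuration
#'
#' The single source of truth for a run: lattice geometry, cell count,
#' infection level, diffusion, kinetics, scenario flags, and RNG seed.
#'
#' @param grid_nx,grid_ny Lattice box counts (default 40 x 40).
#' @param box_length Box side length in micrometers (default 30, about one
#'   dendritic-cell diameter; at most one cell per box).
#' @param n_cells Number of cells placed on the lattice (default 210).
#' @param moi Multiplicity of infection (default 0.5); the infected fraction
#'   is `1 - exp(-moi)` under Poisson infection statistics.
#' @param diffusion_coeff Cytokine diffusion coefficient, um^2/s (default 10).
#' @param hop_prob Probability that a molecule hops to an adjacent box per
#'   diffusion step (default 0.5); together with `box_length` and
#'   `diffusion_coeff` this fixes the synchronization step, 11.25 s at the
#'   defaults (see [diffusion_time_step()]).
#' @param total_hours Simulated time span in hours (default 15).
#' @param sample_interval Observable sampling interval in seconds (default
#'   300); samples are taken at the first synchronization point at or after
#'   each nominal sample time.
#' @param receptors_per_cell IFNAR copies per cell (default 1000).
#' @param threshold_fraction Fraction of receptors that must be bound for the
#'   DDX58 switch rate (and the IFN-beta transcription upgrade) to reach its
#'   half point (default 0.475, i.e. 475 of 1000).
#' @param rates A [rate_table()].
#' @param seed Integer master seed; placement, infection, initial state and
#'   the SSA/diffusion engine use seeds derived from it by fixed offsets.
#' @param infection_mode `"bernoulli"` (each cell infected independently with
#'   probability `1 - exp(-moi)`) or `"fixed_fraction"` (exactly
#'   `round(n_cells * (1 - exp(-moi)))` cells, a uniformly random subset).
#' @param pretreat_amount Free cytokines added per box at
#'   `pretreat_time_h` (default 0 = no pretreatment).
#' @param pretreat_time_h Pretreatment onset, hours (default 6).
#' @param pretreat_occupied_only If `TRUE`, pretreatment is added only to
#'   cell-occupied boxes (default `FALSE`: every box).
#' @param simultaneous_onset_h If finite, bypass stochastic enhanceosome
#'   assembly: every infected cell switches to the transcribing state at this
#'   time and the enhanceosome channels are frozen thereafter (default `NA`).
#' @param tag_sources Track the secreting cell of every extracellular and
#'   bound cytokine molecule (needed for [autocrine_fraction()]; costs time
#'   and memory, default `FALSE`).
#' @param scenario Free-text scenario label carried into outputs.
#'
#' @return An object of class `ifn_config`.
#' @export
#' @examples
#' cfg <- sim_config(total_hours = 1)
#' cfg$n_cells
sim_config <- function(grid_nx = 40L, grid_ny = 40L, box_length = 30,
                       n_cells = 210L, moi = 0.5, diffusion_coeff = 10,
                       hop_prob = 0.5, total_hours = 15,
                       sample_interval = 300, receptors_per_cell = 1000L,
                       threshold_fraction = 0.475, rates = rate_table(),
                       seed = 1L,
                       infection_mode = c("bernoulli", "fixed_fraction"),
                       pretreat_amount = 0, pretreat_time_h = 6,
                       pretreat_occupied_only = FALSE,
                       simultaneous_onset_h = NA_real_,
                       tag_sources = FALSE, scenario = "baseline") {
  infection_mode <- match.arg(infection_mode)
  cfg <- list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
              box_length = box_length, n_cells = as.integer(n_cells),
              moi = moi, diffusion_coeff = diffusion_coeff,
              hop_prob = hop_prob, total_hours = total_hours,
              sample_interval = sample_interval,
              receptors_per_cell = as.integer(receptors_per_cell),
              threshold_fraction = threshold_fraction, rates = rates,
              seed = as.integer(seed), infection_mode = infection_mode,
              pretreat_amount = pretreat_amount,
              pretreat_time_h = pretreat_time_h,
              pretreat_occupied_only = isTRUE(pretreat_occupied_only),
              simultaneous_onset_h = as.numeric(simultaneous_onset_h),
              tag_sources = isTRUE(tag_sources),
              scenario = as.character(scenario))
  validate_config(cfg)
  structure(cfg, class = "ifn_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (grid_nx < 1 || grid_ny < 1) stop("grid dimensions must be positive")
    if (n_cells < 1) stop("'n_cells' must be a positive integer")
    if (grid_nx * grid_ny < n_cells)
      stop("lattice capacity exceeded: ", n_cells, " cells on ",
           grid_nx, " x ", grid_ny, " boxes")
    if (moi < 0) stop("'moi' must be >= 0")
    if (hop_prob <= 0 || hop_prob > 1) stop("'hop_prob' must be in (0, 1]")
    if (threshold_fraction <= 0 || threshold_fraction > 1)
      stop("'threshold_fraction' must be in (0, 1]")
    if (diffusion_coeff <= 0) stop("'diffusion_coeff' must be > 0")
    if (box_length <= 0) stop("'box_length' must be > 0")
    if (total_hours <= 0) stop("'total_hours' must be > 0")
    if (sample_interval <= 0) stop("'sample_interval' must be > 0")
    if (receptors_per_cell < 1) stop("'receptors_per_cell' must be >= 1")
    if (pretreat_amount < 0) stop("'pretreat_amount' must be >= 0")
    if (!inherits(rates, "ifn_rates")) stop("'rates' must be a rate_table()")
  })
  invisible(cfg)
}

#' @export
print.ifn_config <- function(x, ...) {
  cat("<ifn_config> ", x$scenario, "\n", sep = "")
  cat(sprintf("  lattice %d x %d boxes of %g um, %d cells, MOI %g (%s)\n",
              x$grid_nx, x$grid_ny, x$box_length, x$n_cells, x$moi,
              x$infection_mode))
  cat(sprintf("  D = %g um^2/s, hop %g -> dt = %g s; %g h, sampled every %g s\n",
              x$diffusion_coeff, x$hop_prob,
              diffusion_time_step(x$box_length, x$diffusion_coeff, x$hop_prob),
              x$total_hours, x$sample_interval))
  cat(sprintf("  %d IFNAR/cell, threshold %g (B* = %g); seed %d\n",
              x$receptors_per_cell, x$threshold_fraction,
              receptor_threshold(x), x$seed))
  invisible(x)
}

#' Bound-receptor threshold implied by a configuration
#'
#' `B* = threshold_fraction * receptors_per_cell`: the bound-IFNAR count at
#' which the DDX58 switch rate equals the switch-off rate (half-maximal
#' stationary induction) and the IFN-beta transcription upgrade is half way.
#'
#' @param config An [sim_config()] object.
#' @return Numeric scalar.
#' @export
receptor_threshold <- function(config) {
  config$threshold_fraction * config$receptors_per_cell
}

#' Diffusion synchronization time step
#'
#' On a 4-neighbor 2D lattice, a random walker with per-step hop probability
#' `p` has mean-squared displacement `p * L^2` per step, so matching the
#' continuum law MSD = 4 D t gives a step of `p * L^2 / (4 D)`: 11.25 s at
#' the default geometry (p = 0.5, L = 30 um, D = 10 um^2/s).
#'
#' @param box_length Box side, um.
#' @param D Diffusion coefficient, um^2/s.
#' @param hop_prob Per-step hop probability.
#' @return Time step in seconds.
#' @export
#' @examples
#' diffusion_time_step(30, 10, 0.5)  # 11.25
diffusion_time_step <- function(box_length, D, hop_prob) {
  if (D <= 0) stop("'D' must be > 0")
  if (box_length <= 0) stop("'box_length' must be > 0")
  if (hop_prob <= 0 || hop_prob > 1) stop("'hop_prob' must be in (0, 1]")
  hop_prob * box_length^2 / (4 * D)
}

#' Expected infected fraction at a given multiplicity of infection
#'
#' Under Poisson infection statistics a cell escapes infection with
#' probability `exp(-moi)`, so the expected infected fraction is
#' `1 - exp(-moi)`: 39.3\% at MOI 0.5, 86.5\% at MOI 2.
#'
#' @param moi Multiplicity of infection (>= 0).
#' @return Probability in `[0, 1)`.
#' @export
#' @examples
#' expected_infected_fraction(0.5)
expected_infected_fraction <- function(moi) {
  if (any(moi < 0)) stop("'moi' must be >= 0")
  1 - exp(-moi)
}

#' Cell density of a configuration
#'
#' The simulation volume is the lattice area times one box length of
#' thickness (one cell diameter). At the defaults (210 cells on 40 x 40 boxes
#' of 30 um) the density is 4.86e6, roughly 5e6 cells/mL.
#'
#' @param config An [sim_config()] object.
#' @return Cells per milliliter.
#' @export
cell_density <- function(config) {
  vol_um3 <- (config$grid_nx * config$box_length) *
    (config$grid_ny * config$box_length) * config$box_length
  config$n_cells / (vol_um3 * 1e-12)  # 1 mL = 1e12 um^3
}

# -- flat key = value config file I/O ----------------------------------------

#' Read a simulation configuration from a key = value text file
#'
#' The format is a flat TOML-like subset: one `key = value` pair per line,
#' `#` comments, strings in double quotes, `true`/`false` booleans, numbers,
#' and rate constants under dotted keys `rates.<name>`. Any key that is not a
#' configuration field is rejected.
#'
#' @param path File path.
#' @return An `ifn_config`.
#' @seealso [write_sim_config()]
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("unparseable config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- lapply(kv, function(m) parse_config_value(m[[3]]))
  names(vals) <- keys
  is_rate <- startsWith(keys, "rates.")
  rate_args <- vals[is_rate]
  names(rate_args) <- sub("^rates\\.", "", names(rate_args))
  unknown_rates <- setdiff(names(rate_args), names(formals(rate_table)))
  if (length(unknown_rates))
    stop("unknown rate key(s): ", paste(unknown_rates, collapse = ", "))
  cfg_args <- vals[!is_rate]
  known <- setdiff(names(formals(sim_config)), "rates")
  unknown <- setdiff(names(cfg_args), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg_args$rates <- do.call(rate_table, rate_args)
  do.call(sim_config, cfg_args)
}

parse_config_value <- function(txt) {
  txt <- trimws(txt)
  if (grepl('^".*"$', txt)) return(gsub('^"|"$', "", txt))
  if (txt %in% c("true", "TRUE")) return(TRUE)
  if (txt %in% c("false", "FALSE")) return(FALSE)
  if (txt %in% c("nan", "NA", "na")) return(NA_real_)
  v <- suppressWarnings(as.numeric(txt))
  if (is.na(v)) stop("cannot parse config value: ", txt)
  v
}

#' Write a configuration as key = value text (round-trips with
#' [read_sim_config()])
#'
#' @param config An `ifn_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "ifn_config"))
  fmt <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) ifelse(v, "true", "false")
    else if (is.na(v)) "nan"
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }
  ln <- character(0)
  for (nm in setdiff(names(config), "rates"))
    ln <- c(ln, sprintf("%s = %s", nm, fmt(config[[nm]])))
  for (nm in names(config$rates))
    ln <- c(ln, sprintf("rates.%s = %s", nm, fmt(config$rates[[nm]])))
  writeLines(ln, path)
  invisible(path)
}
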
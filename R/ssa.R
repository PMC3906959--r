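#' Construct a single-cell state
#'
#' One agent's integer copy numbers and discrete gene states. Uninfected
#' cells never assemble the enhanceosome or carry IFN-beta mRNA; the receptor
#' pool satisfies `bound_ifnar + free_ifnar = receptors` at all times.
#'
#' @param infected Logical.
#' @param receptors Total IFNAR copies on the cell (default 1000).
#' @param enh_occ Enhanceosome occupancy, 0..4.
#' @param ifnb_gene `"assembling"` or `"transcribing"`.
#' @param m_ifnb IFN-beta mRNA count.
#' @param bound_ifnar Bound receptor count B.
#' @param dx_gene `"basal"` or `"active"`.
#' @param m_dx DDX58 mRNA count.
#' @param p_rig RIG-I protein count.
#' @return An object of class `cell_state` (named list).
#' @export
#' @examples
#' new_cell_state(infected = TRUE, p_rig = 100)
new_cell_state <- function(infected = FALSE, receptors = 1000L, enh_occ = 0L,
                           ifnb_gene = c("assembling", "transcribing"),
                           m_ifnb = 0L, bound_ifnar = 0L,
                           dx_gene = c("basal", "active"), m_dx = 0L,
                           p_rig = 0L) {
  ifnb_gene <- match.arg(ifnb_gene)
  dx_gene <- match.arg(dx_gene)
  s <- list(enh_occ = as.integer(enh_occ), ifnb_gene = ifnb_gene,
            m_ifnb = as.integer(m_ifnb),
            bound_ifnar = as.integer(bound_ifnar),
            free_ifnar = as.integer(receptors) - as.integer(bound_ifnar),
            dx_gene = dx_gene, m_dx = as.integer(m_dx),
            p_rig = as.integer(p_rig), infected = isTRUE(infected))
  validate_cell_state(s)
  structure(s, class = "cell_state")
}

validate_cell_state <- function(s) {
  counts <- c(s$enh_occ, s$m_ifnb, s$bound_ifnar, s$free_ifnar, s$m_dx,
              s$p_rig)
  if (any(counts < 0)) stop("cell state counts must be non-negative")
  if (s$enh_occ > 4) stop("'enh_occ' must be in 0..4")
  if (!s$infected &&
      (s$enh_occ != 0 || s$ifnb_gene != "assembling" || s$m_ifnb != 0))
    stop("uninfected cells must have enh_occ = 0, an assembling gene, ",
         "and no IFN-beta mRNA")
  invisible(s)
}

pack_cell_state <- function(s) {
  c(s$enh_occ, match(s$ifnb_gene, c("assembling", "transcribing")) - 1L,
    s$m_ifnb, s$bound_ifnar, s$free_ifnar,
    match(s$dx_gene, c("basal", "active")) - 1L, s$m_dx, s$p_rig,
    as.integer(s$infected))
}

unpack_cell_state <- function(v) {
  structure(list(enh_occ = v[[1]],
                 ifnb_gene = c("assembling", "transcribing")[v[[2]] + 1L],
                 m_ifnb = v[[3]], bound_ifnar = v[[4]], free_ifnar = v[[5]],
                 dx_gene = c("basal", "active")[v[[6]] + 1L], m_dx = v[[7]],
                 p_rig = v[[8]], infected = as.logical(v[[9]])),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf(
    "<cell_state> %s | enh %d/4 (%s) | m_ifnb %d | B %d/%d | DDX58 %s m_dx %d | RIG-I %d\n",
    if (x$infected) "infected" else "uninfected", x$enh_occ, x$ifnb_gene,
    x$m_ifnb, x$bound_ifnar, x$bound_ifnar + x$free_ifnar, x$dx_gene,
    x$m_dx, x$p_rig))
  invisible(x)
}

#' Local extracellular environment of a cell
#'
#' Only cytokine molecules inside the box that contains the cell can bind its
#' receptors; this wraps that one number.
#'
#' @param free_ifnb_in_box Unbound cytokine count in the cell's own box.
#' @return An object of class `local_environment`.
#' @export
local_environment <- function(free_ifnb_in_box = 0L) {
  if (free_ifnb_in_box < 0) stop("free cytokine count must be >= 0")
  structure(list(free_ifnb_in_box = as.integer(free_ifnb_in_box)),
            class = "local_environment")
}

#' Enhanceosome channel propensities of an infected cell
#'
#' Sequential cooperative binding of four proteins at the promoter: forward
#' step i runs at `k_f1 * coop^(i-1) * H(p_rig)` where
#' `H(R) = R^h / (K_rig^h + R^h)` is the saturating RIG-I response, backward
#' step i at `k_b(i)`. From full occupancy the gene activates to the
#' transcribing state at `k_act`; from transcribing it deactivates (full
#' disassembly) at `k_deact`.
#'
#' @param state A `cell_state`; must be infected.
#' @param rates A [rate_table()].
#' @return Named propensity vector (1/s) for the ten enhanceosome channels.
#' @export
enhanceosome_propensities <- function(state, rates) {
  stopifnot(inherits(state, "cell_state"))
  if (!state$infected)
    stop("enhanceosome propensities are defined only for infected cells")
  a <- cpp_cell_propensities(pack_cell_state(state), 0, pack_rates(rates),
                             Bstar = 1, b_irf7 = 1, enh_frozen = FALSE)
  a[1:10]
}

#' IFN-beta transcription rate as a function of bound IFNAR
#'
#' In the transcribing gene state the rate rises from `v_ifnb_low` to
#' `v_ifnb_high` as bound receptors accumulate (a coarse-grained account of
#' the replacement of constitutive IRF-3 by receptor-induced IRF-7):
#' `v_low + (v_high - v_low) * B^h / (b_half^h + B^h)`. Zero whenever the
#' gene is not transcribing.
#'
#' @param state A `cell_state`.
#' @param rates A [rate_table()].
#' @param b_half Bound-receptor half point (default 475, the receptor
#'   threshold of the default configuration).
#' @return Rate in mRNA/s.
#' @export
ifnb_transcription_rate <- function(state, rates, b_half = 475) {
  stopifnot(inherits(state, "cell_state"), inherits(rates, "ifn_rates"))
  if (state$ifnb_gene != "transcribing" || !state$infected) return(0)
  B <- state$bound_ifnar
  rates$v_ifnb_low + (rates$v_ifnb_high - rates$v_ifnb_low) *
    B^rates$h_irf7 / (b_half^rates$h_irf7 + B^rates$h_irf7)
}

#' DDX58 gene switching rates
#'
#' The interferon-stimulated gene toggles between a basal and an active
#' production state. The on rate scales quadratically with the bound-receptor
#' count relative to the threshold, `k_on(B) = k_g_off * (B / B*)^2` with
#' `B* = threshold_fraction * receptors_per_cell`; the off rate is the
#' constant `k_g_off`. At `B = B*` the stationary active-state occupancy is
#' therefore 1/2 (half-maximal induction).
#'
#' @param B Bound IFNAR count.
#' @param config An [sim_config()].
#' @param rates Rate table (defaults to `config$rates`).
#' @return Named numeric vector `c(k_on =, k_off =)` in 1/s.
#' @export
#' @examples
#' ddx58_switch_rates(475, sim_config())  # k_on == k_off
ddx58_switch_rates <- function(B, config, rates = config$rates) {
  stopifnot(inherits(config, "ifn_config"), inherits(rates, "ifn_rates"))
  if (B < 0 || B > config$receptors_per_cell)
    stop("'B' must be in 0..receptors_per_cell")
  bstar <- receptor_threshold(config)
  if (bstar <= 0) stop("receptor threshold must be positive")
  c(k_on = rates$k_g_off * (B / bstar)^2, k_off = rates$k_g_off)
}

#' Full reaction channel propensities of one cell
#'
#' The complete channel list of the per-cell stochastic network:
#' enhanceosome assembly/activation (infected cells only), IFN-beta
#' transcription, degradation and secretion, IFNAR binding/unbinding against
#' the free cytokine in the cell's own box, DDX58 gene switching,
#' transcription and degradation, and RIG-I translation and degradation.
#'
#' @param state A `cell_state`.
#' @param env A [local_environment()].
#' @param config An [sim_config()].
#' @param rates Rate table (defaults to `config$rates`).
#' @return Named propensity vector of the 21 channels (1/s).
#' @export
reaction_propensities <- function(state, env, config, rates = config$rates) {
  stopifnot(inherits(state, "cell_state"),
            inherits(env, "local_environment"),
            inherits(config, "ifn_config"))
  validate_cell_state(state)
  cpp_cell_propensities(pack_cell_state(state), env$free_ifnb_in_box,
                        pack_rates(rates),
                        Bstar = receptor_threshold(config),
                        b_irf7 = receptor_threshold(config),
                        enh_frozen = is.finite(config$simultaneous_onset_h))
}

#' Advance one cell by the exact stochastic simulation algorithm
#'
#' Direct-method Gillespie SSA over `[t0, t1]` with the box's free cytokine
#' treated as a local species: secretion adds to it, binding consumes from
#' it, unbinding returns to it. Used standalone for single-cell studies and
#' tests; [run_simulation()] runs the same compiled kernel for every cell
#' between diffusion synchronization points.
#'
#' @param state A `cell_state`.
#' @param env A [local_environment()] holding the box's free cytokine count.
#' @param t0,t1 Window bounds in seconds, `t1 > t0`.
#' @param config An [sim_config()].
#' @param rates Rate table (defaults to `config$rates`).
#' @param seed Optional integer seed (calls `set.seed` if given).
#' @return List with elements `state` (the advanced `cell_state`), `env`
#'   (updated local environment), `n_events`, and `secreted` (secretion
#'   events in the window).
#' @export
ssa_advance <- function(state, env, t0, t1, config, rates = config$rates,
                        seed = NULL) {
  stopifnot(inherits(state, "cell_state"),
            inherits(env, "local_environment"))
  if (t1 <= t0) stop("'t1' must exceed 't0'")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_ssa_advance(pack_cell_state(state), env$free_ifnb_in_box,
                         t0, t1, pack_rates(rates),
                         Bstar = receptor_threshold(config),
                         b_irf7 = receptor_threshold(config),
                         enh_frozen = is.finite(config$simultaneous_onset_h))
  list(state = unpack_cell_state(res$state),
       env = local_environment(res$box_free),
       n_events = res$n_events, secreted = res$secreted)
}
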
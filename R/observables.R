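#' Fano factor of a copy-number sample
#'
#' Variance over mean across cells, the standard dispersion measure for
#' copy-number distributions: 1 for Poisson, > 1 for bursting or
#' population heterogeneity. Uses the sample (n - 1) variance.
#'
#' @param counts Non-empty numeric vector of copy numbers.
#' @return `var(counts)/mean(counts)`, or `NA_real_` when the mean is zero
#'   (the ratio is undefined, not zero).
#' @export
#' @examples
#' fano_factor(c(2, 4, 6))  # 1
fano_factor <- function(counts) {
  if (length(counts) == 0) stop("'counts' must be non-empty")
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  stats::var(counts) / m
}

#' Fraction of infected cells containing IFN-beta mRNA
#'
#' Uninfected cells are excluded from both numerator and denominator.
#'
#' @param m_ifnb IFN-beta mRNA counts, one per cell.
#' @param infected Logical vector of the same length.
#' @return Fraction in `[0, 1]`, or `NA_real_` if there are no infected
#'   cells.
#' @export
fraction_expressing <- function(m_ifnb, infected) {
  stopifnot(length(m_ifnb) == length(infected))
  n_inf <- sum(infected)
  if (n_inf == 0) return(NA_real_)
  sum(m_ifnb > 0 & infected) / n_inf
}

#' Bin per-box values into spatial display categories
#'
#' Half-open binning `[0, b1), [b1, b2), [b2, b3), [b3, Inf)` (a boundary
#' value goes to the upper bin), the convention used for the color-coded
#' lattice maps of mRNA (breakpoints 375/750/1125) and free cytokine
#' (breakpoints 133/400/1200).
#'
#' @param values Non-negative numeric vector (or matrix) of per-box values.
#' @param breakpoints Strictly increasing numeric vector.
#' @return Integer category codes (0 = lowest) with the shape of `values`.
#' @export
#' @examples
#' categorize_spatial_map(c(0, 375, 1300), c(375, 750, 1125))  # 0 1 3
categorize_spatial_map <- function(values, breakpoints) {
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("'breakpoints' must be strictly increasing")
  codes <- findInterval(values, breakpoints)
  if (is.matrix(values)) codes <- matrix(codes, nrow(values))
  codes
}

#' Bound-receptor histograms stratified by IFN-beta expression
#'
#' Splits the population into cells with IFN-beta mRNA (bound receptors from
#' autocrine plus paracrine ligand) and cells without (uninfected cells
#' pooled with non-expressing infected cells; paracrine only) and histograms
#' the bound-IFNAR counts of each stratum on shared breaks.
#'
#' @param bound_ifnar Bound receptor counts, one per cell.
#' @param m_ifnb IFN-beta mRNA counts, one per cell.
#' @param breaks Histogram breaks (default 20 equal bins spanning both
#'   strata).
#' @return List with data frames `with_mrna` and `without_mrna`
#'   (columns `bin_lo`, `bin_hi`, `count`) and the shared `breaks`.
#' @export
bound_receptor_histograms <- function(bound_ifnar, m_ifnb, breaks = NULL) {
  stopifnot(length(bound_ifnar) == length(m_ifnb))
  expressing <- m_ifnb > 0
  if (is.null(breaks))
    breaks <- seq(0, max(bound_ifnar, 1), length.out = 21)
  tab <- function(x) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)
    data.frame(bin_lo = utils::head(h$breaks, -1),
               bin_hi = utils::tail(h$breaks, -1), count = h$counts)
  }
  list(with_mrna = tab(bound_ifnar[expressing]),
       without_mrna = tab(bound_ifnar[!expressing]), breaks = breaks)
}

#' Autocrine fraction of bound receptor-ligand complexes
#'
#' Among all currently bound complexes, the fraction whose ligand was
#' secreted by the receptor's own cell (source recorded at binding time;
#' requires `tag_sources = TRUE` in the configuration).
#'
#' @param self_bound Per-cell counts of self-sourced bound complexes.
#' @param bound_ifnar Per-cell total bound complexes.
#' @return Fraction in `[0, 1]`; `NA_real_` if no complexes are bound, or if
#'   tagging was disabled (`self_bound` is `NULL`).
#' @export
autocrine_fraction <- function(self_bound, bound_ifnar) {
  if (is.null(self_bound)) return(NA_real_)
  stopifnot(length(self_bound) == length(bound_ifnar))
  tot <- sum(bound_ifnar)
  if (tot == 0) return(NA_real_)
  sum(self_bound) / tot
}

#' Population observable time series of a simulation
#'
#' One row per sample time: the DDX58 Fano factor over all cells (infected
#' and uninfected), the expressing fraction among infected cells, population
#' means, the fraction of occupied boxes in the lowest/highest free-cytokine
#' display categories, and the autocrine fraction (NA unless sources were
#' tagged).
#'
#' @param sim An `ifn_sim` from [run_simulation()].
#' @param cytokine_breaks Free-cytokine category breakpoints (default
#'   133/400/1200).
#' @return Data frame with columns `time_s`, `time_h`, `fano_dx`,
#'   `frac_expressing`, `mean_dx`, `mean_bound`, `frac_boxes_low`,
#'   `frac_boxes_high`, `autocrine_fraction`.
#' @export
observable_series <- function(sim, cytokine_breaks = c(133, 400, 1200)) {
  stopifnot(inherits(sim, "ifn_sim"))
  occ <- occupied_box_index(sim)
  inf <- sim$cells$infected
  ns <- length(sim$times)
  out <- data.frame(time_s = sim$times, time_h = sim$times / 3600)
  out$fano_dx <- vapply(seq_len(ns),
                        function(i) fano_factor(sim$m_dx[i, ]), 0)
  out$frac_expressing <- vapply(seq_len(ns), function(i)
    fraction_expressing(sim$m_ifnb[i, ], inf), 0)
  out$mean_dx <- rowMeans(sim$m_dx)
  out$mean_bound <- rowMeans(sim$bound_ifnar)
  occ_field <- sim$field[, occ, drop = FALSE]
  cat_codes <- categorize_spatial_map(occ_field, cytokine_breaks)
  out$frac_boxes_low <- rowMeans(cat_codes == 0)
  out$frac_boxes_high <- rowMeans(cat_codes == 3)
  out$autocrine_fraction <- if (is.null(sim$self_bound)) NA_real_ else
    vapply(seq_len(ns), function(i)
      autocrine_fraction(sim$self_bound[i, ], sim$bound_ifnar[i, ]), 0)
  out
}

#' Scalar summary of one run
#'
#' The regression quantities tracked for every scenario: Fano peak height
#' and time, the 11 h Fano factor, the 11 h expressing fraction, and the
#' 11 h percentage of occupied boxes above the highest cytokine category
#' breakpoint.
#'
#' @param sim An `ifn_sim`.
#' @param at_hours Reference time (default 11).
#' @return Named list.
#' @export
summarize_sim <- function(sim, at_hours = 11) {
  s <- sim$series
  i_peak <- which.max(ifelse(is.na(s$fano_dx), -Inf, s$fano_dx))
  i_ref <- sample_index_at(sim, at_hours)
  list(fano_peak = s$fano_dx[i_peak],
       fano_peak_time_h = s$time_h[i_peak],
       fano_at_ref = s$fano_dx[i_ref],
       frac_expressing_at_ref = s$frac_expressing[i_ref],
       pct_boxes_high_at_ref = 100 * s$frac_boxes_high[i_ref],
       pct_boxes_low_at_ref = 100 * s$frac_boxes_low[i_ref],
       ref_hours = s$time_h[i_ref],
       median_activation_h = stats::median(sim$first_on_s, na.rm = TRUE) / 3600)
}
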
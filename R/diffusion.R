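#' Create an empty cytokine lattice field
#'
#' @param config An [sim_config()].
#' @return Integer matrix of zeros with `grid_ny` rows and `grid_nx` columns
#'   (x = column, y = row), class `ifn_field`.
#' @export
empty_field <- function(config) {
  structure(matrix(0L, nrow = config$grid_ny, ncol = config$grid_nx),
            class = c("ifn_field", "matrix", "array"))
}

#' One lattice random-walk diffusion sweep
#'
#' Every molecule independently hops to one of its 4 neighbors with total
#' probability `hop_prob` (uniform over directions) or stays put. Boundaries
#' are reflecting: an attempted exit leaves the molecule in place. The sweep
#' is sampled per box (binomial leavers, multinomial directions), which is
#' distributionally identical to walking molecules one by one; the total
#' count is conserved exactly.
#'
#' @param field Integer matrix of non-negative per-box counts (y = row,
#'   x = column).
#' @param hop_prob Per-step hop probability in (0, 1].
#' @param seed Optional integer seed.
#' @return Matrix of the same shape.
#' @export
diffusion_sweep <- function(field, hop_prob, seed = NULL) {
  if (!is.matrix(field)) stop("'field' must be a matrix")
  if (any(field < 0)) stop("'field' must be non-negative")
  if (hop_prob <= 0 || hop_prob > 1) stop("'hop_prob' must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_diffusion_sweep(matrix(as.integer(field), nrow(field)), hop_prob)
  structure(out, class = class(field))
}

#' Add a uniform cytokine pretreatment to the field
#'
#' Emulates bath application of the cytokine: every box (or, optionally,
#' only cell-occupied boxes) receives `amount_per_box` additional free
#' molecules. Inside [run_simulation()] this is applied once at the
#' configured onset time.
#'
#' @param field Integer matrix of per-box counts.
#' @param amount_per_box Molecules added per box (>= 0).
#' @param occupied_only If `TRUE`, add only at boxes listed in `grid`.
#' @param grid An `ifn_grid` (required when `occupied_only = TRUE`).
#' @return The incremented field.
#' @export
apply_pretreatment <- function(field, amount_per_box, occupied_only = FALSE,
                               grid = NULL) {
  if (amount_per_box < 0) stop("'amount_per_box' must be >= 0")
  if (!occupied_only) return(field + as.integer(amount_per_box))
  if (is.null(grid)) stop("'grid' is required when 'occupied_only' is TRUE")
  idx <- cbind(grid$box_y + 1L, grid$box_x + 1L)
  field[idx] <- field[idx] + as.integer(amount_per_box)
  field
}
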
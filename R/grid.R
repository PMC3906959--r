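#' Place cells on the lattice
#'
#' Selects `n_cells` distinct boxes uniformly at random without replacement
#' (at most one cell per box) on the `grid_nx` x `grid_ny` lattice.
#'
#' @param config An [sim_config()].
#' @param seed Integer seed for the placement stream; defaults to a fixed
#'   offset of the master seed so that placement is independent of the other
#'   stages.
#' @return An object of class `ifn_grid`: data frame columns `cell`,
#'   `box_x`, `box_y` (0-based), `infected` (all `FALSE` until
#'   [assign_infection()]), with the grid dimensions as attributes.
#' @export
#' @examples
#' g <- build_grid(sim_config())
#' nrow(g)  # 210
build_grid <- function(config, seed = config$seed + 11L) {
  validate_config(config)
  nb <- config$grid_nx * config$grid_ny
  if (nb < config$n_cells)
    stop("lattice capacity exceeded: ", config$n_cells, " cells on ",
         nb, " boxes")
  set.seed(seed)
  idx <- sample.int(nb, config$n_cells, replace = FALSE) - 1L
  g <- data.frame(cell = seq_len(config$n_cells),
                  box_x = idx %/% config$grid_ny,
                  box_y = idx %% config$grid_ny,
                  infected = FALSE)
  structure(g, class = c("ifn_grid", "data.frame"),
            grid_nx = config$grid_nx, grid_ny = config$grid_ny)
}

#' Assign infection status to placed cells
#'
#' Each cell is infected independently with probability `1 - exp(-moi)` (the
#' Poisson zero-class; mode `"bernoulli"`), or a uniformly random subset of
#' exactly `round(n * (1 - exp(-moi)))` cells is infected (mode
#' `"fixed_fraction"`, which reproduces a deterministic infected fraction for
#' regression runs). Only infected cells ever carry the IFN-beta reactions.
#'
#' @param grid An `ifn_grid` from [build_grid()].
#' @param moi Multiplicity of infection (>= 0).
#' @param seed Integer seed for the infection stream.
#' @param mode `"bernoulli"` or `"fixed_fraction"`.
#' @return The grid with its `infected` column filled in.
#' @export
assign_infection <- function(grid, moi, seed = 1L,
                             mode = c("bernoulli", "fixed_fraction")) {
  stopifnot(inherits(grid, "ifn_grid"))
  mode <- match.arg(mode)
  if (moi < 0) stop("'moi' must be >= 0")
  n <- nrow(grid)
  p <- expected_infected_fraction(moi)
  set.seed(seed)
  if (mode == "bernoulli") {
    grid$infected <- stats::runif(n) < p
  } else {
    k <- round(n * p)
    grid$infected <- rep(FALSE, n)
    if (k > 0) grid$infected[sample.int(n, k)] <- TRUE
  }
  grid
}
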
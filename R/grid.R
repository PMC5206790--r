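## Cell-state codes used throughout the lattice state matrix.
STATE_EMPTY <- 0L
STATE_P <- 1L
STATE_Q <- 2L
STATE_A <- 3L
STATE_N <- 4L

#' Create an empty simulation grid
#'
#' Builds the lattice state shared by all modules: the cell-state matrix
#' (one cell per element at most), the per-cell cycle attributes stored as
#' lattice matrices, the capillary density field `E` (at its baseline
#' `E_0` everywhere), the matrix-integrity field (1 everywhere), and the
#' four concentration fields. VEGF and both proteases start at zero;
#' oxygen starts at its normalized physiological steady state (1 over the
#' intact capillary field).
#'
#' The grid is an environment (mutated in place by the driver) of class
#' `sim_grid`.
#'
#' @param params a [model_params()] object.
#' @return a `sim_grid` environment.
#' @export
simulation_grid <- function(params = model_params()) {
  stopifnot(inherits(params, "vt_params"))
  n <- as.integer(params$grid_n)
  g <- new.env(parent = emptyenv())
  g$params <- params
  g$n <- n
  g$dx <- params$dx
  zero <- matrix(0, n, n)
  g$occ <- matrix(STATE_EMPTY, n, n)   # cell state per element
  g$E <- matrix(params$E_0, n, n)      # implicit capillary field
  g$integrity <- matrix(1, n, n)       # extracellular-matrix integrity
  g$V <- zero; g$O <- matrix(1, n, n); g$p <- zero; g$m <- zero
  ## per-cell attributes, lattice-aligned (defined only where occ > 0)
  g$mu <- zero          # cycle duration, h
  g$g1 <- zero          # G1 duration, h (mu - S - G2 - M)
  g$phase <- matrix(0L, n, n)  # 1 G1, 2 S, 3 G2, 4 M
  g$clock <- zero       # h elapsed in current phase
  g$ready <- matrix(FALSE, n, n)  # M completed, awaiting division
  g$ready_since <- zero # sim time h at which the cell became ready
  g$death_time <- zero  # sim time h of death (A/N), for lysis
  g$time <- 0           # simulation clock, h
  g$network <- NULL     # vessel_network, attached by the initializer
  g$sprouts <- list()   # active sprout tips
  ## exact bookkeeping counters
  g$n_divisions <- 0L; g$n_apoptosis <- 0L; g$n_necrosis <- 0L
  g$n_lysed <- 0L
  class(g) <- c("sim_grid", "environment")
  g
}

#' @export
print.sim_grid <- function(x, ...) {
  counts <- state_counts(x)
  cat(sprintf("<sim_grid> %d x %d lattice (dx = %g mm), t = %g h\n",
              x$n, x$n, x$dx, x$time))
  cat(sprintf("  cells: P %d, Q %d, A %d, N %d\n",
              counts[["P"]], counts[["Q"]], counts[["A"]], counts[["N"]]))
  cat(sprintf("  vessels: %s\n",
              if (is.null(x$network)) "none"
              else sprintf("%d segments, %d active sprouts",
                           x$network$n_seg, length(x$sprouts))))
  invisible(x)
}

#' Cell-state census of a grid
#'
#' @param grid a `sim_grid`.
#' @return named integer vector with counts of `P`, `Q`, `A`, `N` cells.
#' @export
state_counts <- function(grid) {
  tab <- tabulate(grid$occ, nbins = 4L)
  c(P = tab[1], Q = tab[2], A = tab[3], N = tab[4])
}

#' Place a cell on the grid
#'
#' Low-level helper used by the initializer and by division: writes a cell
#' with the given state and cycle attributes into a free element.
#'
#' @param grid a `sim_grid`.
#' @param i,j element coordinates.
#' @param state one of `"P"`, `"Q"`.
#' @param mu cycle duration (h).
#' @param phase phase index (1 = G1 .. 4 = M).
#' @param clock h already elapsed in `phase`.
#' @return the grid, invisibly.
#' @export
place_cell <- function(grid, i, j, state = "P", mu = grid$params$mu0,
                       phase = 1L, clock = 0) {
  if (grid$occ[i, j] != STATE_EMPTY)
    stop("element (", i, ", ", j, ") is already occupied", call. = FALSE)
  p <- grid$params
  grid$occ[i, j] <- switch(state, P = STATE_P, Q = STATE_Q,
                           stop("cells are placed alive (P or Q)"))
  grid$mu[i, j] <- mu
  grid$g1[i, j] <- mu - (p$S_dur + p$G2_dur + p$M_dur)
  grid$phase[i, j] <- as.integer(phase)
  grid$clock[i, j] <- clock
  grid$ready[i, j] <- FALSE
  invisible(grid)
}

## matrix of effective oxygen-uptake rates per element (per h)
uptake_matrix <- function(grid) {
  r <- oxy_rates(grid$params)
  k <- matrix(r$k_0, grid$n, grid$n)
  k[grid$occ == STATE_P] <- r$k_P
  k[grid$occ == STATE_Q] <- r$k_Q
  k[grid$occ == STATE_A | grid$occ == STATE_N] <- 0
  k
}
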
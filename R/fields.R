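#' One explicit reaction--diffusion update
#'
#' Integrates \eqn{\partial F/\partial t = D\nabla^2F + prod - decay\,F -
#' cons\,\min(F, cap)} over `dt` by forward-Euler sub-steps of a 5-point
#' Laplacian with no-flux boundaries, clamping negatives after the
#' reaction terms. The sub-step is chosen automatically at
#' `substep_safety` times the explicit stability limit
#' \eqn{\min(dx^2/4D,\ 1/\max(decay+cons))}; passing `nsub` explicitly
#' with a sub-step above the limit is an error.
#'
#' @param F field matrix.
#' @param prod production-rate matrix (or scalar).
#' @param decay decay-rate matrix (or scalar), per h.
#' @param cons saturable consumption-rate matrix (or scalar), per h.
#' @param cap saturation level for consumption (`Inf` = linear).
#' @param D diffusion coefficient, mm^2/h.
#' @param dx lattice spacing, mm.
#' @param dt total time increment, h.
#' @param nsub number of sub-steps (`NULL` = automatic).
#' @param safety fraction of the stability limit used by the automatic
#'   sub-step.
#' @param box integration sub-box `c(i0, i1, j0, j1)` (default: full grid).
#' @return the updated field matrix.
#' @export
rd_step <- function(F, prod = 0, decay = 0, cons = 0, cap = Inf, D, dx, dt,
                    nsub = NULL, safety = 0.9, box = NULL) {
  n1 <- nrow(F); n2 <- ncol(F)
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, n1, n2)
  prod <- as_mat(prod)
  none <- matrix(numeric(0), 0, 0)
  ## a spatially varying decay is folded into the (uncapped) consumption
  ## term, which the kernel evaluates as cons * min(F, cap)
  if (is.matrix(decay)) {
    if (is.matrix(cons) || cons != 0)
      cons <- as_mat(cons) + decay
    else cons <- decay
    if (is.finite(cap) && any(decay > 0))
      stop("capped consumption cannot be combined with a spatially ",
           "varying decay", call. = FALSE)
    decay_s <- 0
  } else {
    decay_s <- decay
    cons <- if (is.matrix(cons) || any(cons != 0)) as_mat(cons) else none
  }
  dt_lim <- dx^2 / (4 * D)
  rmax <- decay_s + (if (length(cons)) max(cons) else 0)
  if (rmax > 0) dt_lim <- min(dt_lim, 1 / rmax)
  if (is.null(nsub)) {
    nsub <- max(1L, ceiling(dt / (safety * dt_lim)))
  } else if (dt / nsub > dt_lim) {
    stop(sprintf(
      "sub-step %.3g h exceeds the explicit stability limit %.3g h",
      dt / nsub, dt_lim), call. = FALSE)
  }
  if (is.null(box)) box <- c(1L, n1, 1L, n2)
  cpp_rd_step(F, prod, decay_s, cons, cap, D, dx, dt / nsub,
              as.integer(nsub), as.integer(box))
}

## bounding box of the support of any of the given matrices, with margin;
## the threshold is relative to each matrix's maximum, so the negligible
## diffusive tail (4 orders of magnitude below peak, well under every
## threshold acting on a field) is truncated
support_box <- function(mats, n, margin = 8L, rel_eps = 1e-4,
                        abs_eps = 0) {
  abs_eps <- rep_len(abs_eps, length(mats))
  any_nz <- Reduce(`|`, lapply(seq_along(mats), function(q) {
    M <- mats[[q]]
    M > max(rel_eps * max(M, 0), abs_eps[q])
  }))
  rows <- which(rowSums(any_nz) > 0)
  cols <- which(colSums(any_nz) > 0)
  if (!length(rows)) return(NULL)
  c(max(1L, min(rows) - margin), min(n, max(rows) + margin),
    max(1L, min(cols) - margin), min(n, max(cols) + margin))
}

#' Quasi-steady oxygen field
#'
#' Solves the discrete steady state of the oxygen equation
#' \eqn{D_O\nabla^2 O + \gamma_v W (O_v - O) - k O = 0} with no-flux
#' boundaries by red-black SOR, warm-started from the supplied field.
#' If the system carries no exchange and no uptake anywhere it is
#' singular; a uniform field is returned with a warning.
#'
#' @param grid a `sim_grid` (its `O` field is used as the starting guess
#'   and the exchange/uptake maps are derived from its state), or an
#'   oxygen matrix if `gammaW` and `k` are supplied.
#' @param gammaW per-element exchange-rate matrix
#'   \eqn{\gamma_v W_{ij}} (per h).
#' @param k per-element uptake-rate matrix (per h).
#' @param params a [model_params()] object.
#' @param tol SOR convergence tolerance (max absolute update).
#' @param max_iter sweep limit.
#' @return the steady oxygen matrix (and, for a grid, stores it in place).
#' @export
steady_oxygen <- function(grid, gammaW = NULL, k = NULL,
                          params = if (inherits(grid, "sim_grid"))
                            grid$params else model_params(),
                          tol = params$steady_tol, max_iter = 20000L) {
  if (inherits(grid, "sim_grid")) {
    wm <- weight_matrices(grid$network, grid$E, params,
                          active_sprout_ids(grid))
    O <- steady_oxygen(grid$O, wm$gammaW, uptake_matrix(grid), params,
                       tol = tol, max_iter = max_iter)
    grid$O <- O
    return(O)
  }
  O0 <- grid
  if (all(gammaW == 0) && all(k == 0)) {
    warning("oxygen system is singular (no exchange, no uptake); ",
            "returning a uniform field")
    return(matrix(mean(O0), nrow(O0), ncol(O0)))
  }
  res <- cpp_steady_oxygen(O0, gammaW, k, params$D_O, params$dx, params$O_v,
                           tol, as.integer(max_iter), 1.8)
  res$O
}

#' Advance all diffusive fields over one automaton step
#'
#' Performs the field update of one automaton step on a grid: VEGF
#' (produced by quiescent cells, consumed by the vasculature with
#' receptor saturation), tumour proteases (produced by proliferative
#' cells), sprout proteases (produced by active sprout segments) are
#' integrated explicitly; oxygen is either solved quasi-steadily
#' (default) or integrated explicitly, with exchange
#' \eqn{\gamma_v W (O_v - O)} against the perfused vasculature and
#' state-dependent uptake.
#'
#' @param grid a `sim_grid` (mutated in place).
#' @param dt automaton step, h.
#' @param use_box logical; restrict the explicit updates to the support
#'   bounding box of each field (a pure run-time optimization -- the box
#'   always covers the field support and all sources with a margin).
#' @return the grid, invisibly.
#' @export
step_fields <- function(grid, dt = 1, use_box = TRUE) {
  p <- grid$params
  n <- grid$n
  occ <- grid$occ
  Qmask <- (occ == STATE_Q) * 1
  Pmask <- (occ == STATE_P) * 1
  wm <- weight_matrices(grid$network, grid$E, p, active_sprout_ids(grid))
  kmat <- uptake_matrix(grid)
  ## integration boxes truncate each field where it is dynamically inert:
  ## far below its own peak and far below any threshold acting on it
  box_of <- function(F, src, abs_eps = 0) {
    if (!use_box) return(NULL)
    b <- support_box(list(F, src), n, abs_eps = c(abs_eps, 0))
    if (is.null(b)) c(1L, 1L, 1L, 1L) else b
  }
  grid$V <- rd_step(grid$V, prod = p$alpha_V * Qmask, decay = p$nu_V,
                    cons = p$lambda_V * wm$W_vegf, cap = p$V_max,
                    D = p$D_V, dx = p$dx, dt = dt,
                    safety = p$substep_safety,
                    box = box_of(grid$V, Qmask, 0.04 * p$V_sprout))
  grid$p <- rd_step(grid$p, prod = p$alpha_p * Pmask, decay = p$nu_p,
                    D = p$D_p, dx = p$dx, dt = dt,
                    safety = p$substep_safety,
                    box = box_of(grid$p, Pmask, 0.04 * p$p_degrade))
  grid$m <- rd_step(grid$m, prod = p$alpha_m * wm$n_mask, decay = p$nu_m,
                    D = p$D_m, dx = p$dx, dt = dt,
                    safety = p$substep_safety,
                    box = box_of(grid$m, wm$n_mask))
  if (p$oxygen_mode == "steady") {
    grid$O <- steady_oxygen(grid$O, wm$gammaW, kmat, p)
  } else {
    grid$O <- rd_step(grid$O, prod = wm$gammaW * p$O_v,
                      decay = wm$gammaW + kmat, D = p$D_O, dx = p$dx,
                      dt = dt, safety = p$substep_safety)
  }
  invisible(grid)
}

#' Write a field snapshot
#'
#' Writes a concentration field both as a CSV matrix (lossless) and as an
#' 8-bit grayscale PNG preview scaled to the field's range.
#'
#' @param F field matrix.
#' @param path_base output path without extension.
#' @return the two paths, invisibly.
#' @export
write_field_snapshot <- function(F, path_base) {
  csv <- paste0(path_base, ".csv")
  utils::write.table(F, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  rng <- range(F)
  img <- if (diff(rng) > 0) (F - rng[1]) / diff(rng) else F * 0
  png_path <- paste0(path_base, ".png")
  png::writePNG(t(img)[nrow(F):1, , drop = FALSE], png_path)
  invisible(c(csv, png_path))
}
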
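#' Solve Poiseuille flow on a vessel network
#'
#' Imposes the entry pressure at the network's entry node and the boundary
#' pressure at every vessel endpoint touching the domain border, then
#' solves mass conservation (Kirchhoff) at all interior nodes with
#' segment conductances \eqn{g = \pi R^4 / (8 \eta L)}. Radii are in um
#' and lengths in mm; only the two pressures are physically anchored, so
#' flow, conductance and shear are in arbitrary but mutually consistent
#' units.
#'
#' @param net a [vessel_network()] with an entry node set (or at least one
#'   boundary node).
#' @param entry_pressure pressure at the entry node, kPa.
#' @param boundary_pressure pressure at domain-border endpoints, kPa.
#' @param viscosity blood viscosity (arbitrary units, constant).
#' @return an object of class `vt_flow`: `nodes` (x, y, pressure),
#'   `segments` (flow, shear stress, conductance, radius) and the imposed
#'   pressures.
#' @export
solve_flow <- function(net, entry_pressure = 13, boundary_pressure = 2,
                       viscosity = 1) {
  ns <- net$n_seg
  if (ns == 0L) stop("empty vessel network", call. = FALSE)
  s <- seq_len(ns)
  n <- net$n
  node_id <- function(x, y) x + (n + 1L) * y + 1L
  a <- node_id(net$x1[s], net$y1[s])
  b <- node_id(net$x2[s], net$y2[s])
  ids <- sort(unique(c(a, b)))
  idx <- match(c(a, b), ids)
  ai <- idx[s]; bi <- idx[ns + s]
  nx <- (ids - 1L) %% (n + 1L)
  ny <- (ids - 1L) %/% (n + 1L)
  L <- ifelse(net$x1[s] != net$x2[s] & net$y1[s] != net$y2[s],
              net$dx * sqrt(2), net$dx)
  g <- pi * net$radius[s]^4 / (8 * viscosity * L)
  ## Dirichlet set: boundary endpoints, then the entry node (takes
  ## precedence if it sits on the border)
  fixed_p <- rep(NA_real_, length(ids))
  fixed_p[nx == 0L | nx == n | ny == 0L | ny == n] <- boundary_pressure
  if (!is.null(net$entry)) {
    e <- match(node_id(net$entry[1], net$entry[2]), ids)
    if (is.na(e)) stop("entry node is not part of the network", call. = FALSE)
    fixed_p[e] <- entry_pressure
  }
  if (!any(!is.na(fixed_p)))
    stop("no pressure boundary conditions: set an entry node or route a ",
         "vessel to the domain border", call. = FALSE)
  ## every connected component must contain a Dirichlet node
  comp <- components_of(length(ids), ai, bi)
  bad <- setdiff(unique(comp), unique(comp[!is.na(fixed_p)]))
  if (length(bad))
    stop(sprintf(
      "singular flow system: %d network component(s) (e.g. around node (%d, %d)) contain no pressure boundary node",
      length(bad), nx[match(bad[1], comp)], ny[match(bad[1], comp)]),
      call. = FALSE)
  free <- which(is.na(fixed_p))
  pr <- fixed_p
  if (length(free)) {
    fmap <- match(seq_along(ids), free)       # node -> unknown index
    ## weighted graph Laplacian restricted to the free nodes
    ii <- c(ai, bi); jj <- c(bi, ai); gg <- c(g, g)
    keep <- !is.na(fmap[ii])
    ii <- ii[keep]; jj <- jj[keep]; gg <- gg[keep]
    diagA <- Matrix::sparseMatrix(i = fmap[ii], j = fmap[ii], x = gg,
                                  dims = c(length(free), length(free)))
    off <- !is.na(fmap[jj])
    A <- diagA - Matrix::sparseMatrix(i = fmap[ii[off]], j = fmap[jj[off]],
                                      x = gg[off],
                                      dims = c(length(free), length(free)))
    rhs_idx <- which(!off)
    bvec <- numeric(length(free))
    if (length(rhs_idx)) {
      contrib <- rowsum(gg[rhs_idx] * fixed_p[jj[rhs_idx]],
                        fmap[ii[rhs_idx]])
      bvec[as.integer(rownames(contrib))] <- contrib
    }
    pr[free] <- as.numeric(Matrix::solve(A, bvec))
  }
  flow <- g * (pr[ai] - pr[bi])
  shear <- 4 * viscosity * abs(flow) / (pi * net$radius[s]^3)
  structure(list(
    nodes = data.frame(x = nx, y = ny, pressure = pr,
                       fixed = !is.na(fixed_p)),
    segments = data.frame(from = ai, to = bi, flow = flow, shear = shear,
                          conductance = g, radius = net$radius[s],
                          length = L),
    entry_pressure = entry_pressure, boundary_pressure = boundary_pressure,
    viscosity = viscosity), class = "vt_flow")
}

## connected components by label propagation (small graphs)
components_of <- function(n_nodes, ai, bi) {
  comp <- seq_len(n_nodes)
  repeat {
    new_ai <- pmin(comp[ai], comp[bi])
    changed <- FALSE
    for (k in seq_along(ai)) {
      m <- min(comp[ai[k]], comp[bi[k]])
      if (comp[ai[k]] != m) { comp[ai[k]] <- m; changed <- TRUE }
      if (comp[bi[k]] != m) { comp[bi[k]] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  comp
}

#' Kirchhoff residual of a flow state
#'
#' Maximum net in/outflow over the interior (non-boundary-condition)
#' nodes, relative to the maximum absolute segment flow.
#'
#' @param flow a `vt_flow` object.
#' @return a single number; at machine precision after [solve_flow()].
#' @export
kirchhoff_residual <- function(flow) {
  nn <- nrow(flow$nodes)
  net_in <- numeric(nn)
  sg <- flow$segments
  for (k in seq_len(nrow(sg))) {
    net_in[sg$from[k]] <- net_in[sg$from[k]] - sg$flow[k]
    net_in[sg$to[k]] <- net_in[sg$to[k]] + sg$flow[k]
  }
  scale <- max(abs(sg$flow), 1e-300)
  max(abs(net_in[!flow$nodes$fixed])) / scale
}

#' Adapt vessel diameters to hemodynamic equilibrium
#'
#' Iterates Poiseuille flow solves with a Pries-style radius update: each
#' non-fixed segment responds to a wall-shear-stress stimulus
#' \eqn{\log_{10}(\tau + \tau_{ref})}, a metabolic stimulus
#' \eqn{k_{met}\log_{10}(Q_{ref}/|Q| + 1)} favouring poorly perfused
#' segments, and a constant shrinking tendency \eqn{-k_{shrink}}, applied
#' as an explicit Euler step on the log-radius. Radii are clamped to
#' `[R_min, R_max]`; segments flagged `fixed` (the reference vessel) keep
#' their radius, which anchors the network. Iteration stops when the
#' largest relative radius change falls below `adapt_tol`. The procedure
#' is deterministic.
#'
#' @param net a [vessel_network()] (radii updated in place).
#' @param params a [model_params()] object (adaptation constants,
#'   pressures and viscosity).
#' @param max_iter iteration cap (default `params$adapt_max_iter`); on
#'   non-convergence the current state is returned with a warning.
#' @return the final `vt_flow`, invisibly (the adapted radii live in
#'   `net`).
#' @export
adapt_diameters <- function(net, params = model_params(),
                            max_iter = params$adapt_max_iter) {
  s <- seq_len(net$n_seg)
  free <- !net$fixed[s]
  fl <- NULL
  for (it in seq_len(max_iter)) {
    fl <- solve_flow(net, params$entry_pressure, params$boundary_pressure,
                     params$viscosity)
    if (!any(free)) return(invisible(fl))
    tau <- fl$segments$shear[free]
    q <- abs(fl$segments$flow[free])
    stim <- log10(tau + params$adapt_tau_ref) +
      params$adapt_k_met * log10(params$adapt_Q_ref / pmax(q, 1e-12) + 1) -
      params$adapt_k_shrink
    r_old <- net$radius[s][free]
    r_new <- pmin(params$R_max,
                  pmax(params$R_min, r_old * exp(params$adapt_step * stim)))
    net$radius[which(free)] <- r_new
    if (max(abs(r_new - r_old) / r_old) < params$adapt_tol)
      return(invisible(solve_flow(net, params$entry_pressure,
                                  params$boundary_pressure,
                                  params$viscosity)))
  }
  warning("diameter adaptation did not converge within ", max_iter,
          " iterations; returning the current state")
  invisible(fl)
}

#' Export a flow state as CSV
#'
#' Writes two CSV files: `<base>_nodes.csv` (node coordinates and
#' pressures) and `<base>_segments.csv` (flow, shear, radius per segment).
#'
#' @param flow a `vt_flow`.
#' @param path_base output path without suffix.
#' @return the two paths, invisibly.
#' @export
export_flow_csv <- function(flow, path_base) {
  np <- paste0(path_base, "_nodes.csv")
  sp <- paste0(path_base, "_segments.csv")
  utils::write.csv(flow$nodes, np, row.names = FALSE)
  utils::write.csv(flow$segments, sp, row.names = FALSE)
  invisible(c(np, sp))
}
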
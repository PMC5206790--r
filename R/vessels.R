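#' Create an empty vessel network
#'
#' The network is a graph of segments living on the edges and diagonals of
#' the grid elements: nodes are lattice corners with integer coordinates
#' in `0..n`, an edge segment joins two adjacent corners (length `dx`), a
#' diagonal segment joins two opposite corners of one element (length
#' `dx * sqrt(2)`). Segments carry a radius (um), a kind (pre-existing or
#' neovessel) and a perfusion flag; only perfused segments deliver oxygen,
#' while all segments consume VEGF.
#'
#' @param n lattice side (elements).
#' @param dx element size, mm.
#' @return an environment of class `vessel_network`.
#' @export
vessel_network <- function(n, dx = 0.02) {
  net <- new.env(parent = emptyenv())
  net$n <- as.integer(n); net$dx <- dx
  net$n_seg <- 0L; net$cap <- 256L
  net$x1 <- net$y1 <- net$x2 <- net$y2 <- integer(256L)
  net$radius <- numeric(256L)
  net$kind <- integer(256L)        # 0 pre-existing, 1 neovessel
  net$perfused <- logical(256L)
  net$fixed <- logical(256L)       # reference-vessel segments (fixed radius)
  net$sprout_id <- integer(256L)   # 0 for non-sprout segments
  net$entry <- NULL                # entry node c(x, y)
  ## per-node structure id: 0 none, -1 perfused network, s > 0 sprout s
  net$node_struct <- matrix(0L, n + 1L, n + 1L)
  net$keys <- new.env(parent = emptyenv(), hash = TRUE)
  class(net) <- c("vessel_network", "environment")
  net
}

#' @export
print.vessel_network <- function(x, ...) {
  s <- seq_len(x$n_seg)
  cat(sprintf(
    "<vessel_network> %d segments on a %d x %d lattice (%d pre-existing, %d neo; %d perfused)\n",
    x$n_seg, x$n, x$n, sum(x$kind[s] == 0L), sum(x$kind[s] == 1L),
    sum(x$perfused[s])))
  invisible(x)
}

seg_key <- function(x1, y1, x2, y2) {
  if (x1 > x2 || (x1 == x2 && y1 > y2)) {
    tmp <- x1; x1 <- x2; x2 <- tmp
    tmp <- y1; y1 <- y2; y2 <- tmp
  }
  paste(x1, y1, x2, y2, sep = "_")
}

## append one segment; returns its index, or 0L if degenerate/duplicate
net_add_segment <- function(net, x1, y1, x2, y2, radius, kind = 0L,
                            perfused = kind == 0L, fixed = FALSE,
                            sprout_id = 0L) {
  n <- net$n
  if (min(x1, y1, x2, y2) < 0 || max(x1, y1, x2, y2) > n)
    stop("segment endpoints must lie on the node lattice 0..n", call. = FALSE)
  if (abs(x1 - x2) > 1L || abs(y1 - y2) > 1L || (x1 == x2 && y1 == y2))
    stop("segments must join adjacent or diagonal lattice nodes",
         call. = FALSE)
  key <- seg_key(x1, y1, x2, y2)
  if (!is.null(net$keys[[key]])) return(0L)
  k <- net$n_seg + 1L
  if (k > net$cap) {
    grow <- function(v) { length(v) <- 2L * net$cap; v }
    net$x1 <- grow(net$x1); net$y1 <- grow(net$y1)
    net$x2 <- grow(net$x2); net$y2 <- grow(net$y2)
    net$radius <- grow(net$radius); net$kind <- grow(net$kind)
    net$perfused <- grow(net$perfused); net$fixed <- grow(net$fixed)
    net$sprout_id <- grow(net$sprout_id)
    net$cap <- 2L * net$cap
  }
  net$x1[k] <- as.integer(x1); net$y1[k] <- as.integer(y1)
  net$x2[k] <- as.integer(x2); net$y2[k] <- as.integer(y2)
  net$radius[k] <- radius; net$kind[k] <- as.integer(kind)
  net$perfused[k] <- isTRUE(perfused); net$fixed[k] <- isTRUE(fixed)
  net$sprout_id[k] <- as.integer(sprout_id)
  net$n_seg <- k
  net$keys[[key]] <- k
  mark <- if (isTRUE(perfused)) -1L else as.integer(sprout_id)
  for (nd in list(c(x1, y1), c(x2, y2))) {
    cur <- net$node_struct[nd[1] + 1L, nd[2] + 1L]
    if (mark == -1L || cur == 0L)
      net$node_struct[nd[1] + 1L, nd[2] + 1L] <- mark
  }
  k
}

#' Segment table of a vessel network
#'
#' @param net a [vessel_network()].
#' @return a data frame with one row per segment: endpoints (node
#'   coordinates), `radius` (um), `kind`, `perfused`, `fixed`,
#'   `sprout_id` and `length_mm`.
#' @export
net_segments <- function(net) {
  s <- seq_len(net$n_seg)
  diag <- net$x1[s] != net$x2[s] & net$y1[s] != net$y2[s]
  data.frame(x1 = net$x1[s], y1 = net$y1[s], x2 = net$x2[s], y2 = net$y2[s],
             radius = net$radius[s],
             kind = c("pre", "neo")[net$kind[s] + 1L],
             perfused = net$perfused[s], fixed = net$fixed[s],
             sprout_id = net$sprout_id[s],
             length_mm = ifelse(diag, net$dx * sqrt(2), net$dx))
}

## per-segment element incidences: each edge segment contributes half its
## length to the (up to two) elements it borders; a diagonal contributes
## its full length to the single element containing it.
seg_contrib <- function(net) {
  s <- seq_len(net$n_seg)
  if (!length(s))
    return(list(seg = integer(0), elem = integer(0), units = numeric(0)))
  x1 <- net$x1[s]; y1 <- net$y1[s]; x2 <- net$x2[s]; y2 <- net$y2[s]
  n <- net$n
  seg <- elem_i <- elem_j <- integer(0); units <- numeric(0)
  add <- function(sg, i, j, u) {
    ok <- i >= 1L & i <= n & j >= 1L & j <= n
    seg <<- c(seg, sg[ok]); elem_i <<- c(elem_i, i[ok])
    elem_j <<- c(elem_j, j[ok]); units <<- c(units, rep(u, sum(ok)))
  }
  h <- which(y1 == y2 & x1 != x2)   # horizontal edge
  if (length(h)) {
    i <- pmin(x1[h], x2[h]) + 1L
    add(h, i, y1[h], 0.5)           # element below (j = y)
    add(h, i, y1[h] + 1L, 0.5)      # element above
  }
  v <- which(x1 == x2 & y1 != y2)   # vertical edge
  if (length(v)) {
    j <- pmin(y1[v], y2[v]) + 1L
    add(v, x1[v], j, 0.5)           # element left (i = x)
    add(v, x1[v] + 1L, j, 0.5)      # element right
  }
  d <- which(x1 != x2 & y1 != y2)   # diagonal
  if (length(d)) add(d, pmax(x1[d], x2[d]), pmax(y1[d], y2[d]), sqrt(2))
  list(seg = seg, elem = (elem_j - 1L) * n + elem_i, units = units)
}

## accumulate per-element sums into an n x n matrix
acc_matrix <- function(idx, val, n) {
  M <- matrix(0, n, n)
  if (length(idx)) {
    sums <- rowsum(val, idx)
    M[as.integer(rownames(sums))] <- sums
  }
  M
}

#' Vessel weight of a grid element
#'
#' The per-element vessel weight sums the lengths of the segments lying on
#' the element's edges (each halved, since an edge is shared by two
#' elements) and diagonals, plus the element's capillary density `E`:
#' \deqn{W_{ij} = \sum_{v \in (i,j)} (L_b/2 + L_d) + E_{ij}.}
#' With `units = "mm"` segment lengths are in millimetres (`L_b = dx`,
#' `L_d = dx\sqrt2`), reproducing the published formula verbatim. With
#' `units = "elements"` lengths are expressed in units of `dx` (an edge
#' contributes 1/2, a diagonal \eqn{\sqrt2}), the scale on which one
#' vessel edge is commensurate with the baseline capillary density
#' `E_0 = 1`; the reaction--diffusion coupling uses this scale.
#'
#' @param net a [vessel_network()].
#' @param i,j element coordinates (may be vectors of equal length).
#' @param E capillary density of the element(s) (scalar or vector).
#' @param units `"mm"` or `"elements"`.
#' @return numeric vector of weights.
#' @export
vessel_weight <- function(net, i, j, E = 1, units = c("mm", "elements")) {
  units <- match.arg(units)
  ctb <- seg_contrib(net)
  lin <- (j - 1L) * net$n + i
  scale <- if (units == "mm") net$dx else 1
  w <- vapply(lin, function(e) sum(ctb$units[ctb$elem == e]) * scale,
              numeric(1))
  w + E
}

## the three per-element weight matrices the field solver needs:
##  - W_vegf: all segments (element units) [+ E if configured]
##  - gammaW: gamma_eff * (E + sum over PERFUSED segments of (R/R_min) u)
##  - n_mask: indicator of elements carrying a segment of an ACTIVE sprout
weight_matrices <- function(net, E, params, active_ids = integer(0)) {
  n <- nrow(E)
  gamma_eff <- oxy_rates(params)$gamma
  if (is.null(net) || net$n_seg == 0L) {
    W_all <- matrix(0, n, n)
    return(list(
      W_vegf = if (params$vegf_weight_includes_E) E else W_all,
      gammaW = gamma_eff * E,
      n_mask = matrix(0, n, n)))
  }
  ctb <- seg_contrib(net)
  sw <- params$seg_weight_scale
  W_all <- acc_matrix(ctb$elem, ctb$units * sw, n)
  perf <- net$perfused[ctb$seg]
  gW <- acc_matrix(ctb$elem[perf],
                   sw * ctb$units[perf] *
                     net$radius[ctb$seg[perf]] / params$R_min,
                   n)
  act <- net$sprout_id[ctb$seg] %in% active_ids & net$sprout_id[ctb$seg] > 0L
  n_mask <- acc_matrix(ctb$elem[act], rep(1, sum(act)), n)
  n_mask[n_mask > 0] <- 1
  list(W_vegf = W_all + if (params$vegf_weight_includes_E) E else 0,
       gammaW = gamma_eff * (E + gW),
       n_mask = n_mask)
}

#' Capillary degradation by tumour proteases
#'
#' Elements where the tumour-protease concentration exceeds `p_degrade`
#' have their capillary density set to zero. Degradation is local and
#' irreversible.
#'
#' @param E capillary density matrix, or a `sim_grid` (mutated in place).
#' @param p protease concentration matrix (defaults to the grid's).
#' @param params a [model_params()] object.
#' @return the updated `E` matrix (or the grid, invisibly).
#' @export
degrade_capillaries <- function(E, p = NULL, params = model_params()) {
  if (inherits(E, "sim_grid")) {
    grid <- E
    grid$E[grid$p > grid$params$p_degrade] <- 0
    return(invisible(grid))
  }
  stopifnot(all(p >= 0))
  E[p > params$p_degrade] <- 0
  E
}

#' Matrix degradation by sprout proteases
#'
#' Extracellular-matrix integrity decreases at a rate proportional to the
#' local sprout-protease concentration, floored at zero.
#'
#' @param integrity integrity matrix in `[0, 1]`, or a `sim_grid`.
#' @param m sprout-protease concentration matrix.
#' @param params a [model_params()] object.
#' @param dt time increment, h.
#' @return updated integrity matrix (or the grid, invisibly).
#' @export
degrade_matrix <- function(integrity, m = NULL, params = model_params(),
                           dt = 1) {
  if (inherits(integrity, "sim_grid")) {
    grid <- integrity
    grid$integrity <- pmax(grid$integrity -
                             grid$params$matrix_degrade_rate * grid$m * dt, 0)
    return(invisible(grid))
  }
  stopifnot(all(m >= 0))
  pmax(integrity - params$matrix_degrade_rate * m * dt, 0)
}

## VEGF seen by a node: mean over its (up to 4) adjacent elements
node_field_value <- function(F, nx, ny) {
  n <- nrow(F)
  val <- numeric(length(nx)); cnt <- numeric(length(nx))
  for (off in list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
    i <- nx + off[1]; j <- ny + off[2]
    ok <- i >= 1L & i <= n & j >= 1L & j <= n
    val[ok] <- val[ok] + F[cbind(i[ok], j[ok])]
    cnt[ok] <- cnt[ok] + 1
  }
  val / pmax(cnt, 1)
}

#' Initiate angiogenic sprouts
#'
#' Lattice nodes lying on perfused vessels where the local VEGF
#' concentration exceeds the sprouting threshold may spawn a sprout tip.
#' Initiation is stochastic with a rate increasing linearly in VEGF excess
#' (equal to `sprout_init_rate` per hour at twice the threshold), at most
#' one sprout per node, and new origins keep a minimum Chebyshev spacing
#' from all active sprout origins.
#'
#' @param grid a `sim_grid` with an attached vessel network.
#' @param dt time increment, h.
#' @return indices of the newly created sprouts, invisibly. Uses the R RNG.
#' @export
initiate_sprouts <- function(grid, dt = 1) {
  net <- grid$network
  p <- grid$params
  if (is.null(net) || net$n_seg == 0L) return(invisible(integer(0)))
  s <- which(net$perfused[seq_len(net$n_seg)])
  if (!length(s)) return(invisible(integer(0)))
  nx <- c(net$x1[s], net$x2[s]); ny <- c(net$y1[s], net$y2[s])
  keep <- !duplicated(nx + (net$n + 1L) * ny)
  nodes <- cbind(nx[keep], ny[keep])
  V_node <- node_field_value(grid$V, nodes[, 1], nodes[, 2])
  elig <- which(V_node > p$V_sprout)
  if (!length(elig)) return(invisible(integer(0)))
  origins <- do.call(rbind, lapply(grid$sprouts, function(sp)
    if (sp$active) sp$origin else NULL))
  new_ids <- integer(0)
  for (r in sample(elig)) {
    nd <- nodes[r, ]
    if (!is.null(origins) && nrow(origins) &&
        any(pmax(abs(origins[, 1] - nd[1]),
                 abs(origins[, 2] - nd[2])) < p$sprout_spacing)) next
    rate <- p$sprout_init_rate * (V_node[r] / p$V_sprout - 1)
    if (stats::runif(1) < 1 - exp(-rate * dt)) {
      id <- length(grid$sprouts) + 1L
      grid$sprouts[[id]] <- list(id = id, origin = nd, tip = nd,
                                 prev = c(0L, 0L), age = 0, active = TRUE,
                                 perfused = FALSE, segs = integer(0),
                                 parent = 0L)
      origins <- rbind(origins, nd)
      new_ids <- c(new_ids, id)
    }
  }
  invisible(new_ids)
}

## ids of currently active sprouts
active_sprout_ids <- function(grid)
  which(vapply(grid$sprouts, function(sp) sp$active, logical(1)))

## mark a sprout (and its ancestors) perfused after anastomosis
perfuse_sprout <- function(grid, id) {
  net <- grid$network
  while (id > 0L) {
    sp <- grid$sprouts[[id]]
    if (length(sp$segs)) {
      net$perfused[sp$segs] <- TRUE
      for (k in sp$segs) {
        net$node_struct[net$x1[k] + 1L, net$y1[k] + 1L] <- -1L
        net$node_struct[net$x2[k] + 1L, net$y2[k] + 1L] <- -1L
      }
    }
    sp$perfused <- TRUE
    sp$active <- FALSE
    grid$sprouts[[id]] <- sp
    id <- sp$parent
    if (id > 0L && isTRUE(grid$sprouts[[id]]$perfused)) break
  }
  invisible(grid)
}

#' Migrate angiogenic sprout tips
#'
#' Each active tip takes at most one lattice step per call (stochastic,
#' probability `sprout_move_prob` per hour), choosing among the eight
#' edge/diagonal directions with probability weighted by the local VEGF
#' gradient (chemotaxis) and by degraded-matrix preference. The trailing
#' segment is laid down as an unperfused neovessel. A tip reaching a node
#' of the perfused network anastomoses: the whole sprout path becomes
#' perfused and the tip is retired. Tips may branch with probability
#' `sprout_branch_prob` per step where VEGF exceeds twice the sprouting
#' threshold. Tips never step through elements holding necrotic debris.
#'
#' @param grid a `sim_grid` with an attached vessel network.
#' @param dt time increment, h.
#' @return the grid, invisibly. Uses the R RNG.
#' @export
migrate_sprout_tips <- function(grid, dt = 1) {
  act <- active_sprout_ids(grid)
  if (!length(act)) return(invisible(grid))
  net <- grid$network
  p <- grid$params
  n <- grid$n
  dirs <- cbind(dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
                dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))
  for (id in sample(act)) {
    sp <- grid$sprouts[[id]]
    if (!sp$active) next
    sp$age <- sp$age + dt
    grid$sprouts[[id]] <- sp
    if (stats::runif(1) >= p$sprout_move_prob * dt) next
    tx <- sp$tip[1]; ty <- sp$tip[2]
    cand_x <- tx + dirs[, 1]; cand_y <- ty + dirs[, 2]
    ok <- cand_x >= 0L & cand_x <= n & cand_y >= 0L & cand_y <= n &
      !(cand_x == tx - sp$prev[1] & cand_y == ty - sp$prev[2])
    ## exclude steps whose segment would cross necrotic debris
    for (d in which(ok)) {
      ei <- pmax(tx, cand_x[d]); ej <- pmax(ty, cand_y[d])
      if (dirs[d, 1] != 0L && dirs[d, 2] != 0L) {       # diagonal
        if (ei >= 1L && ei <= n && ej >= 1L && ej <= n &&
            grid$occ[ei, ej] == STATE_N) ok[d] <- FALSE
      } else {                                           # edge: 2 elements
        if (dirs[d, 2] == 0L) { is <- ei; js <- c(ej, ej + 1L) }
        else { is <- c(ei, ei + 1L); js <- ej }
        for (ii in is) for (jj in js)
          if (ii >= 1L && ii <= n && jj >= 1L && jj <= n &&
              grid$occ[ii, jj] == STATE_N) ok[d] <- FALSE
      }
      ## do not re-lay an existing segment
      if (ok[d] &&
          !is.null(net$keys[[seg_key(tx, ty, cand_x[d], cand_y[d])]]))
        ok[d] <- FALSE
    }
    if (!any(ok)) next
    V0 <- node_field_value(grid$V, tx, ty)
    Vc <- node_field_value(grid$V, cand_x[ok], cand_y[ok])
    Ic <- node_field_value(grid$integrity, cand_x[ok], cand_y[ok])
    w <- exp(pmin(50, p$chemotaxis_kappa * (Vc - V0))) * (2 - Ic)
    pick <- which(ok)[sample_one_weighted(w)]
    nx <- cand_x[pick]; ny <- cand_y[pick]
    k <- net_add_segment(net, tx, ty, nx, ny, radius = p$R_neo, kind = 1L,
                         perfused = FALSE, sprout_id = id)
    if (k == 0L) next
    sp <- grid$sprouts[[id]]
    sp$segs <- c(sp$segs, k)
    sp$prev <- c(nx - tx, ny - ty)
    sp$tip <- c(nx, ny)
    grid$sprouts[[id]] <- sp
    hit <- net$node_struct[nx + 1L, ny + 1L]
    if (hit == -1L) {                      # reached the perfused network
      perfuse_sprout(grid, id)
      next
    }
    if (hit > 0L && hit != id) {
      ## fused with another sprout: every sprout is rooted on the
      ## perfused network, so the joined arc forms a perfused loop
      perfuse_sprout(grid, id)
      perfuse_sprout(grid, hit)
      next
    }
    net$node_struct[nx + 1L, ny + 1L] <- id
    ## branching where VEGF is high
    if (node_field_value(grid$V, nx, ny) > 2 * p$V_sprout &&
        stats::runif(1) < p$sprout_branch_prob) {
      bid <- length(grid$sprouts) + 1L
      grid$sprouts[[bid]] <- list(id = bid, origin = c(nx, ny),
                                  tip = c(nx, ny), prev = c(0L, 0L),
                                  age = 0, active = TRUE, perfused = FALSE,
                                  segs = integer(0), parent = id)
    }
  }
  invisible(grid)
}

sample_one_weighted <- function(w) {
  if (length(w) == 1L) return(1L)
  sample.int(length(w), 1L, prob = w)
}

#' Export a vessel network as a plain-text edge list
#'
#' @param net a [vessel_network()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_network_csv <- function(net, path) {
  df <- net_segments(net)
  attr_line <- sprintf("# n=%d dx=%g entry=%s", net$n, net$dx,
                       if (is.null(net$entry)) "NA"
                       else paste(net$entry, collapse = ","))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a vessel-overlay mask image
#'
#' Renders the elements carrying vessel segments as a grayscale PNG mask
#' (pre-existing vessels brightest, perfused neovessels mid-grey, active
#' sprouts dim), for overlaying on tumour snapshots.
#'
#' @param net a [vessel_network()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
network_overlay_png <- function(net, path) {
  n <- net$n
  ctb <- seg_contrib(net)
  img <- matrix(0, n, n)
  pre <- net$kind[ctb$seg] == 0L
  perf <- net$perfused[ctb$seg]
  img[ctb$elem[!pre & !perf]] <- 0.4
  img[ctb$elem[!pre & perf]] <- 0.7
  img[ctb$elem[pre]] <- 1
  png::writePNG(t(img)[n:1, , drop = FALSE], path)
  invisible(path)
}

#' Import a vessel network from a plain-text edge list
#'
#' @param path CSV path written by [export_network_csv()].
#' @return a [vessel_network()].
#' @export
import_network_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("n=(\\d+) dx=([0-9.eE+-]+) entry=([0-9,]+|NA)",
                               hdr))[[1]]
  if (length(m) != 4L) stop("malformed network header", call. = FALSE)
  df <- utils::read.csv(path, skip = 1L)
  net <- vessel_network(as.integer(m[2]), as.numeric(m[3]))
  for (r in seq_len(nrow(df)))
    net_add_segment(net, df$x1[r], df$y1[r], df$x2[r], df$y2[r],
                    radius = df$radius[r],
                    kind = if (df$kind[r] == "neo") 1L else 0L,
                    perfused = df$perfused[r], fixed = df$fixed[r],
                    sprout_id = df$sprout_id[r])
  if (m[4] != "NA")
    net$entry <- as.integer(strsplit(m[4], ",")[[1]])
  net
}
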
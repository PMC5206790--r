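#' Read a grayscale image
#'
#' Reads a PNG (or, if the `tiff` package is installed, a TIFF) image and
#' returns it as a numeric matrix in `[0, 1]`, averaging channels if the
#' file is not already grayscale.
#'
#' @param path image path.
#' @return numeric matrix (rows = image rows).
#' @export
read_grayscale <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3])],
                                           c(1, 2), mean)
  img
}

#' Area-averaging image resize
#'
#' Resizes a matrix to `nr x nc` by exact area averaging (each output
#' pixel is the overlap-weighted mean of the input pixels it covers),
#' preserving density information when downsampling to the computation
#' grid.
#'
#' @param img numeric matrix.
#' @param nr,nc output dimensions.
#' @return resized matrix.
#' @export
resize_area <- function(img, nr, nc = nr) {
  M <- function(n_out, n_in) {
    ## overlap of output interval [i-1, i) * (n_in/n_out) with input cells
    W <- matrix(0, n_out, n_in)
    r <- n_in / n_out
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * r; hi <- i * r
      cells <- floor(lo):min(ceiling(hi) - 1, n_in - 1)
      w <- pmin(hi, cells + 1) - pmax(lo, cells)
      W[i, cells + 1] <- w / r
    }
    W
  }
  M(nr, nrow(img)) %*% img %*% t(M(nc, ncol(img)))
}

#' Build the initial virtual tumour from a fluorescence-style image
#'
#' Reproduces the image-to-automaton procedure: (1) three ascending
#' intensity thresholds applied to the original image give three nested
#' region masks (low/medium/high cell density); (2) the masks are resized
#' to the computation grid by area averaging; (3) each region is filled
#' stochastically -- grey-level Gaussian noise is added and re-thresholded
#' at the region's fill quantile, so the expected occupancy equals the
#' configured per-region fill rate (`fill_low`, `fill_med`, `fill_high`);
#' (4) the three occupancy images are summed to give the initial tumour,
#' and only its bulk (largest connected component after a small dilation)
#' is retained, dropping scattered cells. Every occupied element receives
#' a proliferative cell when a grid is supplied.
#'
#' @param img grayscale matrix in `[0, 1]` (any size).
#' @param thresholds three strictly ascending intensity thresholds.
#' @param params a [model_params()] object.
#' @param grid optional `sim_grid`; if given, cells are placed on it with
#'   desynchronized cycle positions.
#' @return an object of class `vt_density_map`: `labels` (0 background,
#'   1 low, 2 medium, 3 high), `occupancy` (logical matrix), `n_cells`.
#'   Uses the R RNG.
#' @export
tumour_from_image <- function(img, thresholds, params = model_params(),
                              grid = NULL) {
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0))
    stop("thresholds must be three strictly ascending values",
         call. = FALSE)
  n <- as.integer(params$grid_n)
  b1 <- resize_area((img >= thresholds[1]) * 1, n) > 0.5
  b2 <- resize_area((img >= thresholds[2]) * 1, n) > 0.5 & b1
  b3 <- resize_area((img >= thresholds[3]) * 1, n) > 0.5 & b2
  labels <- matrix(0L, n, n)
  labels[b1] <- 1L; labels[b2] <- 2L; labels[b3] <- 3L
  fills <- c(params$fill_low, params$fill_med, params$fill_high)
  Z <- matrix(stats::rnorm(n * n), n, n)   # grey-level noise field
  occupancy <- matrix(FALSE, n, n)
  for (r in 1:3) {
    region <- labels == r
    ## noise + re-threshold at the fill quantile: P(occupied) = fills[r]
    occupancy[region] <- Z[region] > stats::qnorm(1 - fills[r])
  }
  if (!any(occupancy)) {
    warning("empty tumour after thresholding")
  } else {
    occupancy <- keep_bulk(occupancy, params$lcc_dilate)
  }
  if (!is.null(grid)) {
    stopifnot(grid$n == n)
    populate_cells(grid, occupancy)
  }
  structure(list(labels = labels, occupancy = occupancy,
                 n_cells = sum(occupancy), thresholds = thresholds,
                 fills = fills),
            class = "vt_density_map")
}

## largest connected component after dilation (bulk-of-tumour selection)
keep_bulk <- function(occupancy, dilate_radius = 2L) {
  brush <- EBImage::makeBrush(2L * dilate_radius + 1L, shape = "disc")
  dil <- EBImage::dilate(occupancy * 1, brush)
  lab <- EBImage::bwlabel(dil)
  sizes <- tabulate(lab[occupancy])          # occupied cells per component
  occupancy & (lab == which.max(sizes))
}

## place proliferative cells with uniformly random cycle positions
populate_cells <- function(grid, occupancy) {
  idx <- which(occupancy)
  if (!length(idx)) return(invisible(grid))
  p <- grid$params
  mu <- p$mu0
  fixed <- c(p$S_dur, p$G2_dur, p$M_dur)
  g1 <- mu - sum(fixed)
  u <- stats::runif(length(idx), 0, mu)
  bounds <- cumsum(c(g1, fixed))
  phase <- findInterval(u, bounds) + 1L      # 1..4
  clock <- u - c(0, bounds)[phase]
  grid$occ[idx] <- STATE_P
  grid$mu[idx] <- mu
  grid$g1[idx] <- g1
  grid$phase[idx] <- phase
  grid$clock[idx] <- clock
  invisible(grid)
}

#' Rasterize vessel polylines onto the lattice
#'
#' Transposes segmented vessel centrelines into the automaton: each
#' polyline (vertices in node units, `0..n`) is walked with 8-connected
#' steps, laying pre-existing perfused segments on the traversed edges
#' and diagonals. All vessels get the default 30 um diameter except the
#' designated reference vessel (80 um), whose segments are flagged fixed
#' for the adaptation step. Parallel venule/arteriole pairs are *not*
#' merged -- representing only one of the two is the caller's modelling
#' choice.
#'
#' @param polylines list of two-column matrices (x, y in node units).
#' @param entry entry node `c(x, y)`; defaults to the first vertex of the
#'   reference polyline. Must lie on a rasterized polyline.
#' @param reference index of the reference polyline.
#' @param params a [model_params()] object.
#' @return a [vessel_network()].
#' @export
vessels_from_polylines <- function(polylines, entry = NULL, reference = 1L,
                                   params = model_params()) {
  n <- as.integer(params$grid_n)
  net <- vessel_network(n, params$dx)
  for (k in seq_along(polylines)) {
    pl <- polylines[[k]]
    is_ref <- k == reference
    radius <- if (is_ref) 40 else 15        # um (80 / 30 um diameters)
    nodes <- rasterize_polyline(pl, n)
    for (r in seq_len(nrow(nodes) - 1L))
      net_add_segment(net, nodes[r, 1], nodes[r, 2],
                      nodes[r + 1L, 1], nodes[r + 1L, 2],
                      radius = radius, kind = 0L, perfused = TRUE,
                      fixed = is_ref)
  }
  if (is.null(entry)) entry <- round(polylines[[reference]][1, ])
  entry <- as.integer(round(entry))
  if (net$node_struct[entry[1] + 1L, entry[2] + 1L] == 0L)
    stop("entry point (", entry[1], ", ", entry[2],
         ") does not lie on any rasterized polyline", call. = FALSE)
  net$entry <- entry
  net
}

## 8-connected node chain through the polyline vertices
rasterize_polyline <- function(pl, n) {
  pl[, 1] <- pmin(pmax(pl[, 1], 0), n)
  pl[, 2] <- pmin(pmax(pl[, 2], 0), n)
  out <- NULL
  for (r in seq_len(nrow(pl) - 1L)) {
    a <- pl[r, ]; b <- pl[r + 1L, ]
    N <- max(1L, ceiling(max(abs(b - a))))
    xs <- round(seq(a[1], b[1], length.out = N + 1L))
    ys <- round(seq(a[2], b[2], length.out = N + 1L))
    keep <- c(TRUE, diff(xs) != 0 | diff(ys) != 0)
    out <- rbind(out, cbind(xs, ys)[keep, , drop = FALSE])
  }
  dedup <- c(TRUE, diff(out[, 1]) != 0 | diff(out[, 2]) != 0)
  out[dedup, , drop = FALSE]
}

#' Hemodynamic initialization of the vasculature
#'
#' Runs the flow solve and diameter adaptation on a freshly rasterized
#' network (13 kPa at the entry node, 2 kPa at the domain border by
#' default) until the steady state, returning the network that serves as
#' the initial vascular condition for tumour growth. Deterministic.
#'
#' @param net a [vessel_network()] from [vessels_from_polylines()].
#' @param params a [model_params()] object.
#' @return `net`, adapted in place, invisibly.
#' @export
build_initial_vasculature <- function(net, params = model_params()) {
  adapt_diameters(net, params)
  invisible(net)
}

#' Generate a synthetic tumour case
#'
#' Emulates the experimental inputs of the image-based initialization: a
#' granular, blob-shaped fluorescence-style tumour image with three
#' concentric intensity zones (dense core, medium annulus, dim rim) and
#' an irregular boundary, plus a handful of vessel polylines passing near
#' the blob -- a main (reference) vessel crossing the frame with an entry
#' point on the border, and secondary vessels branching off it around the
#' tumour. Fully reproducible from the seed (the global RNG state is
#' left untouched).
#'
#' @param seed integer seed.
#' @param params a [model_params()] object (frame geometry follows
#'   `grid_n * dx`).
#' @param img_px image side in pixels.
#' @param r0_mm mean blob radius, mm.
#' @param r_jitter relative radius jitter across cases.
#' @param zone_fracs radii of the high/medium/low-density zones as
#'   fractions of the blob radius.
#' @param zone_intensities image intensity of the three zones
#'   (high, medium, low).
#' @param wobble amplitude of the low-order boundary irregularity.
#' @param speckle_sd fine speckle noise SD.
#' @param blotch_px granule size of the coarse fluorescence blotches,
#'   image pixels.
#' @param blotch_sd amplitude of the coarse blotches; together with the
#'   zone intensities and thresholds this sets how patchy (hole-riddled)
#'   the initial occupancy is.
#' @return an object of class `vt_synth_case`: `image`, `polylines`
#'   (node units), `entry`, `reference`, suggested `thresholds`, `blob`
#'   geometry and the `seed`.
#' @export
generate_synthetic_case <- function(seed, params = model_params(),
                                    img_px = 400, r0_mm = 0.6,
                                    r_jitter = 0.1,
                                    zone_fracs = c(0.5, 0.8, 1),
                                    zone_intensities = c(0.9, 0.6, 0.35),
                                    wobble = 0.1, speckle_sd = 0.08,
                                    blotch_px = 16, blotch_sd = 0.2) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  n <- as.integer(params$grid_n)
  ext_mm <- n * params$dx
  cx <- ext_mm / 2 + stats::runif(1, -0.04, 0.04) * ext_mm
  cy <- ext_mm / 2 + stats::runif(1, -0.04, 0.04) * ext_mm
  r0 <- r0_mm * (1 + stats::runif(1, -r_jitter, r_jitter))
  ks <- 2:5
  amp <- wobble * stats::rnorm(length(ks)) / sqrt(ks)
  phi <- stats::runif(length(ks), 0, 2 * pi)
  xs <- (seq_len(img_px) - 0.5) * ext_mm / img_px
  X <- matrix(xs, img_px, img_px)
  Y <- matrix(xs, img_px, img_px, byrow = TRUE)
  R <- sqrt((X - cx)^2 + (Y - cy)^2)
  TH <- atan2(Y - cy, X - cx)
  wob <- matrix(1, img_px, img_px)
  for (q in seq_along(ks))
    wob <- wob + amp[q] * cos(ks[q] * TH + phi[q])
  r_eff <- R / (r0 * wob)
  img <- matrix(0.03, img_px, img_px)
  img[r_eff < zone_fracs[3]] <- zone_intensities[3]
  img[r_eff < zone_fracs[2]] <- zone_intensities[2]
  img[r_eff < zone_fracs[1]] <- zone_intensities[1]
  ## granular texture on two scales: coarse fluorescence blotches
  ## (tens of um, giving the patchy, hole-riddled day-3 appearance)
  ## plus cell-scale speckle and fine pixel noise
  nb <- ceiling(img_px / blotch_px)
  blotch <- kronecker(matrix(stats::rnorm(nb^2, 0, blotch_sd), nb, nb),
                      matrix(1, blotch_px, blotch_px))[1:img_px, 1:img_px]
  coarse <- matrix(stats::rnorm((img_px / 4)^2, 0, speckle_sd),
                   img_px / 4, img_px / 4)
  img <- img + blotch + kronecker(coarse, matrix(1, 4, 4)) +
    stats::rnorm(img_px^2, 0, speckle_sd / 2)
  img <- pmin(pmax(img, 0), 1)
  ## main (reference) vessel: crosses the frame beside the blob
  side <- sample(c(-1, 1), 1)
  x0 <- cx + side * (r0 + 0.3 + stats::runif(1, 0, 0.2))
  slope <- stats::runif(1, -0.15, 0.15)
  yy <- seq(0, ext_mm, by = 0.25)
  main <- cbind(pmin(pmax(x0 + slope * (yy - ext_mm / 2), 0), ext_mm), yy)
  polylines <- list(main)
  ## secondary vessels: branch off the main vessel, skirt the blob
  for (b in seq_len(sample(2:4, 1))) {
    start <- main[sample(4:(nrow(main) - 3L), 1), ]
    th <- stats::runif(1, 0, 2 * pi)
    d <- r0 + stats::runif(1, 0.1, 0.3)
    mid <- c(cx + d * cos(th), cy + d * sin(th))
    ## exit at the border nearest to the continuation direction
    dir <- mid - start
    dir <- dir / max(abs(dir), 1e-9)
    tmax <- min(ifelse(dir > 0, (ext_mm - mid) / pmax(dir, 1e-9),
                       mid / pmax(-dir, 1e-9)))
    end <- mid + dir * tmax
    bez <- function(t, a, b, cpt)
      outer((1 - t)^2, a) + outer(2 * t * (1 - t), cpt) + outer(t^2, b)
    polylines[[length(polylines) + 1L]] <-
      bez(seq(0, 1, length.out = 12), start, end, mid)
  }
  to_nodes <- function(pl) pl * n / ext_mm
  polylines <- lapply(polylines, to_nodes)
  entry <- round(polylines[[1]][1, ])
  structure(list(image = img, polylines = polylines,
                 entry = as.integer(entry), reference = 1L,
                 thresholds = c(0.2, 0.47, 0.75),
                 blob = list(centre_mm = c(cx, cy), r0_mm = r0,
                             area_mm2 = pi * r0^2),
                 seed = as.integer(seed)),
            class = "vt_synth_case")
}

#' @export
print.vt_synth_case <- function(x, ...) {
  cat(sprintf(
    "<vt_synth_case> seed %d: blob r = %.3f mm at (%.2f, %.2f) mm, %d vessel polylines\n",
    x$seed, x$blob$r0_mm, x$blob$centre_mm[1], x$blob$centre_mm[2],
    length(x$polylines)))
  invisible(x)
}

#' Build a ready-to-run grid from a synthetic case
#'
#' Full initialization pipeline: density thresholding of the case image
#' with cell placement, polyline rasterization, hemodynamic adaptation of
#' the vasculature, and an initial quasi-steady oxygen solve.
#'
#' @param case a [generate_synthetic_case()] object (or a list with the
#'   same fields built from real images).
#' @param params a [model_params()] object.
#' @return a `sim_grid` ready for [run_simulation()]. Uses the R RNG (for
#'   the stochastic fill step).
#' @export
initialize_grid <- function(case, params = model_params()) {
  grid <- simulation_grid(params)
  dm <- tumour_from_image(case$image, case$thresholds, params, grid = grid)
  net <- vessels_from_polylines(case$polylines, entry = case$entry,
                                reference = case$reference, params = params)
  build_initial_vasculature(net, params)
  grid$network <- net
  grid$density_map <- dm
  steady_oxygen(grid)
  grid
}

#' Save / load a machine-readable initial state
#'
#' Writes the cell table (element coordinates, state and cycle position)
#' and the vessel network as CSV so a run can be rebuilt without the
#' source images.
#'
#' @param grid a `sim_grid`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
save_state <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(grid$occ != STATE_EMPTY)
  cells <- data.frame(
    i = (idx - 1L) %% grid$n + 1L, j = (idx - 1L) %/% grid$n + 1L,
    state = c("P", "Q", "A", "N")[grid$occ[idx]],
    mu = grid$mu[idx], phase = grid$phase[idx], clock = grid$clock[idx])
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  if (!is.null(grid$network))
    export_network_csv(grid$network, file.path(dir, "network.csv"))
  invisible(dir)
}

#' @rdname save_state
#' @param params a [model_params()] object.
#' @export
load_state <- function(dir, params = model_params()) {
  grid <- simulation_grid(params)
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  code <- match(cells$state, c("P", "Q", "A", "N"))
  idx <- (cells$j - 1L) * grid$n + cells$i
  grid$occ[idx] <- code
  grid$mu[idx] <- cells$mu
  grid$g1[idx] <- cells$mu - (params$S_dur + params$G2_dur + params$M_dur)
  grid$phase[idx] <- cells$phase
  grid$clock[idx] <- cells$clock
  np <- file.path(dir, "network.csv")
  if (file.exists(np)) grid$network <- import_network_csv(np)
  steady_oxygen(grid)
  grid
}
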
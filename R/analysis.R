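#' Apparent tumour area
#'
#' The apparent area is obtained by delineating the tumour edge: the
#' living-cell occupancy mask is morphologically closed (disc, radius 2
#' elements), holes are filled, and the largest connected component is
#' measured. It is always at least the effective area (occupied elements
#' times the element area).
#'
#' @param mask logical occupancy matrix.
#' @param dx element size, mm.
#' @param close_radius closing-disc radius, elements.
#' @param largest_only measure only the largest delineated component
#'   (the default, the bulk-of-tumour convention); with `FALSE` all
#'   components are summed, which keeps apparent >= effective even when
#'   the living mass is transiently fragmented by dead regions.
#' @return apparent area, mm^2 (0 with a warning for an empty mask).
#' @export
apparent_area <- function(mask, dx = 0.02, close_radius = 2L,
                          largest_only = TRUE) {
  if (!any(mask)) {
    warning("empty occupancy mask; apparent area 0")
    return(0)
  }
  brush <- EBImage::makeBrush(2L * close_radius + 1L, shape = "disc")
  closed <- EBImage::closing(mask * 1, brush)
  filled <- EBImage::fillHull(closed)
  if (!largest_only) return(sum(filled > 0) * dx^2)
  lab <- EBImage::bwlabel(filled)
  sum(lab == which.max(tabulate(lab[lab > 0]))) * dx^2
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' Normalize growth curves by their integral
#'
#' Each curve \eqn{s_k(t)} is divided by its trapezoid integral over the
#' common day grid, \eqn{\tilde s_k(t) = s_k(t) / \int_0^{28} s_k\,dt},
#' making curves of different absolute size comparable. The integral of
#' every returned curve is 1.
#'
#' @param curves numeric matrix, one column per tumour case, rows on the
#'   common day grid.
#' @param days the day grid (defaults to `0:(nrow - 1)`).
#' @return the normalized matrix, with the day grid as attribute `days`
#'   and the original integrals as attribute `integrals`.
#' @export
normalize_curves <- function(curves, days = NULL) {
  curves <- as.matrix(curves)
  if (is.null(days)) days <- 0:(nrow(curves) - 1)
  stopifnot(length(days) == nrow(curves))
  ints <- apply(curves, 2, function(y) trapz(days, y))
  if (any(ints <= 0))
    stop("curve with non-positive integral cannot be normalized",
         call. = FALSE)
  out <- sweep(curves, 2, ints, "/")
  attr(out, "days") <- days
  attr(out, "integrals") <- ints
  out
}

#' Locate the angiogenic bottleneck
#'
#' The bottleneck is the day at which the across-case standard deviation
#' of the integral-normalized growth curves is minimal -- the point where
#' tumours of different speed converge as angiogenic regulation
#' compensates their differences. Ties break toward the earliest day.
#'
#' @param curves a matrix of (normalized) curves, one column per case;
#'   see [normalize_curves()].
#' @param days the day grid (defaults to the `days` attribute, else
#'   `0:(nrow - 1)`).
#' @return list with `day` (the argmin) and `profile` (data frame of day
#'   vs across-case SD).
#' @export
bottleneck_day <- function(curves, days = NULL) {
  curves <- as.matrix(curves)
  if (ncol(curves) < 2L)
    stop("at least two curves are needed to measure variability",
         call. = FALSE)
  if (is.null(days)) days <- attr(curves, "days")
  if (is.null(days)) days <- 0:(nrow(curves) - 1)
  sds <- apply(curves, 1, stats::sd)
  list(day = days[which.min(sds)],
       profile = data.frame(day = days, sd = sds))
}

#' Normalized intensity histogram of a tumour snapshot
#'
#' Texture readout of a fluorescence-style image: intensities of the
#' tumour pixels are min--max normalized to `[0, 1]` and binned; the
#' histogram is normalized by the number of tumour pixels so its integral
#' is 1. Only pixels inside the tumour mask count.
#'
#' @param img intensity matrix.
#' @param mask logical tumour mask (non-empty).
#' @param bins number of uniform bins on `[0, 1]`.
#' @return data frame with `mid` (bin centre) and `density`;
#'   `sum(density) / bins == 1`.
#' @export
intensity_histogram <- function(img, mask, bins = 64L) {
  stopifnot(any(mask))
  v <- img[mask]
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("constant intensity over the tumour mask; degenerate ",
            "single-bin histogram")
    v <- rep(0, length(v))
  } else {
    v <- (v - rng[1]) / diff(rng)
  }
  bin <- pmin(bins, floor(v * bins) + 1L)
  counts <- tabulate(bin, nbins = bins)
  data.frame(mid = (seq_len(bins) - 0.5) / bins,
             density = counts / length(v) * bins)
}

#' Proliferative-fraction series over a batch
#'
#' Per-day fraction of living tumour cells that are proliferating,
#' \eqn{n_P / (n_P + n_Q)}, per case, with the across-case mean, SD and
#' standard error of the mean. Days on which a case has no living cells
#' are reported as missing for that case.
#'
#' @param records list of growth records (see [run_simulation()]).
#' @return data frame: `day`, `mean`, `sd`, `sem`, `n_cases`.
#' @export
pq_fraction_series <- function(records) {
  stopifnot(length(records) >= 1L)
  days <- records[[1]]$day
  fr <- vapply(records, function(r) {
    stopifnot(identical(r$day, days))
    living <- r$n_P + r$n_Q
    ifelse(living > 0, r$n_P / living, NA_real_)
  }, numeric(length(days)))
  fr <- matrix(fr, nrow = length(days))
  n_ok <- rowSums(!is.na(fr))
  sdv <- apply(fr, 1, stats::sd, na.rm = TRUE)
  sdv[n_ok == 1L] <- 0                      # a single case has no spread
  data.frame(
    day = days,
    mean = rowMeans(fr, na.rm = TRUE),
    sd = sdv,
    sem = sdv / sqrt(pmax(n_ok, 1)),
    n_cases = n_ok)
}

#' Apparent-area fold change over a run
#'
#' Ratio of the final to the initial apparent tumour area; the batch form
#' returns the per-case ratios with their mean and SD.
#'
#' @param record a growth record, or a list of them.
#' @return for one record, a single ratio; for a list, a list with
#'   `fold_changes`, `mean` and `sd`.
#' @export
growth_fold_change <- function(record) {
  one <- function(r) {
    a0 <- r$apparent_area_mm2[r$day == min(r$day)]
    if (a0 <= 0) stop("zero initial apparent area", call. = FALSE)
    r$apparent_area_mm2[r$day == max(r$day)] / a0
  }
  if (is.data.frame(record)) return(one(record))
  fc <- vapply(record, one, numeric(1))
  list(fold_changes = fc, mean = mean(fc), sd = stats::sd(fc))
}

#' Render a fluorescence-style intensity image of the grid
#'
#' Maps the cell states to brightness (proliferative brightest, then
#' quiescent, then dying) and smooths with a 3 x 3 local mean, emulating
#' the appearance of the fluorescence images used for the texture
#' histograms.
#'
#' @param grid a `sim_grid` (or a state matrix).
#' @param weights brightness of P, Q, A, N cells.
#' @return an intensity matrix in `[0, 1]`.
#' @export
render_intensity <- function(grid, weights = c(P = 1, Q = 0.5, A = 0.25,
                                               N = 0.15)) {
  occ <- if (inherits(grid, "sim_grid")) grid$occ else grid
  w <- matrix(0, nrow(occ), ncol(occ))
  for (s in 1:4) w[occ == s] <- weights[s]
  box_mean3(w)
}

## 3x3 local mean with edge renormalization
box_mean3 <- function(M) {
  acc <- matrix(0, nrow(M), ncol(M))
  cnt <- matrix(0, nrow(M), ncol(M))
  n1 <- nrow(M); n2 <- ncol(M)
  for (di in -1:1) for (dj in -1:1) {
    ri <- max(1, 1 + di):min(n1, n1 + di)
    rj <- max(1, 1 + dj):min(n2, n2 + dj)
    si <- max(1, 1 - di):min(n1, n1 - di)
    sj <- max(1, 1 - dj):min(n2, n2 - dj)
    acc[ri, rj] <- acc[ri, rj] + M[si, sj]
    cnt[ri, rj] <- cnt[ri, rj] + 1
  }
  acc / cnt
}

#' Plot normalized growth curves and their variability profile
#'
#' Base-graphics figure: the integral-normalized growth curves of a batch
#' (grey), their mean (black) and, in a lower panel, the across-case SD
#' profile with the bottleneck day marked.
#'
#' @param curves normalized curve matrix from [normalize_curves()].
#' @param days day grid.
#' @param file optional PNG path; if given the plot is written there.
#' @return the [bottleneck_day()] result, invisibly.
#' @export
plot_bottleneck <- function(curves, days = NULL, file = NULL) {
  if (is.null(days)) days <- attr(curves, "days")
  bd <- bottleneck_day(curves, days)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::matplot(days, curves, type = "l", lty = 1, col = "grey60",
                    xlab = "day", ylab = "normalized growth")
  graphics::lines(days, rowMeans(curves), lwd = 2)
  graphics::plot(bd$profile$day, bd$profile$sd, type = "l", lwd = 2,
                 xlab = "day", ylab = "across-case SD")
  graphics::abline(v = bd$day, lty = 2)
  invisible(bd)
}
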
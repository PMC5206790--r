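## Independent oracles used across the suite. These re-derive expected
## behaviour by brute force, without touching the package internals.

## --- division-rule oracle -------------------------------------------------
## occ5: 5x5 logical occupancy (mother at (3,3) implied occupied).
## Returns the expected outcome class by direct enumeration of the rules:
## (i) a free Moore neighbour; (ii) an occupied neighbour that can be
## pushed into a free element of its own Moore neighbourhood; (iii) none.
oracle_division_class <- function(occ5) {
  nb <- function(i, j) {
    out <- NULL
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 5 && jj >= 1 && jj <= 5)
        out <- rbind(out, c(ii, jj))
    }
    out
  }
  ring1 <- nb(3, 3)
  free1 <- !occ5[ring1]
  if (any(free1)) return("placed")
  for (r in seq_len(nrow(ring1))) {
    nbs2 <- nb(ring1[r, 1], ring1[r, 2])
    for (q in seq_len(nrow(nbs2))) {
      tgt <- nbs2[q, ]
      if (!(tgt[1] == 3 && tgt[2] == 3) && !occ5[tgt[1], tgt[2]])
        return("pushed")
    }
  }
  "apoptosis"
}

## build a 5x5 grid with the given occupancy (mother ready at the centre)
make_patch_grid <- function(occ5, params = model_params(grid_n = 5)) {
  g <- simulation_grid(params)
  idx <- which(occ5)
  g$occ[idx] <- 1L
  g$mu[idx] <- params$mu0
  g$g1[idx] <- params$mu0 - 13
  g$phase[idx] <- 1L
  g$occ[3, 3] <- 1L
  g$mu[3, 3] <- params$mu0
  g$g1[3, 3] <- params$mu0 - 13
  g$phase[3, 3] <- 4L
  g$ready[3, 3] <- TRUE
  g
}

## run the implementation on a patch and validate the outcome against the
## oracle, including legality of any placement
check_division_pattern <- function(occ5, params = model_params(grid_n = 5)) {
  g <- make_patch_grid(occ5, params)
  before <- sum(g$occ != 0L)
  res <- attempt_division(g, 3L, 3L)
  expected <- oracle_division_class(occ5)
  ok <- res$outcome == expected
  if (ok && expected %in% c("placed", "pushed")) {
    d <- res$daughter
    ok <- g$occ[d[1], d[2]] == 1L && sum(g$occ != 0L) == before + 1L
    if (ok && expected == "placed")
      ok <- max(abs(d - c(3, 3))) == 1       # adjacent to the mother
    if (ok && expected == "pushed") {
      mv <- res$moved
      ok <- max(abs(mv$from - c(3, 3))) == 1 &&      # first ring
        max(abs(mv$to - mv$from)) == 1 &&            # one displacement
        !occ5[mv$to[1], mv$to[2]] &&                 # into a free element
        identical(as.integer(d), as.integer(mv$from))
    }
  }
  if (ok && expected == "apoptosis")
    ok <- g$occ[3, 3] == 3L && sum(g$occ == 1L) == before - 1L
  ok
}

## ring coordinates of the 5x5 patch
ring1_idx <- cbind(c(2, 3, 4, 2, 4, 2, 3, 4), c(2, 2, 2, 3, 3, 4, 4, 4))
ring2_idx <- {
  all5 <- expand.grid(i = 1:5, j = 1:5)
  on2 <- pmax(abs(all5$i - 3), abs(all5$j - 3)) == 2
  as.matrix(all5[on2, ])
}

## --- morphology oracle ----------------------------------------------------
## independent closing + hole fill + largest component by plain loops;
## the structuring element (a radius-2 disc: the 5x5 square minus its
## corners) is spelled out explicitly
oracle_apparent_count <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  offs <- expand.grid(di = -2:2, dj = -2:2)
  offs <- offs[!(abs(offs$di) == 2 & abs(offs$dj) == 2), ]
  shift_any <- function(M, sign) {
    out <- matrix(FALSE, n1, n2)
    for (r in seq_len(nrow(offs))) {
      di <- sign * offs$di[r]; dj <- sign * offs$dj[r]
      ri <- max(1, 1 + di):min(n1, n1 + di)
      rj <- max(1, 1 + dj):min(n2, n2 + dj)
      si <- max(1, 1 - di):min(n1, n1 - di)
      sj <- max(1, 1 - dj):min(n2, n2 - dj)
      out[ri, rj] <- out[ri, rj] | M[si, sj]
    }
    out
  }
  dil <- shift_any(mask, 1L)
  ero <- !shift_any(!dil, 1L)          # erosion = complement dilation
  ## hole fill: flood the exterior from a padded border (4-connected)
  pad <- matrix(FALSE, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- ero
  outside <- matrix(FALSE, n1 + 2, n2 + 2)
  stack <- list(c(1, 1))
  while (length(stack)) {
    pt <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- pt[1]; j <- pt[2]
    if (i < 1 || i > n1 + 2 || j < 1 || j > n2 + 2) next
    if (outside[i, j] || pad[i, j]) next
    outside[i, j] <- TRUE
    stack <- c(stack, list(c(i - 1, j), c(i + 1, j), c(i, j - 1),
                           c(i, j + 1)))
  }
  filled <- !outside[2:(n1 + 1), 2:(n2 + 1)]
  ## largest 8-connected component by label propagation
  lab <- matrix(0L, n1, n2)
  cur <- 0L
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (!filled[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      pt <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      a <- pt[1]; b <- pt[2]
      if (a < 1 || a > n1 || b < 1 || b > n2) next
      if (!filled[a, b] || lab[a, b] != 0L) next
      lab[a, b] <- cur
      for (di in -1:1) for (dj in -1:1)
        if (di || dj) stack <- c(stack, list(c(a + di, b + dj)))
    }
  }
  if (cur == 0L) 0L else max(tabulate(lab[lab > 0L]))
}

## small empty network helper
empty_net <- function(n = 10, dx = 0.02) vessel_network(n, dx)
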
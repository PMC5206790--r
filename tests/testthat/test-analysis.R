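test_that("apparent area closes gaps and fills holes", {
  dx <- 0.02
  ## solid block: apparent equals effective
  mask <- matrix(FALSE, 40, 40); mask[11:20, 11:20] <- TRUE
  expect_equal(apparent_area(mask, dx), 100 * dx^2)
  ## interior holes are filled
  mask2 <- mask
  mask2[cbind(c(13, 15, 17, 18), c(14, 16, 13, 18))] <- FALSE
  expect_equal(apparent_area(mask2, dx), 100 * dx^2)
  expect_equal(sum(mask2) * dx^2, 96 * dx^2)
  ## checkerboard: closure bridges the gaps; matches the flood-fill oracle
  cb <- matrix(FALSE, 40, 40)
  cb[11:26, 11:26] <- outer(11:26, 11:26, function(i, j) (i + j) %% 2 == 0)
  app <- apparent_area(cb, dx)
  expect_gt(app, sum(cb) * dx^2)
  expect_equal(app, oracle_apparent_count(cb) * dx^2)
  ## empty mask: zero with a warning
  expect_warning(z <- apparent_area(matrix(FALSE, 5, 5), dx), "empty")
  expect_equal(z, 0)
})

test_that("curve normalization divides by the trapezoid integral", {
  days <- 0:28
  const <- matrix(5, 29, 3)
  nc <- normalize_curves(const, days)
  expect_equal(unname(nc[1, ]), rep(1 / 28, 3))        # constant -> 1/T
  set.seed(12)
  curves <- matrix(runif(29 * 4, 0.5, 2), 29, 4)
  nc2 <- normalize_curves(curves, days)
  ints <- apply(nc2, 2, function(y) sum((y[-1] + y[-29]) / 2))
  expect_equal(unname(ints), rep(1, 4), tolerance = 1e-12)
  ## scale invariance: proportional curves normalize identically
  nc3 <- normalize_curves(cbind(curves[, 1], 7 * curves[, 1]), days)
  expect_equal(nc3[, 1], nc3[, 2], tolerance = 1e-12)
  expect_error(normalize_curves(matrix(0, 29, 2), days), "integral")
})

test_that("the bottleneck day is the variability minimum", {
  days <- 0:28
  ## identical curves: SD = 0 everywhere, earliest day returned
  same <- matrix(rep(seq(1, 2, length.out = 29), 3), 29, 3)
  expect_equal(bottleneck_day(same, days)$day, 0)
  ## fan of lines pivoting at day 17
  set.seed(13)
  slopes <- seq(-0.02, 0.02, length.out = 7)
  fan <- sapply(slopes, function(a) 1 / 28 + a * (days - 17))
  bd <- bottleneck_day(fan, days)
  expect_equal(bd$day, 17)
  expect_equal(nrow(bd$profile), 29)
  ## two exact SD minima: tie broken toward the earliest
  f <- (days - 10) * (days - 20)
  two <- sapply(c(1, 2, 3), function(a) a * f)
  expect_equal(bottleneck_day(two, days)$day, 10)
  expect_error(bottleneck_day(fan[, 1, drop = FALSE], days), "two curves")
})

test_that("intensity histograms are unit-integral texture readouts", {
  set.seed(15)
  img <- matrix(runif(2500), 50, 50)
  mask <- matrix(FALSE, 50, 50); mask[11:40, 11:40] <- TRUE
  h <- intensity_histogram(img, mask, bins = 64)
  expect_equal(sum(h$density) / 64, 1, tolerance = 1e-12)
  expect_equal(nrow(h), 64)
  ## constant image: degenerate single bin, still unit integral
  expect_warning(h2 <- intensity_histogram(matrix(0.5, 10, 10),
                                           matrix(TRUE, 10, 10)),
                 "degenerate")
  expect_equal(sum(h2$density) / 64, 1)
  expect_equal(sum(h2$density > 0), 1)
  ## granular early-style texture vs smooth late-style texture:
  ## the smooth image carries more high-intensity mass
  granular <- matrix(rbeta(2500, 1.2, 4), 50, 50)   # dark-dominated
  smooth <- matrix(rbeta(2500, 6, 2), 50, 50)       # bright-dominated
  hg <- intensity_histogram(granular, mask)
  hs <- intensity_histogram(smooth, mask)
  mass_hi <- function(h) sum(h$density[h$mid > 0.5]) / 64
  expect_gt(mass_hi(hs), mass_hi(hg))
})

test_that("proliferative-fraction series match a hand computation", {
  r1 <- data.frame(day = 0:2, n_P = c(100, 40, 20), n_Q = c(0, 60, 80),
                   n_A = 0, n_N = 0)
  r2 <- data.frame(day = 0:2, n_P = c(50, 30, 5), n_Q = c(50, 70, 95),
                   n_A = 0, n_N = 0)
  s <- pq_fraction_series(list(r1, r2))
  expect_equal(s$mean, c((1 + 0.5) / 2, (0.4 + 0.3) / 2, (0.2 + 0.05) / 2))
  expect_equal(s$sd[2], sd(c(0.4, 0.3)))
  expect_equal(s$sem[2], sd(c(0.4, 0.3)) / sqrt(2))
  ## single case: SD = 0
  s1 <- pq_fraction_series(list(r1))
  expect_equal(s1$sd, rep(0, 3))
  ## all-P record: fraction identically 1
  rp <- data.frame(day = 0:2, n_P = c(10, 20, 40), n_Q = 0, n_A = 0,
                   n_N = 0)
  expect_equal(pq_fraction_series(list(rp))$mean, rep(1, 3))
  ## a day with no living cells is reported missing
  rz <- data.frame(day = 0:2, n_P = c(10, 0, 5), n_Q = c(0, 0, 5),
                   n_A = 0, n_N = 0)
  expect_equal(pq_fraction_series(list(rz))$n_cases, c(1, 0, 1))
})

test_that("fold change is the day-28 to day-0 apparent-area ratio", {
  r <- data.frame(day = 0:28, apparent_area_mm2 = rep(2, 29))
  expect_equal(growth_fold_change(r), 1)
  r$apparent_area_mm2 <- seq(2, 4, length.out = 29)
  expect_equal(growth_fold_change(r), 2)
  rs <- lapply(c(1.2, 1.8, 2.4), function(f)
    data.frame(day = 0:28, apparent_area_mm2 = seq(1, f, length.out = 29)))
  fc <- growth_fold_change(rs)
  expect_equal(fc$fold_changes, c(1.2, 1.8, 2.4))
  expect_equal(fc$mean, mean(c(1.2, 1.8, 2.4)))
  expect_equal(fc$sd, sd(c(1.2, 1.8, 2.4)))
  expect_error(growth_fold_change(
    data.frame(day = 0:1, apparent_area_mm2 = c(0, 1))), "zero initial")
})

test_that("rendered intensity is brightest over proliferating regions", {
  occ <- matrix(0L, 20, 20)
  occ[3:8, 3:8] <- 1L       # P block
  occ[13:18, 13:18] <- 2L   # Q block
  img <- render_intensity(occ)
  expect_gt(img[5, 5], img[15, 15])
  expect_equal(img[5, 5], 1)
  expect_true(all(img >= 0 & img <= 1))
})
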
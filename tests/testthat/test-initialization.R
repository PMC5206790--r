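test_that("density thresholding follows the three-level procedure", {
  p <- model_params(grid_n = 50)
  expect_error(tumour_from_image(matrix(0.5, 100, 100), c(0.5, 0.4, 0.8), p),
               "ascending")
  ## uniform black image: empty tumour
  expect_warning(
    dm <- tumour_from_image(matrix(0, 100, 100), c(0.2, 0.5, 0.8), p),
    "empty")
  expect_equal(dm$n_cells, 0)
  ## uniform bright image: everything high density, occupancy at the
  ## configured high fill rate up to sampling error
  set.seed(14)
  dm2 <- tumour_from_image(matrix(0.95, 100, 100), c(0.2, 0.5, 0.8), p)
  expect_true(all(dm2$labels == 3L))
  expect_lt(abs(mean(dm2$occupancy) - p$fill_high), 0.02)
})

test_that("a three-ring phantom yields densities ordered core > rim", {
  p <- model_params(grid_n = 60)
  img <- matrix(0.02, 120, 120)
  d <- sqrt(outer((1:120 - 60)^2, (1:120 - 60)^2, "+"))
  img[d < 50] <- 0.3; img[d < 35] <- 0.6; img[d < 20] <- 0.9
  dens <- matrix(0, 20, 3)
  set.seed(3)
  for (s in 1:20) {
    dm <- tumour_from_image(img, c(0.15, 0.45, 0.75), p)
    for (r in 1:3) dens[s, r] <- mean(dm$occupancy[dm$labels == r])
  }
  m <- colMeans(dens)
  expect_true(m[3] > m[2] && m[2] > m[1])   # strictly decreasing outward
  expect_equal(m, c(p$fill_low, p$fill_med, p$fill_high), tolerance = 0.05)
})

test_that("initial cell placement matches occupancy and is desynchronized", {
  p <- model_params(grid_n = 60)
  g <- simulation_grid(p)
  img <- matrix(0, 120, 120)
  img[40:80, 40:80] <- 0.95
  set.seed(4)
  dm <- tumour_from_image(img, c(0.2, 0.5, 0.8), p, grid = g)
  expect_equal(sum(g$occ == 1L), dm$n_cells)       # all cells proliferative
  expect_equal(sum(g$occ != 0L), sum(dm$occupancy))
  expect_setequal(unique(g$phase[g$occ == 1L]), 1:4)  # spread over phases
  ## effective initial area = count x dx^2
  expect_equal(sum(dm$occupancy) * p$dx^2,
               sum(g$occ == 1L | g$occ == 2L) * p$dx^2)
})

test_that("polylines rasterize to 8-connected chains of correct length", {
  p <- model_params(grid_n = 40)
  ## horizontal line: edge segments, length within one dx of Euclidean
  net <- vessels_from_polylines(list(cbind(c(0, 40), c(20, 20))),
                                params = p)
  sg <- net_segments(net)
  expect_true(all(sg$length_mm == p$dx))
  expect_equal(sum(sg$length_mm), 40 * p$dx, tolerance = p$dx)
  ## 45-degree diagonal: diagonal segments
  net2 <- vessels_from_polylines(list(cbind(c(0, 40), c(0, 40))),
                                 params = p)
  sg2 <- net_segments(net2)
  expect_true(all(abs(sg2$length_mm - p$dx * sqrt(2)) < 1e-12))
  expect_lt(abs(sum(sg2$length_mm) - sqrt(2) * 40 * p$dx),
            p$dx * sqrt(2) + 1e-12)
  ## crossing polylines share a lattice node (connected flow graph)
  net3 <- vessels_from_polylines(
    list(cbind(c(0, 40), c(20, 20)), cbind(c(20, 20), c(0, 40))),
    entry = c(0, 20), params = p)
  fl <- solve_flow(net3)                     # solvable: single component
  expect_lt(kirchhoff_residual(fl), 1e-8)
  ## entry point must lie on a polyline
  expect_error(vessels_from_polylines(
    list(cbind(c(0, 40), c(20, 20))), entry = c(5, 5), params = p),
    "entry point")
})

test_that("hemodynamic initialization adapts every free vessel", {
  p <- model_params(grid_n = 40)
  pls <- list(cbind(c(20, 20), c(0, 40)),          # reference, vertical
              cbind(c(20, 0), c(20, 28)),          # branches to borders
              cbind(c(20, 40), c(30, 14)))
  net <- vessels_from_polylines(pls, params = p)
  s <- seq_len(net$n_seg)
  expect_true(all(net$radius[s][net$fixed[s]] == 40))   # 80 um reference
  expect_true(all(net$radius[s][!net$fixed[s]] == 15))  # 30 um others
  suppressWarnings(build_initial_vasculature(net, p))
  expect_true(all(net$radius[s][net$fixed[s]] == 40))
  expect_true(all(net$radius[s][!net$fixed[s]] != 15))  # adaptation acted
  ## determinism: the same input adapts to the same network
  net2 <- vessels_from_polylines(pls, params = p)
  suppressWarnings(build_initial_vasculature(net2, p))
  expect_identical(net$radius[s], net2$radius[seq_len(net2$n_seg)])
})

test_that("synthetic cases are reproducible, distinct and well-formed", {
  p <- model_params()
  c1 <- generate_synthetic_case(3, p)
  c2 <- generate_synthetic_case(3, p)
  expect_identical(c1, c2)                   # same seed: identical case
  ## the generator must not disturb the global RNG stream
  set.seed(99); x1 <- runif(3)
  set.seed(99); invisible(generate_synthetic_case(5, p)); x2 <- runif(3)
  expect_identical(x1, x2)
  ## distinct cases with blob area in the configured range
  cases <- lapply(1:7, generate_synthetic_case, params = p)
  imgs <- vapply(cases, function(cc) sum(cc$image), numeric(1))
  expect_equal(length(unique(imgs)), 7L)
  r0 <- vapply(cases, function(cc) cc$blob$r0_mm, numeric(1))
  expect_true(all(r0 >= 0.6 * 0.9 & r0 <= 0.6 * 1.1))
  ## entry lies on the reference polyline and the frame border
  for (cc in cases) {
    expect_true(cc$entry[1] %in% c(0, p$grid_n) ||
                  cc$entry[2] %in% c(0, p$grid_n))
  }
})

test_that("the full pipeline initializes a consistent, reusable state", {
  p <- model_params(grid_n = 100)
  case <- generate_synthetic_case(2, p, r0_mm = 0.3)
  set.seed(10)
  g <- initialize_grid(case, p)
  ## three density classes present in the map, cells all proliferative
  expect_setequal(unique(as.vector(g$density_map$labels)), 0:3)
  expect_gt(sum(g$occ == 1L), 50)
  expect_equal(sum(g$occ != 0L), sum(g$occ == 1L))
  ## oxygen was solved: above baseline near vessels, depressed at cells
  expect_gt(max(g$O), 1)
  expect_lt(min(g$O), 1)
  ## determinism of the whole pipeline
  set.seed(10)
  g2 <- initialize_grid(case, p)
  expect_identical(g$occ, g2$occ)
  expect_identical(g$network$radius[seq_len(g$network$n_seg)],
                   g2$network$radius[seq_len(g2$network$n_seg)])
  ## state file round trip preserves the cells and the network
  dir <- tempfile()
  save_state(g, dir)
  g3 <- load_state(dir, p)
  expect_identical(g3$occ, g$occ)
  expect_equal(g3$mu[g3$occ != 0], g$mu[g$occ != 0])
  expect_equal(g3$network$n_seg, g$network$n_seg)
})
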
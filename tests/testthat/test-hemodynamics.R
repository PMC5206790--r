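test_that("a single segment follows the Poiseuille closed form", {
  net <- vessel_network(10, dx = 0.02)
  net_add_segment(net, 0, 5, 1, 5, radius = 20)
  net$entry <- c(1, 5)
  fl <- solve_flow(net, entry_pressure = 13, boundary_pressure = 2,
                   viscosity = 1)
  expect_equal(abs(fl$segments$flow),
               pi * 20^4 / (8 * 1 * 0.02) * 11)       # g * dP, exactly
  ## flow runs from the 13 kPa entry toward the 2 kPa border
  pr <- fl$nodes$pressure
  expect_setequal(pr, c(2, 13))
})

test_that("a symmetric bifurcation splits flow 50/50", {
  net <- vessel_network(10, dx = 0.02)
  ## parent from the entry into a junction, two equal arms to the border
  net_add_segment(net, 5, 5, 5, 4, radius = 20)
  net_add_segment(net, 5, 4, 4, 3, radius = 12)
  net_add_segment(net, 4, 3, 4, 2, radius = 12)
  net_add_segment(net, 4, 2, 4, 1, radius = 12)
  net_add_segment(net, 4, 1, 4, 0, radius = 12)
  net_add_segment(net, 5, 4, 6, 3, radius = 12)
  net_add_segment(net, 6, 3, 6, 2, radius = 12)
  net_add_segment(net, 6, 2, 6, 1, radius = 12)
  net_add_segment(net, 6, 1, 6, 0, radius = 12)
  net$entry <- c(5, 5)
  fl <- solve_flow(net)
  q <- abs(fl$segments$flow)
  expect_equal(q[2], q[6])                     # the two arms
  expect_equal(q[1], q[2] + q[6])              # conservation at the fork
  expect_lt(kirchhoff_residual(fl), 1e-10)
})

test_that("random networks match a dense linear-algebra oracle", {
  set.seed(21)
  for (rep in 1:3) {
    net <- vessel_network(12, dx = 0.02)
    ## random connected scribble from the border inward
    cur <- c(0L, 6L)
    for (s in 1:25) {
      step <- c(sample(c(-1L, 0L, 1L), 1), sample(c(-1L, 0L, 1L), 1))
      if (all(step == 0L)) step <- c(1L, 0L)
      nxt <- pmin(pmax(cur + step, 0L), 12L)
      if (!all(nxt == cur))
        net_add_segment(net, cur[1], cur[2], nxt[1], nxt[2],
                        radius = runif(1, 10, 30))
      cur <- nxt
    }
    net$entry <- cur
    fl <- solve_flow(net)
    expect_lt(kirchhoff_residual(fl), 1e-10)
    ## independent dense solve of the same conservation system
    s <- seq_len(net$n_seg)
    a <- fl$segments$from; b <- fl$segments$to
    g <- fl$segments$conductance
    nn <- nrow(fl$nodes)
    L <- matrix(0, nn, nn)
    for (k in s) {
      L[a[k], a[k]] <- L[a[k], a[k]] + g[k]
      L[b[k], b[k]] <- L[b[k], b[k]] + g[k]
      L[a[k], b[k]] <- L[a[k], b[k]] - g[k]
      L[b[k], a[k]] <- L[b[k], a[k]] - g[k]
    }
    fixed <- fl$nodes$fixed
    pfix <- fl$nodes$pressure[fixed]
    A <- L[!fixed, !fixed, drop = FALSE]
    rhs <- -L[!fixed, fixed, drop = FALSE] %*% pfix
    p_free <- solve(A, rhs)
    expect_equal(fl$nodes$pressure[!fixed], as.numeric(p_free),
                 tolerance = 1e-10)
  }
})

test_that("disconnected components without boundary conditions are rejected", {
  net <- vessel_network(10, dx = 0.02)
  net_add_segment(net, 0, 5, 1, 5, radius = 15)
  net_add_segment(net, 4, 4, 5, 5, radius = 15)   # floating island
  net$entry <- c(1, 5)
  expect_error(solve_flow(net), "singular")
})

test_that("diameter adaptation converges deterministically within bounds", {
  p <- model_params(grid_n = 20)
  mk <- function() {
    net <- vessel_network(20, dx = 0.02)
    ## reference trunk from the border, fixed radius
    for (y in 0:9) net_add_segment(net, 10, y, 10, y + 1, radius = 40,
                                   fixed = TRUE)
    ## two parallel return paths to the border: one short, one long
    net_add_segment(net, 10, 10, 9, 10, radius = 15)
    for (x in 9:1) net_add_segment(net, x, 10, x - 1, 10, radius = 15)
    net_add_segment(net, 10, 10, 11, 11, radius = 15)
    for (y in 11:14) net_add_segment(net, 11, y, 11, y + 1, radius = 15)
    for (x in 11:1) net_add_segment(net, x, 15, x - 1, 15, radius = 15)
    net$entry <- c(10, 0)
    net
  }
  net1 <- mk(); net2 <- mk()
  suppressWarnings(adapt_diameters(net1, p))
  suppressWarnings(adapt_diameters(net2, p))
  s <- seq_len(net1$n_seg)
  expect_identical(net1$radius[s], net2$radius[s])   # no RNG involved
  expect_true(all(net1$radius[s] >= p$R_min & net1$radius[s] <= p$R_max))
  expect_true(all(net1$radius[s][net1$fixed[s]] == 40))  # reference fixed
  ## shorter parallel path carries more flow, ends thicker
  short_first <- which(!net1$fixed[s])[1]
  long_first <- which(net1$x1[s] == 10 & net1$y1[s] == 10 &
                      net1$x2[s] == 11 & net1$y2[s] == 11)
  expect_gt(net1$radius[short_first], net1$radius[long_first])
  ## a converged network is a fixed point
  before <- net1$radius[s]
  suppressWarnings(adapt_diameters(net1, p))
  expect_equal(net1$radius[s], before, tolerance = 1e-3)
})

test_that("a reference-only network is left unchanged by adaptation", {
  p <- model_params(grid_n = 10)
  net <- vessel_network(10, dx = 0.02)
  for (y in 0:9) net_add_segment(net, 5, y, 5, y + 1, radius = 40,
                                 fixed = TRUE)
  net$entry <- c(5, 0)
  adapt_diameters(net, p)
  expect_true(all(net$radius[seq_len(net$n_seg)] == 40))
})

test_that("oxygen permeability scales with R/R_min", {
  p <- model_params(grid_n = 10)
  E0 <- matrix(0, 10, 10)
  mk <- function(r) {
    net <- vessel_network(10, dx = 0.02)
    net_add_segment(net, 4, 4, 5, 4, radius = r)
    vtumour:::weight_matrices(net, E0, p)$gammaW
  }
  g1 <- mk(p$R_min); g2 <- mk(2 * p$R_min)
  expect_equal(sum(g2), 2 * sum(g1))
  expect_equal(max(g1), p$gamma_v_base * p$oxygen_rate_scale * 0.5 *
                 p$seg_weight_scale)
})
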
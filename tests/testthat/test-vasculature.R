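test_that("vessel weight reproduces the published edge/diagonal formula", {
  p <- model_params(grid_n = 10)
  net <- vessel_network(10, dx = 0.02)
  ## no segments: W = E
  expect_equal(vessel_weight(net, 5, 5, E = 1), 1)
  ## one full edge segment, E = 0: W = dx/2 = 0.01 mm
  net_add_segment(net, 4, 4, 5, 4, radius = 15)
  expect_equal(vessel_weight(net, 5, 5, E = 0), 0.01)
  ## its two flanking elements see the same half-length
  expect_equal(vessel_weight(net, 5, 4, E = 0), 0.01)
  ## one diagonal, E = E_0: W = dx sqrt(2) + E_0
  net2 <- vessel_network(10, dx = 0.02)
  net_add_segment(net2, 4, 4, 5, 5, radius = 15)
  expect_equal(vessel_weight(net2, 5, 5, E = 1), 0.02 * sqrt(2) + 1)
  ## element units: edge 1/2, diagonal sqrt(2)
  expect_equal(vessel_weight(net, 5, 5, E = 0, units = "elements"), 0.5)
  expect_equal(vessel_weight(net2, 5, 5, E = 0, units = "elements"), sqrt(2))
})

test_that("vessel weight is additive over segments and monotone in E", {
  net <- vessel_network(10, dx = 0.02)
  w0 <- vessel_weight(net, 5, 5, E = 0)
  net_add_segment(net, 4, 4, 5, 4, radius = 15)
  w1 <- vessel_weight(net, 5, 5, E = 0)
  net_add_segment(net, 4, 4, 5, 5, radius = 15)
  w2 <- vessel_weight(net, 5, 5, E = 0)
  expect_equal(w1 - w0, 0.01)
  expect_equal(w2 - w1, 0.02 * sqrt(2))       # additivity
  expect_gt(vessel_weight(net, 5, 5, E = 1), w2)  # monotone in E
  ## duplicate segments are not double-counted
  expect_equal(net_add_segment(net, 5, 4, 4, 4, radius = 15), 0L)
  expect_equal(vessel_weight(net, 5, 5, E = 0), w2)
})

test_that("capillary degradation is thresholded, local and irreversible", {
  p <- model_params(grid_n = 8, p_degrade = 100)
  E <- matrix(p$E_0, 8, 8)
  pf <- matrix(0, 8, 8)
  expect_equal(degrade_capillaries(E, pf, p), E)     # p = 0: unchanged
  pf[4, 4] <- 101
  E2 <- degrade_capillaries(E, pf, p)
  expect_equal(E2[4, 4], 0)
  expect_equal(sum(E2 == 0), 1)                      # strictly local
  ## irreversible: once 0, stays 0 under p = 0
  E3 <- degrade_capillaries(E2, matrix(0, 8, 8), p)
  expect_equal(E3[4, 4], 0)
})

test_that("matrix integrity decays linearly with protease exposure", {
  p <- model_params(matrix_degrade_rate = 0.01)
  integ <- matrix(1, 4, 4)
  m <- matrix(2, 4, 4)
  expect_equal(degrade_matrix(integ, matrix(0, 4, 4), p, dt = 5), integ)
  for (t in 1:10) integ <- degrade_matrix(integ, m, p, dt = 1)
  expect_equal(integ, matrix(max(0, 1 - 0.01 * 2 * 10), 4, 4))
  for (t in 1:100) integ <- degrade_matrix(integ, m, p, dt = 1)
  expect_equal(integ, matrix(0, 4, 4))               # floored at 0
})

test_that("sprouting is strictly VEGF-gated", {
  p <- model_params(grid_n = 20, sprout_init_rate = 10)
  g <- simulation_grid(p)
  net <- vessel_network(20, p$dx)
  for (x in 0:19) net_add_segment(net, x, 10, x + 1, 10, radius = 15)
  g$network <- net
  set.seed(1)
  for (t in 1:(28 * 24)) initiate_sprouts(g, 1)      # V = 0 throughout
  expect_length(g$sprouts, 0)
})

test_that("sprouts originate near VEGF hotspots with minimum spacing", {
  p <- model_params(grid_n = 20, sprout_init_rate = 5, V_sprout = 1e-3)
  mk <- function() {
    g <- simulation_grid(p)
    net <- vessel_network(20, p$dx)
    for (x in 0:19) net_add_segment(net, x, 10, x + 1, 10, radius = 15)
    g$network <- net
    g
  }
  ## single hotspot beside one end of the vessel
  hits <- 0
  set.seed(5)
  for (rep in 1:100) {
    g <- mk()
    g$V <- matrix(0, 20, 20)
    g$V[3, 10] <- 0.05
    g$V <- vtumour:::box_mean3(vtumour:::box_mean3(g$V))
    initiate_sprouts(g, 1)
    if (length(g$sprouts) &&
        any(vapply(g$sprouts, function(s) s$origin[1] <= 6, logical(1))))
      hits <- hits + 1
  }
  expect_gt(hits, 80)                                 # origin near hotspot
  ## uniformly high V: origins respect the spacing constraint
  g <- mk()
  g$V <- matrix(0.05, 20, 20)
  set.seed(6)
  for (t in 1:50) initiate_sprouts(g, 1)
  origins <- t(vapply(g$sprouts, function(s) s$origin, numeric(2)))
  if (nrow(origins) > 1) {
    dd <- as.matrix(dist(origins, method = "maximum"))
    diag(dd) <- Inf
    expect_gte(min(dd), p$sprout_spacing)
  }
})

test_that("tip migration drifts up a VEGF gradient and is isotropic without one", {
  p <- model_params(grid_n = 30, sprout_move_prob = 1)
  new_tip_grid <- function(V) {
    g <- simulation_grid(p)
    g$network <- vessel_network(30, p$dx)
    g$V <- V
    g$sprouts <- list(list(id = 1L, origin = c(15L, 15L), tip = c(15L, 15L),
                           prev = c(0L, 0L), age = 0, active = TRUE,
                           perfused = FALSE, segs = integer(0), parent = 0L))
    g$network$node_struct[16, 16] <- 1L
    g
  }
  ## linear gradient along x: displacement projects positively
  Vgrad <- matrix(rep(seq(0, 0.01, length.out = 30), 30), 30, 30)
  set.seed(8)
  proj <- replicate(200, {
    g <- new_tip_grid(Vgrad)
    migrate_sprout_tips(g, 1)
    g$sprouts[[1]]$tip[1] - 15
  })
  expect_gt(mean(proj), 0)
  expect_gt(mean(proj) / (sd(proj) / sqrt(200)), 2.6)   # 99% confidence
  ## uniform V: step distribution consistent with an unbiased walk
  set.seed(9)
  Vuni <- matrix(0.005, 30, 30)
  dirs <- replicate(1e4, {
    g <- new_tip_grid(Vuni)
    migrate_sprout_tips(g, 1)
    paste(g$sprouts[[1]]$tip - c(15, 15), collapse = ",")
  })
  counts <- table(dirs)
  expect_equal(length(counts), 8L)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("tips anastomose on node contact and the path becomes perfused", {
  p <- model_params(grid_n = 20, sprout_move_prob = 1,
                    chemotaxis_kappa = 5e4)
  g <- simulation_grid(p)
  net <- vessel_network(20, p$dx)
  for (y in 0:19) net_add_segment(net, 12, y, 12, y + 1, radius = 15)
  g$network <- net
  ## strong VEGF gradient pulling the tip straight toward the vessel
  g$V <- matrix(rep(seq(0, 0.05, length.out = 20), 20), 20, 20)
  g$sprouts <- list(list(id = 1L, origin = c(8L, 10L), tip = c(8L, 10L),
                         prev = c(0L, 0L), age = 0, active = TRUE,
                         perfused = FALSE, segs = integer(0), parent = 0L))
  net$node_struct[9, 11] <- 1L
  set.seed(3)
  for (t in 1:30) migrate_sprout_tips(g, 1)
  sp <- g$sprouts[[1]]
  expect_false(sp$active)
  expect_true(sp$perfused)
  expect_true(all(net$perfused[sp$segs]))
  ## perfused neovessels now count in the oxygen-delivery weight
  wm <- vtumour:::weight_matrices(net, matrix(0, 20, 20), p,
                                  active_ids = integer(0))
  expect_gt(sum(wm$gammaW), 0)
})

test_that("sprout paths are connected lattice chains and never shrink", {
  p <- model_params(grid_n = 30, sprout_move_prob = 1, V_sprout = 1e-3)
  g <- simulation_grid(p)
  net <- vessel_network(30, p$dx)
  for (x in 0:29) net_add_segment(net, x, 5, x + 1, 5, radius = 15)
  g$network <- net
  g$V <- matrix(rep(seq(0.002, 0.02, length.out = 30), each = 30), 30, 30)
  set.seed(4)
  lens <- integer(0)
  for (t in 1:40) {
    initiate_sprouts(g, 1)
    migrate_sprout_tips(g, 1)
    lens <- c(lens, sum(net$kind[seq_len(net$n_seg)] == 1L))
  }
  expect_true(all(diff(lens) >= 0))          # total neovessel length grows
  expect_gt(max(lens), 0)
  for (sp in g$sprouts) {
    if (length(sp$segs) < 2) next
    sg <- net_segments(net)[sp$segs, ]
    ## consecutive segments share an endpoint
    for (r in seq_len(nrow(sg) - 1)) {
      pts1 <- rbind(c(sg$x1[r], sg$y1[r]), c(sg$x2[r], sg$y2[r]))
      pts2 <- rbind(c(sg$x1[r + 1], sg$y1[r + 1]),
                    c(sg$x2[r + 1], sg$y2[r + 1]))
      expect_true(any(apply(pts1, 1, function(a)
        any(apply(pts2, 1, function(b) all(a == b))))))
    }
  }
})
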
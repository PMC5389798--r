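test_that("circulant layers are k-regular with the closed-form spectrum", {
  c4 <- circulant_layer(4, 2)
  expect_equal(c4$degrees, rep(2L, 4))
  expect_equal(c4$degree_sum, 8L)
  expect_equal(c4$omega, c(0, 2, 2, 4), tolerance = 1e-12)

  # dense eigensolver vs the circulant closed form
  for (nk in list(c(8, 2), c(10, 4), c(12, 6), c(24, 4))) {
    layer <- circulant_layer(nk[1], nk[2])
    expect_equal(layer$omega, circulant_omega_oracle(nk[1], nk[2]),
                 tolerance = 1e-10)
    expect_equal(layer$degrees, rep(as.integer(nk[2]), nk[1]))
  }

  # largest eigenvalue bounded by twice the degree
  c6 <- circulant_layer(6, 4)
  expect_equal(c6$degree_sum, 24L)
  expect_lte(max(c6$omega), 2 * 4)

  expect_error(circulant_layer(6, 3), "even")
  expect_error(circulant_layer(4, 4), "0 < k < n")
})

test_that("complete layers have the K_n spectrum and quadratic degree sum", {
  k3 <- complete_layer(3)
  expect_equal(k3$omega, c(0, 3, 3), tolerance = 1e-12)
  expect_equal(k3$degree_sum, 6L)
  k5 <- complete_layer(5)
  expect_equal(k5$degree_sum, 20L)
  # the largest eigenvalue equals the layer size here
  expect_equal(max(k5$omega), 5, tolerance = 1e-12)
  expect_error(complete_layer(1), "n must be >= 2")
})

test_that("small-world rewiring preserves the degree sum and connectivity", {
  # zero rewiring reproduces the ring lattice exactly
  ws0 <- small_world_layer(10, 4, 0)
  expect_equal(ws0$adjacency, circulant_layer(10, 4)$adjacency)

  for (seed in 1:8) {
    ws <- small_world_layer(30, 4, 0.3, seed = seed)
    expect_equal(ws$degree_sum, 4L * 30L)
    expect_true(extensivity:::graph_connected(ws$adjacency))
  }
  ws_big <- small_world_layer(200, 6, 1, seed = 3)
  expect_equal(ws_big$degree_sum, 6L * 200L)

  # full rewiring generally changes the spectrum
  ws1 <- small_world_layer(10, 4, 1, seed = 7)
  expect_equal(ws1$degree_sum, 40L)
  expect_gt(max(abs(ws1$omega - circulant_layer(10, 4)$omega)), 1e-6)

  expect_error(small_world_layer(10, 4, 1.2), "p_rewire")
})

test_that("Erdos-Renyi layers obey the handshake and trace identities", {
  expect_equal(erdos_renyi_layer(6, 1, seed = 0)$adjacency,
               complete_layer(6)$adjacency)
  er <- erdos_renyi_layer(20, 0.2, seed = 3)
  expect_equal(er$degree_sum, sum(er$adjacency))
  expect_equal(sum(er$omega), er$degree_sum, tolerance = 1e-9)
  expect_error(erdos_renyi_layer(10, 0), "p must")
})

test_that("every generated layer satisfies sum(omega) = S and omega >= 0", {
  for (layer in property_layers()) {
    expect_equal(sum(layer$omega), layer$degree_sum,
                 tolerance = 1e-9 * max(1, layer$degree_sum))
    expect_equal(layer$omega[1], 0)
    expect_true(all(layer$omega >= -1e-10))
    expect_equal(rowSums(layer$laplacian), rep(0, layer$n_nodes),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("mirror multiplexes obey the closed-form eigenvalue pairing", {
  c4 <- circulant_layer(4, 2)
  g <- mirror_multiplex(c4, 4)
  expect_equal(g$alpha, 1)
  L <- supra_laplacian(g, 0.1, 0.05)
  expect_equal(sort(L$mu), c(0, .1, .2, .2, .3, .3, .4, .5), tolerance = 1e-10)

  # doubled multiplicity: alpha = 2, pairing still exact
  g2 <- mirror_multiplex(c4, 8)
  expect_equal(g2$alpha, 2)
  L2 <- supra_laplacian(g2, 0.1, 0.05)
  expect_equal(sort(L2$mu),
               sort(c(0.1 * c4$omega, 0.1 * c4$omega + 2 * 0.05 * 2)),
               tolerance = 1e-10)

  expect_error(mirror_multiplex(c4, 3), "multiple")

  for (layer in property_layers()) {
    n <- layer$n_nodes
    g <- mirror_multiplex(layer, 2L * n)
    mu <- supra_laplacian(g, 0.07, 0.02)$mu
    expect_equal(sort(mu), mirror_mu_oracle(layer, 2L * n, 0.07, 0.02),
                 tolerance = 1e-10)
  }
})

test_that("general multiplex construction validates input and fills D1, D2", {
  g1 <- circulant_layer(5, 2); g2 <- circulant_layer(5, 2)
  g <- build_multiplex(g1, g2, matrix(integer(0), 0, 2))
  expect_equal(g$l12, 0L)
  expect_equal(g$alpha, 0)

  g <- build_multiplex(g1, g2, rbind(c(1L, 1L)))
  expect_equal(g$l12, 1L)
  expect_equal(diag(g$laplacian_A)[1:5], c(1, 0, 0, 0, 0))
  expect_equal(diag(g$laplacian_A)[6:10], c(1, 0, 0, 0, 0))
  expect_equal(rowSums(g$laplacian_A), rep(0, 10), ignore_attr = TRUE)

  # saturation at l12 = N1 * N2
  c4 <- circulant_layer(4, 2)
  all_pairs <- as.matrix(expand.grid(1:4, 1:4))
  gf <- build_multiplex(c4, c4, all_pairs)
  expect_equal(gf$l12, 16L)

  expect_error(build_multiplex(g1, g2, rbind(c(0L, 1L))), "out of range")
  expect_error(build_multiplex(g1, g2, rbind(c(1L, 1L), c(1L, 1L))),
               "duplicate")
})

test_that("supra-Laplacian has zero row sums and the trace identity", {
  g <- build_multiplex(circulant_layer(6, 2), circulant_layer(6, 2),
                       rbind(c(1L, 2L), c(3L, 4L)))
  expect_error(supra_laplacian(g, -0.1, 0), "non-negative")

  L0 <- supra_laplacian(g, 0, 0)
  expect_equal(L0$matrix, matrix(0, 12, 12), ignore_attr = TRUE)
  expect_equal(L0$mu, rep(0, 12))

  L <- supra_laplacian(g, 0.1, 0.3)
  expect_equal(rowSums(L$matrix), rep(0, 12), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(sum(L$mu), sum(diag(L$matrix)), tolerance = 1e-10)
  expect_equal(L$mu[1], 0)

  # gamma = 0 mirror: duplicated single-layer spectrum
  gm <- mirror_multiplex(circulant_layer(4, 2), 4)
  Lg <- supra_laplacian(gm, 0.1, 0)
  expect_equal(sort(Lg$mu), rep(c(0, .2, .2, .4), each = 2), tolerance = 1e-10)
})

test_that("edge-list and descriptor round trips are lossless", {
  dir <- withr::local_tempdir()
  ws <- small_world_layer(14, 4, 0.3, seed = 5)
  p <- file.path(dir, "ws.tsv")
  write_layer_edgelist(ws, p)
  ws2 <- read_layer_edgelist(p)
  expect_equal(ws2$adjacency, ws$adjacency, ignore_attr = TRUE)
  expect_equal(ws2$omega, ws$omega)

  g <- build_multiplex(ws, small_world_layer(14, 4, 0.3, seed = 6),
                       rbind(c(1L, 5L), c(2L, 9L)))
  desc <- write_multiplex(g, dir, name = "pair", epsilon = 0.1, gamma = 0.02)
  g2 <- read_multiplex(desc)
  expect_equal(g2$l12, 2L)
  expect_equal(g2$inter_adjacency, g$inter_adjacency)
  expect_equal(attr(g2, "epsilon"), 0.1)
})
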
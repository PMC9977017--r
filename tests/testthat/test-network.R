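test_that("network metrics match hand calculations on canonical graphs", {
  # triangle
  k3 <- net_from_adj(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
  m <- network_metrics(k3)
  expect_equal(unname(m["n_nodes"]), 3)
  expect_equal(unname(m["avg_degree"]), 2)
  expect_equal(unname(m["n_loops"]), 1)
  expect_equal(unname(m["loop3"]), 1)
  expect_equal(unname(m["loop4"]), 0)
  expect_equal(unname(m["clust1"]), 1 / 3)  # as printed: no factor 3
  expect_equal(unname(m["clust2"]), 1)
  expect_equal(unname(m["radius"]), 1)
  expect_equal(unname(m["spectral_radius"]), 2, tolerance = 1e-10)
  expect_equal(unname(m["trace"]), 0)
  expect_equal(unname(m["energy"]), 6, tolerance = 1e-10)

  # 4-cycle
  c4 <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    c4[e[1], e[2]] <- c4[e[2], e[1]] <- 1
  }
  m4 <- network_metrics(net_from_adj(c4))
  expect_equal(unname(m4["loop3"]), 0)
  expect_equal(unname(m4["loop4"]), 1)
  expect_equal(unname(m4["n_loops"]), 1)
  expect_equal(unname(m4["spectral_radius"]), 2, tolerance = 1e-10)
  expect_equal(unname(m4["energy"]), 8, tolerance = 1e-10)

  # a single node with a self-loop
  solo <- net_from_adj(matrix(0L, 1, 1), self_loops = 1L)
  ms <- network_metrics(solo)
  expect_equal(unname(ms["trace"]), 1)
  expect_equal(unname(ms["spectral_radius"]), 1)
  expect_equal(unname(ms["energy"]), 1)
  expect_equal(unname(ms["n_loops"]), 0)

  # the conventional transitivity is available behind the flag
  expect_equal(unname(network_metrics(k3, transitivity_factor3 = TRUE)["clust1"]),
               1)
})

test_that("cycle formulas equal exhaustive enumeration", {
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(count_cycles(k4, 3), 4)
  expect_equal(count_cycles(k4, 4), 3)
  expect_error(count_cycles(k4, 5), "3 or 4")

  # trees are acyclic
  tree <- matrix(0, 7, 7)
  for (e in list(c(1, 2), c(1, 3), c(2, 4), c(2, 5), c(3, 6), c(3, 7))) {
    tree[e[1], e[2]] <- tree[e[2], e[1]] <- 1
  }
  expect_equal(count_cycles(tree, 3), 0)
  expect_equal(count_cycles(tree, 4), 0)

  # random graphs: formula == enumeration, exactly
  for (s in 1:50) {
    a <- rand_adj(12, 0.3, seed = s)
    expect_identical(count_cycles(a, 3), brute_cycles(a, 3))
    expect_identical(count_cycles(a, 4), brute_cycles(a, 4))
  }
  # exhaustive sweep over small graphs of every size up to 8 nodes
  for (s in 1:150) {
    n <- 4 + (s %% 5)
    a <- rand_adj(n, 0.4, seed = 1000 + s)
    expect_identical(count_cycles(a, 3), brute_cycles(a, 3))
    expect_identical(count_cycles(a, 4), brute_cycles(a, 4))
  }
})

test_that("spectral identities hold on random networks", {
  for (s in 1:30) {
    a <- rand_adj(10, 0.35, seed = 200 + s)
    self <- which(rbinom(10, 1, 0.3) == 1)
    net <- net_from_adj(a, self_loops = self)
    m <- network_metrics(net)
    # Perron-Frobenius: spectral radius at least the average degree
    expect_gte(m[["spectral_radius"]], m[["avg_degree"]] - 1e-10)
    # energy = trace(A^2) via the matrix route
    A <- net$adjacency
    expect_equal(m[["energy"]], sum(diag(A %*% A)), tolerance = 1e-8)
    # trace counts self-loop nodes
    expect_equal(m[["trace"]], length(self))
  }
})

test_that("transition networks are built from cell transitions", {
  # constant trivariate signal: one node with a self-loop
  g <- trivariate_grid(1:100, rep(1, 100), rep(2, 100), rep(3, 100))
  net <- build_transition_network(g, 1)
  expect_equal(net$n_nodes, 1)
  expect_equal(nrow(net$edges), 0)
  expect_equal(net$self_loops, 1)

  # mutually independent noise leaves the rank cloud uniform, so the
  # partition keeps a single cell: a 1-node network
  set.seed(101)
  gu <- trivariate_grid(1:5000, rnorm(5000), rnorm(5000), rnorm(5000))
  expect_equal(build_transition_network(gu, 1)$n_nodes, 1)

  # dependent noise gives a connected multi-node network
  for (s in 1:20) {
    set.seed(s)
    z <- rnorm(5000)
    gn <- trivariate_grid(1:5000, z + 0.5 * rnorm(5000),
                          z + 0.5 * rnorm(5000), z + 0.5 * rnorm(5000))
    nn <- build_transition_network(gn, 1)
    expect_gte(nn$n_nodes, 2)
    ig <- igraph::graph_from_adjacency_matrix(
      (function(A) { diag(A) <- 0; A })(nn$adjacency), mode = "undirected")
    expect_equal(igraph::components(ig)$no, 1)
  }

  # time reversal leaves the undirected construction unchanged
  set.seed(42)
  gr <- trivariate_grid(1:800, rnorm(800), rnorm(800), rnorm(800))
  n1 <- build_transition_network(gr, 1)
  grev <- trivariate_grid(1:800, rev(gr$hr), rev(gr$dc), rev(gr$act))
  n2 <- build_transition_network(grev, 1)
  expect_equal(n1$n_nodes, n2$n_nodes)
  expect_equal(sort(paste(n1$edges[, 1], n1$edges[, 2])),
               sort(paste(n2$edges[, 1], n2$edges[, 2])))
  expect_equal(n1$self_loops, n2$self_loops)
})

test_that("the MSNR block has the pinned 220-feature layout", {
  mk_grid <- function(seed) {
    set.seed(seed)
    trivariate_grid(1:600, rnorm(600, 80), rnorm(600, 5), rnorm(600, 40))
  }
  ens <- lapply(4:6, mk_grid)
  b <- msnr_block(ens, scales = 1:10)
  expect_length(b, 220)
  expect_equal(sum(grepl("_mean$", names(b))), 110)
  expect_equal(sum(grepl("_var$", names(b))), 110)
  expect_true(all(b[grepl("_var$", names(b))] >= 0))

  same <- msnr_block(list(mk_grid(9), mk_grid(9)), scales = c(1, 3))
  expect_true(all(same[grepl("_var$", names(same))] == 0))

  b2 <- msnr_block(ens[c(2, 3, 1)], scales = 1:10)
  expect_equal(b, b2)
})
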
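test_that("self-loop augmentation sets the diagonal and saturates at 1", {
  # empty graph -> identity
  empty <- regulation_network(adjacency = matrix(0, 3, 3), genes = c("a", "b", "c"))
  expect_equal(unname(add_self_loops(empty)$adjacency), diag(3))

  # single edge 1 -> 2 on two nodes
  net <- regulation_network(
    tibble::tibble(source_gene = "a", target_gene = "b"),
    genes = c("a", "b")
  )
  expect_equal(unname(add_self_loops(net)$adjacency),
               matrix(c(1, 0, 1, 1), 2, 2))

  # pre-existing self-loops saturate: oracle is elementwise max(A, I)
  for (seed in 1:5) {
    A <- withr::with_seed(seed, {
      A <- matrix(rbinom(25, 1, 0.4), 5, 5)
      A
    })
    net <- regulation_network(adjacency = A, genes = paste0("g", 1:5))
    expect_equal(unname(add_self_loops(net)$adjacency),
                 pmax(A, diag(5)))
  }
})

test_that("non-binary and non-square adjacency are rejected with location", {
  A <- matrix(0, 2, 2)
  A[1, 2] <- 2
  net <- structure(list(genes = c("a", "b"), adjacency = A, directed = TRUE),
                   class = "regulation_network")
  expect_error(add_self_loops(net), "\\(1, 2\\)")
  expect_error(regulation_network(adjacency = matrix(0, 2, 3)), "square")
})

test_that("degree operator matches hand-computed in/out degrees", {
  # symmetric triangle + self-loops: every in-degree 3
  tri <- add_self_loops(triangle_network())
  expect_equal(unname(build_degree_operator(tri, mode = "in")$diag_values),
               rep(1 / 3, 3))

  # chain 1->2->3 + self-loops, in-degrees 1, 2, 2
  ch <- add_self_loops(chain_network())
  expect_equal(unname(build_degree_operator(ch, mode = "in")$diag_values),
               c(1, 1 / 2, 1 / 2))
  # out-degrees 2, 2, 1
  expect_equal(unname(build_degree_operator(ch, mode = "out")$diag_values),
               c(1 / 2, 1 / 2, 1))
})

test_that("raw networks get the signed -1/|E| fallback for zero degrees", {
  raw <- regulation_network(tibble::tibble(source_gene = "a", target_gene = "b"),
                            genes = c("a", "b"))
  d <- build_degree_operator(raw, mode = "in", allow_raw = TRUE)
  expect_equal(unname(d$diag_values), c(-1, 1))
  expect_false(d$built_on_selfloops)

  # isolated node also receives -1/|E|
  raw3 <- regulation_network(tibble::tibble(source_gene = "a", target_gene = "b"),
                             genes = c("a", "b", "c"))
  d3 <- build_degree_operator(raw3, mode = "in", allow_raw = TRUE)
  expect_equal(unname(d3$diag_values), c(-1, 1, -1))

  # refusing raw networks without the flag, and fully empty raw networks
  expect_error(build_degree_operator(raw), "self-loops")
  empty <- regulation_network(adjacency = matrix(0, 2, 2), genes = c("a", "b"))
  expect_error(build_degree_operator(empty, allow_raw = TRUE), "degenerate")
})

test_that("every degree operator diagonal is nonzero and invertible on random digraphs", {
  for (seed in 1:100) {
    G <- withr::with_seed(seed, sample(3:50, 1))
    raw <- rand_digraph(G, 0.1, seed = seed + 1000)
    # augmented network: standard path
    aug <- add_self_loops(raw)
    d_aug <- build_degree_operator(aug, mode = "in")
    expect_true(all(d_aug$diag_values != 0))
    # raw network with allow_raw: sources (in-degree 0) get the fallback
    if (sum(raw$adjacency) > 0) {
      d_raw <- build_degree_operator(raw, mode = "in", allow_raw = TRUE)
      expect_true(all(d_raw$diag_values != 0))
      expect_true(all(is.finite(1 / d_raw$diag_values)))
      expect_gt(rcond(diag(d_raw$diag_values)), 0)
    }
  }
})

test_that("propagation reduces to identity on a self-loop-only graph", {
  net <- add_self_loops(
    regulation_network(adjacency = matrix(0, 4, 4), genes = paste0("g", 1:4))
  )
  d <- build_degree_operator(net)
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(unname(propagate_layer(H, net, d)), H)
})

test_that("row-stochastic preservation on symmetric graphs", {
  tri <- add_self_loops(triangle_network())
  d <- build_degree_operator(tri)
  ones <- matrix(1, 3, 1)
  expect_equal(unname(propagate_layer(ones, tri, d)), ones)
})

test_that("propagate_layer equals the explicit double-loop oracle", {
  for (seed in 1:50) {
    G <- withr::with_seed(seed, sample(2:20, 1))
    K <- withr::with_seed(seed + 1, sample(1:5, 1))
    net <- add_self_loops(rand_digraph(G, 0.3, seed = seed + 2000))
    d <- build_degree_operator(net, mode = "in")
    H <- withr::with_seed(seed + 3000, matrix(rnorm(G * K), G, K))
    expect_equal(unname(propagate_layer(H, net, d)),
                 propagate_loop_oracle(net$adjacency, d$diag_values, H),
                 tolerance = 1e-12)
  }
})

test_that("in and out modes coincide and rows are stochastic on symmetric graphs", {
  for (seed in 1:20) {
    G <- withr::with_seed(seed, sample(3:30, 1))
    raw <- rand_digraph(G, 0.2, seed = seed + 4000)
    sym_adj <- pmax(raw$adjacency, t(raw$adjacency))
    net <- add_self_loops(
      regulation_network(adjacency = sym_adj, genes = raw$genes, directed = FALSE)
    )
    d_in <- build_degree_operator(net, mode = "in")
    d_out <- build_degree_operator(net, mode = "out")
    expect_identical(d_in$diag_values, d_out$diag_values)
    P <- d_in$diag_values * net$adjacency
    expect_equal(unname(rowSums(P)), rep(1, G), tolerance = 1e-12)
  }
})

test_that("dimension mismatches are reported with shapes", {
  net <- add_self_loops(chain_network())
  d <- build_degree_operator(net)
  expect_error(propagate_layer(matrix(0, 2, 1), net, d), "2 rows.*3 genes")
})

test_that("weight diffusion on the 3-chain matches the hand-computed step", {
  net <- chain_network()
  h0 <- matrix(c(0, 0, 1), 3, 1, dimnames = list(net$genes, "c1"))
  w <- extract_weights(net, h0, propagation_config(n_layers = 1))
  expect_equal(unname(drop(w)), c(0, 1 / 2, 1 / 2))
})

test_that("zero layers and edgeless graphs leave the initial weights unchanged", {
  net <- rand_digraph(6, 0.3, seed = 7)
  H0 <- withr::with_seed(8, matrix(rbinom(12, 1, 0.3), 6, 2))
  rownames(H0) <- net$genes
  expect_equal(extract_weights(net, H0, propagation_config(n_layers = 0)), H0)

  lonely <- regulation_network(adjacency = matrix(0, 6, 6), genes = net$genes)
  for (L in c(1, 3)) {
    w <- extract_weights(lonely, H0, propagation_config(n_layers = L))
    expect_equal(unname(w), unname(H0))
  }
})

test_that("diffusion is linear in the initial weights under identity activation", {
  net <- rand_digraph(12, 0.25, seed = 21)
  H0 <- withr::with_seed(22, matrix(runif(36), 12, 3))
  rownames(H0) <- net$genes
  cfg <- propagation_config(n_layers = 2)
  for (c in c(0.5, 3, -2)) {
    expect_equal(extract_weights(net, c * H0, cfg),
                 c * extract_weights(net, H0, cfg),
                 tolerance = 1e-12)
  }
})

test_that("a one-hot weight stays within L reverse-edge hops of the hot gene", {
  for (seed in 1:10) {
    net <- rand_digraph(15, 0.15, seed = seed + 5000)
    hot <- withr::with_seed(seed, sample(15, 1))
    H0 <- matrix(0, 15, 1, dimnames = list(net$genes, "c1"))
    H0[hot, 1] <- 1
    A_aug <- pmax(net$adjacency, diag(15))
    for (L in 1:3) {
      w <- extract_weights(net, H0, propagation_config(n_layers = L))
      # nodes with a directed path of length <= L into the hot node
      reach <- (Reduce(`%*%`, rep(list(A_aug), L)))[, hot] > 0
      expect_true(all(w[!reach, 1] == 0))
    }
  }
})

test_that("gene-order mismatch between network and weights is caught", {
  net <- chain_network()
  H0 <- matrix(0, 3, 1, dimnames = list(c("g1", "g3", "g2"), "c1"))
  expect_error(extract_weights(net, H0), "mismatch.*position 2")
})

test_that("edge lists round-trip through TSV and collapse duplicates", {
  edges <- tibble::tibble(source_gene = c("a", "b", "a"),
                          target_gene = c("b", "c", "b"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(edges, path)
  expect_warning(back <- read_edge_list(path), "duplicate")
  expect_equal(nrow(back), 2)
  expect_warning(regulation_network(edges), "duplicate")
})
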
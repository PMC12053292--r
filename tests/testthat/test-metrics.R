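test_that("canonical graphs give textbook attribute values", {
  K4 <- complete_graph(4)
  expect_equal(clustering_coefficient(K4), 1)
  expect_equal(as.numeric(characteristic_path_length(K4)), 1)
  expect_equal(global_efficiency(K4), 1)
  expect_equal(local_efficiency(K4), 1)

  st <- star_graph(5)
  expect_equal(clustering_coefficient(st), 0)
  expect_equal(as.numeric(characteristic_path_length(st)), 1.6)
  expect_equal(global_efficiency(st), 0.7)
  expect_equal(unname(nodal_efficiency(st, 1)), 1)
  expect_equal(unname(nodal_efficiency(st, 2)), 0.625)
  expect_equal(unname(degree_centrality(st, 1)), 4)
  expect_equal(unname(betweenness_centrality(st, 1)), 6)

  pg <- path_graph(3)
  expect_equal(as.numeric(characteristic_path_length(pg)), 4 / 3)
  expect_equal(unname(betweenness_centrality(pg)), c(0, 1, 0))
})

test_that("all attributes match the brute-force oracle on random graphs", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    A <- random_adjacency(n, p = runif(1, 0.25, 0.7))
    o <- oracle_global_metrics(A)
    expect_equal(clustering_coefficient(A), o$Cp, tolerance = 1e-12)
    expect_equal(as.numeric(characteristic_path_length(A, warn = FALSE)),
                 o$Lp, tolerance = 1e-12)
    expect_equal(global_efficiency(A), o$Eg, tolerance = 1e-12)
    expect_equal(local_efficiency(A), o$Eloc, tolerance = 1e-12)
    expect_equal(unname(nodal_efficiency(A)), o$Ne, tolerance = 1e-12)
    expect_equal(unname(degree_centrality(A)), o$Dc, tolerance = 1e-12)
    expect_equal(unname(betweenness_centrality(A)), o$Bc, tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases Eg nor increases reachable-pair Lp", {
  set.seed(17)
  for (rep in 1:10) {
    A <- random_adjacency(8, 0.35)
    holes <- which(upper.tri(A) & A == 0)
    if (!length(holes)) next
    e <- sample(holes, 1)
    B <- A
    B[e] <- 1
    B <- pmax(B, t(B))
    expect_gte(global_efficiency(B), global_efficiency(A))
    DA <- oracle_distances(A)
    DB <- oracle_distances(B)
    both <- is.finite(DA) & row(DA) != col(DA)
    if (any(both))
      expect_lte(mean(DB[both]), mean(DA[both]))
  }
})

test_that("attributes are invariant under node relabelling", {
  set.seed(23)
  A <- random_adjacency(9, 0.4)
  p <- sample(9)
  B <- A[p, p]
  expect_equal(clustering_coefficient(B), clustering_coefficient(A))
  expect_equal(global_efficiency(B), global_efficiency(A))
  expect_equal(unname(nodal_efficiency(B)), unname(nodal_efficiency(A))[p])
  expect_equal(unname(betweenness_centrality(B)),
               unname(betweenness_centrality(A))[p])
})

test_that("equal-weight weighted networks reduce to the binary computation", {
  set.seed(31)
  A <- random_adjacency(8, 0.4)
  W <- A * 1  # weights all exactly 1
  wn <- structure(list(adjacency = W, mode = "weighted"),
                  class = "imn_network")
  bn <- structure(list(adjacency = A, mode = "binary"),
                  class = "imn_network")
  expect_equal(global_efficiency(wn), global_efficiency(bn))
  expect_equal(clustering_coefficient(wn), clustering_coefficient(bn))
  expect_equal(unname(degree_centrality(wn)), unname(degree_centrality(bn)))
  expect_equal(unname(betweenness_centrality(wn)),
               unname(betweenness_centrality(bn)))
})

test_that("weighted conventions: strength degree and inverse-weight paths", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.25
  wn <- structure(list(adjacency = W, mode = "weighted"),
                  class = "imn_network")
  expect_equal(unname(degree_centrality(wn)), c(0.5, 0.75, 0.25))
  # path lengths are 1/w: d(1,3) = 2 + 4 = 6
  expect_equal(as.numeric(characteristic_path_length(wn, warn = FALSE)),
               mean(c(2, 4, 6)))
})

test_that("small-world indices behave on canonical constructions", {
  expect_equal(unname(small_world(complete_graph(6), n_null = 3, seed = 1)),
               c(1, 1, 1))
  set.seed(5)
  ws <- watts_strogatz(60, 6, 0.05)
  sw <- small_world(ws, n_null = 10, seed = 2)
  expect_gt(sw["gamma"], 1.5)
  expect_gt(sw["sigma"], 1)
  # fixed seed reproduces exactly
  expect_identical(sw, small_world(ws, n_null = 10, seed = 2))
})

test_that("AUC integration follows the trapezoid rule on the default grid", {
  g <- sparsity_grid()
  expect_equal(auc_over_sparsity(rep(1, length(g)), g), 0.33)
  expect_equal(auc_over_sparsity(g, g), 0.5 * (0.393^2 - 0.063^2),
               tolerance = 1e-12)
  expect_equal(auc_over_sparsity(c(1, 3), c(0.1, 0.2)), 0.2)
  expect_warning(res <- auc_over_sparsity(c(1, NaN, 2), c(0.1, 0.2, 0.3)),
                 "NaN")
  expect_true(is.nan(res))
})

test_that("disconnected graphs are flagged and Lp averages reachable pairs", {
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  expect_warning(lp <- characteristic_path_length(A), "disconnected")
  expect_true(attr(lp, "disconnected"))
  expect_equal(as.numeric(lp), 1)
  expect_error(characteristic_path_length(matrix(0, 4, 4)), "no edges")
})
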
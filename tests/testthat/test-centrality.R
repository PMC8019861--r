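star5 <- function() {
  g <- igraph::make_star(5, mode = "undirected")
  igraph::V(g)$name <- c("C", "L1", "L2", "L3", "L4")
  g
}

test_that("star graph closed forms hold for all five measures", {
  tab <- suppressWarnings(compute_all(star5()))
  center <- tab[tab$node == "C", ]
  leaves <- tab[tab$node != "C", ]
  expect_equal(center$degree, 4)
  expect_equal(center$betweenness, 1)       # all 6 pairs through C
  expect_equal(center$closeness, 1)
  expect_equal(center$centroid_value, 3)
  expect_equal(center$eigenvector, 1 / sqrt(2), tolerance = 1e-8)
  expect_equal(leaves$degree, rep(1, 4))
  expect_equal(leaves$betweenness, rep(0, 4))
  expect_equal(leaves$closeness, rep(4 / 7, 4))
  expect_equal(leaves$centroid_value, rep(-3, 4))
  expect_equal(leaves$eigenvector, rep(sqrt(1 / 8), 4),
               tolerance = 1e-8)
})

test_that("path and complete-graph closed forms hold", {
  p3 <- igraph::make_graph(~ a - b, b - c)
  tab <- compute_all(p3)
  expect_equal(tab$betweenness[tab$node == "b"], 1)
  expect_equal(tab$betweenness[tab$node != "b"], c(0, 0))
  expect_equal(tab$closeness, c(2 / 3, 1, 2 / 3))
  expect_equal(tab$centroid_value, c(-1, 1, -1))
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  tab4 <- compute_all(k4)
  expect_equal(tab4$degree, rep(3, 4))
  expect_equal(tab4$betweenness, rep(0, 4))
  expect_equal(tab4$closeness, rep(1, 4))
  expect_equal(tab4$centroid_value, rep(0, 4))
  expect_equal(tab4$eigenvector, rep(0.5, 4), tolerance = 1e-8)
})

test_that("a single edge is handled at the n = 2 boundary", {
  e <- igraph::make_graph(~ A - B)
  expect_warning(tab <- compute_all(e), "n < 3")
  expect_equal(tab$degree, c(1, 1))
  expect_equal(tab$betweenness, c(0, 0))
  expect_equal(tab$closeness, c(1, 1))
  expect_equal(tab$centroid_value, c(0, 0))
  expect_equal(tab$eigenvector, rep(1 / sqrt(2), 2), tolerance = 1e-8)
})

test_that("all five measures match brute-force oracles on random graphs", {
  for (s in 1:8) {
    g <- random_connected_graph(25, p = 0.15, seed = 100 + s)
    nm <- igraph::V(g)$name
    tab <- compute_all(g)
    expect_identical(tab$node, sort(nm))
    ord <- tab$node
    expect_equal(tab$degree,
                 unname(lengths(igraph::as_adj_list(g))[ord]))
    expect_equal(tab$betweenness, unname(oracle_betweenness(g)[ord]),
                 tolerance = 1e-12)
    expect_equal(tab$closeness, unname(oracle_closeness(g)[ord]),
                 tolerance = 1e-12)
    expect_identical(tab$centroid_value,
                     as.integer(oracle_centroid(g)[ord]))
    ev <- oracle_eigenvector(g)[ord]
    cosine <- sum(tab$eigenvector * ev) /
      sqrt(sum(tab$eigenvector^2) * sum(ev^2))
    expect_gt(cosine, 1 - 1e-8)
  }
})

test_that("pairwise closeness-contest scores are antisymmetric", {
  g <- random_connected_graph(15, p = 0.2, seed = 77)
  oracle_centroid(g, check_antisymmetry = TRUE)
  succeed()
})

test_that("eigenvector iteration satisfies the shifted eigen equation", {
  tol <- 1e-12
  for (s in c(5, 6)) {
    g <- random_connected_graph(20, p = 0.2, seed = s)
    x <- eigenvector_centrality(g, tol = tol)
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    x <- x[rownames(A)]
    lambda <- as.numeric(x %*% A %*% x)  # Rayleigh quotient
    resid <- max(abs((A %*% x + x) - (lambda + 1) * x))
    expect_lt(resid, 10 * tol * (lambda + 1))
  }
  # non-convergence is reported as an error
  expect_error(eigenvector_centrality(star5(), tol = 1e-15,
                                      max_iter = 2L),
               "did not converge")
})

test_that("measures are invariant under node relabeling", {
  g <- random_connected_graph(18, p = 0.2, seed = 9)
  tab <- compute_all(g)
  perm <- igraph::permute(g, sample(igraph::vcount(g)))
  tab_p <- compute_all(perm)
  merged <- merge(tab, tab_p, by = "node")
  expect_equal(merged$degree.x, merged$degree.y)
  expect_equal(merged$betweenness.x, merged$betweenness.y,
               tolerance = 1e-12)
  expect_equal(merged$closeness.x, merged$closeness.y,
               tolerance = 1e-12)
  expect_equal(merged$centroid_value.x, merged$centroid_value.y)
  expect_equal(merged$eigenvector.x, merged$eigenvector.y,
               tolerance = 1e-8)
})

test_that("adding an edge never lowers degree or the endpoint eigenvector", {
  set.seed(41)
  for (i in 1:5) {
    g <- random_connected_graph(15, p = 0.2, seed = 200 + i)
    nm <- igraph::V(g)$name
    non_edges <- which(igraph::as_adjacency_matrix(g, sparse = FALSE)
                       == 0, arr.ind = TRUE)
    non_edges <- non_edges[non_edges[, 1] < non_edges[, 2], ,
                           drop = FALSE]
    pick <- non_edges[sample(nrow(non_edges), 1), ]
    g2 <- igraph::add_edges(g, nm[pick])
    expect_equal(igraph::degree(g2)[[nm[pick[1]]]],
                 igraph::degree(g)[[nm[pick[1]]]] + 1L)
    e1 <- eigenvector_centrality(g)
    e2 <- eigenvector_centrality(g2)
    expect_gte(e2[[nm[pick[1]]]], e1[[nm[pick[1]]]] - 1e-9)
  }
})

test_that("centrality table invariants hold on a realistic network", {
  g <- generate_interactome(300, 2, 55)
  tab <- compute_all(g)
  expect_equal(nrow(tab), 300)
  expect_true(all(tab$betweenness >= 0 & tab$betweenness <= 1))
  expect_true(all(tab$closeness > 0 & tab$closeness <= 1))
  expect_true(all(tab$eigenvector >= 0))
  expect_equal(sum(tab$eigenvector^2), 1, tolerance = 1e-9)
  n <- nrow(tab)
  expect_true(all(tab$centroid_value >= -(n - 1) &
                    tab$centroid_value <= n - 2))
  expect_error(closeness_centrality(
    igraph::make_graph(~ A - B, C - D)), "disconnected")
  expect_error(centroid_value(
    igraph::make_graph(~ A - B, C - D)), "disconnected")
})
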
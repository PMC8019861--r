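# Brute-force oracles, independent of the package's implementation
# paths: Floyd-Warshall distances, exhaustive shortest-path enumeration,
# dense eigendecomposition, literal O(n^3) gamma-table, hand-rolled
# step-up adjustment and hypergeometric enumeration.

oracle_distances <- function(g) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  dimnames(D) <- list(igraph::V(g)$name, igraph::V(g)$name)
  D
}

# normalized betweenness by enumerating every shortest path
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  D <- oracle_distances(g)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  paths <- function(s, t) {
    if (s == t) return(list(t))
    res <- list()
    for (u in adj[[s]]) {
      if (D[u, t] == D[s, t] - 1) {
        for (p in paths(u, t)) res[[length(res) + 1L]] <- c(s, p)
      }
    }
    res
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      ps <- paths(s, t)
      for (p in ps) {
        interior <- p[-c(1L, length(p))]
        bc[interior] <- bc[interior] + 1 / length(ps)
      }
    }
  }
  out <- bc / ((n - 1) * (n - 2) / 2)
  names(out) <- igraph::V(g)$name
  out
}

oracle_closeness <- function(g) {
  D <- oracle_distances(g)
  (nrow(D) - 1) / rowSums(D)
}

oracle_eigenvector <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  v <- abs(v)
  names(v) <- igraph::V(g)$name
  v / sqrt(sum(v^2))
}

# literal triple-loop gamma table; also checks f antisymmetry
oracle_centroid <- function(g, check_antisymmetry = FALSE) {
  D <- oracle_distances(g)
  n <- nrow(D)
  gam <- matrix(0L, n, n)
  for (v in seq_len(n)) {
    for (u in seq_len(n)) {
      cnt <- 0L
      for (w in seq_len(n)) {
        if (D[w, v] < D[w, u]) cnt <- cnt + 1L
      }
      gam[v, u] <- cnt
    }
  }
  f <- gam - t(gam)
  if (check_antisymmetry) stopifnot(all(f == -t(f)))
  out <- vapply(seq_len(n), function(v) min(f[v, -v]), numeric(1))
  names(out) <- igraph::V(g)$name
  out
}

random_connected_graph <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(stepped))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

fisher_enum <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  x <- seq.int(max(0L, c1 - r2), min(r1, c1))
  probs <- dhyper(x, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small 15-column MITAB line builder for parser tests
mitab_line <- function(id_a, id_b, alias_a = "-", alias_b = "-",
                       source = "psi-mi:\"MI:0469\"(IntAct)") {
  paste(c(id_a, id_b, "-", "-", alias_a, alias_b, "-", "-", "-",
          "taxid:9606", "taxid:9606", "-", source, "-", "-"),
        collapse = "\t")
}

md5_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  sums
}
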
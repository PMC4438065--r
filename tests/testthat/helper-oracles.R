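# Fixture builders and independent brute-force oracles used across tests.
# Everything here is deliberately naive (set arithmetic, literal double
# sums, exhaustive enumeration) and stays independent of the package's
# computational paths.

adj_from_edges <- function(labels, edges) {
  a <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (e in edges) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  a
}

net_path3 <- function() skull_network(
  adj_from_edges(c("a", "b", "c"), list(c("a", "b"), c("b", "c"))))

net_cycle4 <- function() skull_network(
  adj_from_edges(letters[1:4],
                 list(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a"))))

net_k4 <- function() {
  a <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(a) <- 0
  skull_network(a)
}

net_star4 <- function() skull_network(  # K_{1,3}
  adj_from_edges(c("hub", "x", "y", "z"),
                 list(c("hub", "x"), c("hub", "y"), c("hub", "z"))))

# two triangles joined by one edge: 6 nodes, 7 edges
net_barbell <- function() skull_network(
  adj_from_edges(letters[1:6],
                 list(c("a", "b"), c("b", "c"), c("a", "c"),
                      c("d", "e"), c("e", "f"), c("d", "f"),
                      c("c", "d"))))

# two 4-cliques joined by one edge
net_two_cliques <- function() {
  a <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  a[1:4, 1:4] <- 1
  a[5:8, 5:8] <- 1
  diag(a) <- 0
  a[4, 5] <- a[5, 4] <- 1
  skull_network(a)
}

# exhaustive triangle count through each node
oracle_triangles <- function(a) {
  n <- nrow(a)
  tri <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    cnt <- 0
    if (length(nb) >= 2) {
      for (u in seq_along(nb)) {
        for (v in seq_len(u - 1)) {
          if (a[nb[u], nb[v]] == 1) cnt <- cnt + 1
        }
      }
    }
    tri[i] <- cnt
  }
  tri
}

# mean Watts-Strogatz clustering from the exhaustive triangle count
oracle_clustering <- function(a) {
  k <- rowSums(a)
  tri <- oracle_triangles(a)
  ci <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  mean(ci)
}

# literal Newman Q: double sum over all ordered pairs including i = j
oracle_q <- function(a, memb) {
  m2 <- sum(a)
  k <- unname(rowSums(a))
  q <- 0
  n <- nrow(a)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) q <- q + a[i, j] - k[i] * k[j] / m2
    }
  }
  q / m2
}

# all set partitions of n elements as membership vectors (Bell(n) of them)
set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in set_partitions(n - 1)) {
    for (m in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, m)
  }
  out
}

# seeded random connected G(n, p) adjacency matrix
random_connected_adj <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
    a <- a + t(a)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    if (igraph::components(g)$no == 1 && sum(a) > 0) break
  }
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}

# nested two-level planted hierarchy: 2 super-blocks of 2 sub-blocks each
nested_hierarchy_adj <- function(seed, n_sub = 6, p_sub = 0.9,
                                 p_super = 0.15, p_between = 0.02) {
  set.seed(seed)
  n <- 4 * n_sub
  sub <- rep(1:4, each = n_sub)
  super <- rep(1:2, each = 2 * n_sub)
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- if (sub[i] == sub[j]) p_sub
           else if (super[i] == super[j]) p_super
           else p_between
      if (stats::runif(1) < p) a[i, j] <- a[j, i] <- 1
    }
  }
  dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  list(a = a, sub = sub, super = super)
}

# adjusted Rand index between two memberships (via igraph, independent of
# the package's clustering path)
ari <- function(x, y) igraph::compare(as.integer(factor(x)),
                                      as.integer(factor(y)),
                                      method = "adjusted.rand")

# hand-derived Abouheif proximities for the balanced tree ((A,B),(C,D)):
# cherry mates go through one binary split (1/2), cross pairs through
# three (1/8)
abouheif_w_balanced4 <- function() {
  w <- matrix(1 / 8, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(w) <- 0
  w["A", "B"] <- w["B", "A"] <- 1 / 2
  w["C", "D"] <- w["D", "C"] <- 1 / 2
  w
}

# Cmean from an explicit proximity matrix (direct formula)
cmean_from_w <- function(w, x) {
  w <- w / rowSums(w)
  z <- x - mean(x)
  sum(z * (w %*% z)) / sum(z^2)
}
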
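test_that("TO boundary conditions and conventions hold on constructed fixtures", {
  # u, v each adjacent to exactly {x, y}, not to each other: identical
  # connection patterns, TO = 1
  shared <- skull_network(adj_from_edges(
    c("u", "v", "x", "y"),
    list(c("u", "x"), c("u", "y"), c("v", "x"), c("v", "y"))))
  to <- topological_overlap(shared)
  expect_equal(to$values["u", "v"], 1)

  # disjoint neighborhoods on a path: ends of P4 share nothing
  p4 <- skull_network(adj_from_edges(
    letters[1:4], list(c("a", "b"), c("b", "c"), c("c", "d"))))
  expect_equal(topological_overlap(p4)$values["a", "d"], 0)

  # triangle, default pair-excluded convention: one shared neighbor over
  # pair-excluded degrees min(1,1) -> 1; mutually adjacent specular-style
  # bones score 1
  tri <- skull_network(adj_from_edges(
    letters[1:3], list(c("a", "b"), c("b", "c"), c("a", "c"))))
  expect_equal(topological_overlap(tri, "open_neighborhood")$values["a", "b"], 1)
  # raw-degree convention: 1 shared neighbor / min degree 2
  expect_equal(topological_overlap(tri, "raw_degree")$values["a", "b"], 1 / 2)
  # GTOM step-1: (1 + 1)/(2 + 1 - 1)
  expect_equal(topological_overlap(tri, "gtom1")$values["a", "b"], 1)

  for (conv in c("open_neighborhood", "raw_degree", "gtom1")) {
    v <- topological_overlap(net_barbell(), conv)$values
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(v, t(v))
    expect_equal(diag(v), setNames(rep(1, 6), letters[1:6]))
  }
})

test_that("TO is permutation-equivariant under node relabeling", {
  set.seed(41)
  net <- generate_skull(n_pairs = 5, n_midline = 3, seed = 41)
  perm <- sample(length(net$bones))
  shuffled <- skull_network(net$adjacency[perm, perm])
  for (conv in c("open_neighborhood", "gtom1")) {
    v1 <- topological_overlap(net, conv)$values
    v2 <- topological_overlap(shuffled, conv)$values
    expect_equal(v2[net$bones, net$bones], v1)
  }
})

test_that("newman_q matches hand values and the literal double-sum oracle", {
  bn <- net_barbell()
  expect_equal(newman_q(bn, setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])),
               5 / 14)
  expect_equal(newman_q(bn, rep(1, 6)), 0)
  expect_error(newman_q(bn, setNames(1:3, c("a", "b", "c"))), "misses")

  for (seed in 1:10) {
    n <- 5 + seed %% 3
    a <- random_connected_adj(n, 0.5, 100 + seed)
    net <- skull_network(a)
    memb <- sample(1:3, n, replace = TRUE)
    expect_equal(newman_q(net, memb), oracle_q(a, memb), tolerance = 1e-12)
    # independent cross-check against igraph's implementation
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(newman_q(net, memb), igraph::modularity(g, memb),
                 tolerance = 1e-12)
  }
})

test_that("mean Q over random assignments matches the closed-form expectation", {
  # E[Q] under uniform random assignment into g groups is
  # sum(k^2)/(2K)^2 * (1/g - 1): near zero, slightly negative
  a <- random_connected_adj(30, 0.3, 77)
  net <- skull_network(a)
  g <- 4
  k <- rowSums(a)
  expected <- sum(k^2) / sum(a)^2 * (1 / g - 1)
  set.seed(78)
  qs <- replicate(10000, newman_q(net, sample.int(g, 30, replace = TRUE)))
  se <- sd(qs) / sqrt(length(qs))
  expect_lt(abs(mean(qs) - expected), 3 * se)
  expect_lt(abs(mean(qs)), 0.05)  # "approximately zero" on this scale
})

test_that("hierarchical_modules recovers two 4-cliques exactly, with the exhaustive-best Q", {
  net <- net_two_cliques()
  part <- hierarchical_modules(net)
  expect_equal(part$n_modules, 2)
  expect_equal(ari(part$assignment, rep(1:2, each = 4)), 1)
  # exhaustive Q maximization over all 4140 partitions of 8 nodes
  best <- max(vapply(set_partitions(8),
                     function(m) oracle_q(net$adjacency, m), numeric(1)))
  expect_equal(part$Q, best, tolerance = 1e-12)
  expect_equal(part$M, 2 * part$Q)
})

test_that("complete graphs yield the trivial single module with Q = 0", {
  a5 <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(a5) <- 0
  part <- hierarchical_modules(skull_network(a5))
  expect_equal(part$n_modules, 1)
  expect_equal(part$Q, 0)
  expect_equal(part$M, 0)
  expect_equal(modularity_strength(part), 0)
})

test_that("the selected partition beats every other dendrogram cut", {
  for (seed in c(3, 19)) {
    net <- generate_skull(n_pairs = 8, n_midline = 4, seed = seed)
    part <- hierarchical_modules(net)
    expect_true(all(part$Q >= part$q_by_k - 1e-12))
    expect_equal(part$M, part$n_modules * part$Q)
  }
})

test_that("planted two-block skulls are recovered with adjusted Rand 1", {
  truth <- setNames(rep(1:2, each = 12),
                    paste0(rep(sprintf("p%02d", 1:12), each = 2),
                           c("_l", "_r")))
  for (seed in 1:20) {
    net <- generate_skull(n_pairs = 12, n_midline = 0,
                          modular_layout = planted_layout(c(6, 6)),
                          seed = seed)
    part <- hierarchical_modules(net)
    expect_equal(ari(part$assignment[names(truth)], truth), 1)
  }
})

test_that("macromodules return the first dendrogram split with containment", {
  # planted two blocks: macromodules equal the blocks
  net <- generate_skull(n_pairs = 12, n_midline = 0,
                        modular_layout = planted_layout(c(6, 6)), seed = 5)
  part <- hierarchical_modules(net)
  mm <- part$macromodules
  expect_length(mm$members, 2)
  expect_setequal(unlist(mm$members), net$bones)
  left_units <- paste0(rep(sprintf("p%02d", 1:6), each = 2), c("_l", "_r"))
  expect_true(setequal(mm$members[[1]], left_units) ||
              setequal(mm$members[[2]], left_units))

  # nested hierarchy: optimal partition = 4 sub-blocks, first split = the
  # 2 super-blocks, every module nested in one macromodule
  h <- nested_hierarchy_adj(seed = 1)
  nnet <- skull_network(h$a)
  npart <- hierarchical_modules(nnet)
  expect_equal(npart$n_modules, 4)
  expect_equal(ari(npart$assignment, h$sub), 1)
  two <- integer(24)
  two[match(npart$macromodules$members[[1]], nnet$bones)] <- 1
  two[match(npart$macromodules$members[[2]], nnet$bones)] <- 2
  expect_equal(ari(two, h$super), 1)
  expect_false(any(npart$macromodules$containment$straddles))

  # star graph: content linkage-dependent, but deterministic
  star <- net_star4()
  m1 <- hierarchical_modules(star)$macromodules$members
  m2 <- hierarchical_modules(star)$macromodules$members
  expect_identical(m1, m2)
})

test_that("specular module pairs are detected under the l/r suffix swap", {
  part <- function(assign) structure(list(assignment = assign),
                                     class = "skull_partition")
  # exact mirror
  p1 <- part(setNames(c(1, 1, 2, 2), c("nas_l", "lac_l", "nas_r", "lac_r")))
  sp1 <- detect_specular(p1)
  expect_length(sp1, 1)
  expect_equal(sort(sp1[[1]]$modules), c(1, 2))
  expect_length(sp1[[1]]$arbitrary_bones, 0)

  # mirror with an unpaired bone riding in the left module
  p2 <- part(setNames(c(1, 1, 1, 2, 2),
                      c("nas_l", "lac_l", "vom", "nas_r", "lac_r")))
  sp2 <- detect_specular(p2)
  expect_length(sp2, 1)
  expect_equal(sp2[[1]]$arbitrary_bones, "vom")

  # not mirrors
  p3 <- part(setNames(c(1, 2), c("nas_l", "lac_r")))
  expect_length(detect_specular(p3), 0)

  # no side suffixes at all
  p4 <- part(setNames(c(1, 2), c("occ", "vom")))
  expect_length(detect_specular(p4), 0)
})

test_that("anchor bones label the four module types with occ > eth > pal > pmx priority", {
  part <- function(assign) structure(list(assignment = assign),
                                     class = "skull_partition")
  p <- part(setNames(c(1, 1, 1, 1, 1, 1, 2, 2, 2, 3, 3, 4),
                     c("occ", "par_l", "par_r", "tem_l", "tem_r", "sph",
                       "eth", "lac_l", "lac_r",
                       "pal_l", "pal_r",
                       "pmx_l")))
  labs <- label_modules(p)
  expect_equal(unname(labs[c("1", "2", "3")]),
               c("neurocranial", "midfacial", "palatal"))
  expect_equal(unname(labs["4"]), "premaxillary_l")

  # palatines grouped with the vomer still label palatal
  p2 <- part(setNames(c(1, 1, 1, 2), c("pal_l", "pal_r", "vom", "occ")))
  expect_equal(unname(label_modules(p2)["1"]), "palatal")

  # lone non-anchor module is unlabeled
  p3 <- part(setNames(c(1, 2, 2, 2), c("zyg_l", "occ", "pal_l", "pal_r")))
  expect_equal(unname(label_modules(p3)["1"]), "unlabeled")

  # conflict: occ and eth in one module -> neurocranial wins, logged
  p4 <- part(setNames(c(1, 1, 2), c("occ", "eth", "vom")))
  labs4 <- label_modules(p4)
  expect_equal(unname(labs4["1"]), "neurocranial")
  expect_match(attr(labs4, "conflicts"), "neurocranial,midfacial")

  # only part of the palatines -> not palatal
  p5 <- part(setNames(c(1, 2, 2), c("pal_l", "pal_r", "occ")))
  expect_equal(unname(label_modules(p5)["1"]), "unlabeled")
})
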
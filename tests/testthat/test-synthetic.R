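test_that("generated skulls are valid, mirrored, and hit the target density", {
  for (seed in 1:15) {
    net <- generate_skull(n_pairs = 9, n_midline = 6, target_density = 0.25,
                          seed = seed)
    expect_silent(validate_skull_network(net))
    expect_equal(length(net$bones), 24)
    expect_lt(abs(net_density(net) - 0.25), 0.05)
    # mirrored-edge property: (a_l, b_l) present iff (a_r, b_r) present
    a <- net$adjacency
    lefts <- net$bones[grepl("_l$", net$bones)]
    rights <- sub("_l$", "_r", lefts)
    expect_equal(unname(a[lefts, lefts]), unname(a[rights, rights]))
    mids <- net$bones[!grepl("_[lr]$", net$bones)]
    expect_equal(unname(a[lefts, mids]), unname(a[rights, mids]))
  }
})

test_that("generators are bit-reproducible given seeds", {
  n1 <- generate_skull(7, 4, seed = 99)
  n2 <- generate_skull(7, 4, seed = 99)
  expect_identical(n1$adjacency, n2$adjacency)
  t1 <- generate_tree(15, seed = 88)
  t2 <- generate_tree(15, seed = 88)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  x1 <- simulate_bm_trait(t1, seed = 77)
  x2 <- simulate_bm_trait(t2, seed = 77)
  expect_identical(x1, x2)
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_skull(5, 2, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generated skulls at the default scale look like real primate skulls", {
  # N, K, D of 9-pair/5-midline skulls at density 0.25 fall in the observed
  # ranges for adult primate skulls: N 21-24, K 60-74, D 0.22-0.30
  for (seed in 1:10) {
    prof <- complexity_profile(generate_skull(9, 5, seed = seed,
                                              bone_names = primate_bone_names()))
    expect_equal(prof$N, 23)
    expect_true(prof$K >= 60 && prof$K <= 74)
    expect_true(prof$D >= 0.2174 && prof$D <= 0.3048)
  }
})

test_that("planted layouts produce the declared block structure", {
  net <- generate_skull(12, 0, modular_layout = planted_layout(c(6, 6)),
                        seed = 31)
  a <- net$adjacency
  block1 <- paste0(rep(sprintf("p%02d", 1:6), each = 2), c("_l", "_r"))
  block2 <- setdiff(net$bones, block1)
  within <- (sum(a[block1, block1]) + sum(a[block2, block2])) / 2
  between <- sum(a[block1, block2])
  # density contrast: within-block edge fraction far above between
  expect_gt(within / (2 * choose(12, 2)), 5 * between / 144)
  expect_error(generate_skull(4, 0, modular_layout = planted_layout(c(2, 3)),
                              seed = 1), "units")
})

test_that("bone loss and fusion perturb the network as defined", {
  net <- generate_skull(9, 5, seed = 13, bone_names = primate_bone_names())
  # fuse the two frontals? frontal is midline here; fuse an adjacent pair
  a <- net$adjacency
  adj_pair <- NULL
  for (b in c("par", "nas", "pmx", "pal")) {
    if (a[paste0(b, "_l"), paste0(b, "_r")] == 1) {
      adj_pair <- paste0(b, c("_l", "_r")); break
    }
  }
  if (is.null(adj_pair)) {
    # guarantee an adjacent pair to fuse
    a["nas_l", "nas_r"] <- a["nas_r", "nas_l"] <- 1
    net <- skull_network(a, taxon = net$taxon)
    adj_pair <- c("nas_l", "nas_r")
  }
  fused <- perturb_network(net, "fuse_bones", adj_pair)
  expect_equal(length(fused$bones), length(net$bones) - 1)
  merged_name <- sub("_l$", "", adj_pair[1])
  expect_true(merged_name %in% fused$bones)
  # merged neighborhood = union of the two, minus the internal contact
  nb_expected <- setdiff(
    net$bones[net$adjacency[adj_pair[1], ] == 1 |
              net$adjacency[adj_pair[2], ] == 1], adj_pair)
  nb_got <- fused$bones[fused$adjacency[merged_name, ] == 1]
  expect_setequal(nb_got, nb_expected)

  expect_error(perturb_network(net, "fuse_bones", c("par_l", "xxx")),
               "unknown bone")
  nonadj <- which(net$adjacency == 0 & upper.tri(net$adjacency),
                  arr.ind = TRUE)[1, ]
  expect_error(perturb_network(net, "fuse_bones",
                               net$bones[c(nonadj[1], nonadj[2])]),
               "non-adjacent")

  # losing a degree-1 bone drops exactly one contact
  star <- net_star4()
  lost <- perturb_network(star, "lose_bone", "x")
  expect_equal(sum(lost$adjacency) / 2, 2)
  expect_false("x" %in% lost$bones)
  # losing the hub would disconnect
  expect_error(perturb_network(star, "lose_bone", "hub"), "disconnects")
})

test_that("fusing adjacent high-degree bones in a dense block raises density", {
  # constructed case: fuse two hubs of a dense cluster
  net <- net_two_cliques()
  fused <- perturb_network(net, "fuse_bones", c("a", "b"))
  expect_gte(net_density(fused), net_density(net))
})

test_that("Yule trees are bifurcating, ultrametric at unit height, and sized correctly", {
  expect_error(generate_tree(1, seed = 1), "at least 2")
  t2 <- generate_tree(2, seed = 2)
  expect_equal(length(t2$tip.label), 2)
  t20 <- generate_tree(20, seed = 3)
  expect_true(ape::is.binary(t20))
  expect_true(ape::is.ultrametric(t20, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(t20)), 1)
  expect_equal(t20$Nnode, 19)  # 19 internal contrasts available
})

test_that("the BM simulator obeys the degenerate limit and covariance ordering", {
  tree <- generate_tree(6, seed = 4)
  tiny <- simulate_bm_trait(tree, sigma2 = 1e-12, root_value = 3, seed = 5)
  expect_equal(unname(tiny), rep(3, 6), tolerance = 1e-4)
  expect_error(simulate_bm_trait(tree, sigma2 = 0, seed = 1), "positive")

  # cherry tips covary more than tips across the root
  t4 <- read_newick_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tips <- t(vapply(1:1500, function(i)
    simulate_bm_trait(t4, seed = 9000 + i), numeric(4)))
  cv <- cov(tips)
  expect_gt(cv["A", "B"], cv["A", "C"] + 0.5)
  expect_gt(cv["C", "D"], cv["B", "D"] + 0.5)
})
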
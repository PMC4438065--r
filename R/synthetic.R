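# evaluate expr under a given seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Standard primate skull bone names
#'
#' The fourteen bones of the primate skull roof, face and base commonly
#' coded in bone-contact networks: nine bilateral pairs (parietal,
#' temporal, zygomatic, lacrimal, nasal, nasal concha, palatine,
#' premaxilla, maxilla) and five midline bones (occipital, sphenoid,
#' frontal -- unpaired in haplorrhines --, ethmoid, vomer), for 23 nodes
#' in total.
#'
#' @return list with character vectors \code{pairs} and \code{midline}.
#' @export
primate_bone_names <- function() {
  list(pairs = c("par", "tem", "zyg", "lac", "nas", "nch", "pal", "pmx",
                 "max"),
       midline = c("occ", "sph", "fro", "eth", "vom"))
}

#' Planted modular layout for the skull generator
#'
#' Describes a block structure to plant into a generated network: bones
#' are grouped into blocks and edges are sampled densely within blocks and
#' sparsely between them. Blocks are defined over the left-side units of
#' the generator (each bilateral pair is one unit; each midline bone one
#' unit), so the planted structure respects the mirrored symmetry.
#'
#' @param sizes integer vector of block sizes over the
#'   \code{n_pairs + n_midline} units, in generator order (pairs first,
#'   then midline).
#' @param p_within probability of an edge orbit inside a block (default
#'   0.9).
#' @param p_between probability between blocks (default 0.05).
#' @return list usable as \code{modular_layout} in [generate_skull()].
#' @export
planted_layout <- function(sizes, p_within = 0.9, p_between = 0.05) {
  list(blocks = rep(seq_along(sizes), sizes),
       p_within = p_within, p_between = p_between)
}

#' Generate a bilaterally symmetric skull-like network
#'
#' Builds a random connected bone-contact network with the scale and
#' structure of real skull codings: \code{n_pairs} bilateral bone pairs
#' (labeled \code{<base>_l}/\code{<base>_r}) plus \code{n_midline}
#' unpaired midline bones. Edges are sampled by symmetry orbit -- a
#' left-side contact is always mirrored on the right, and a midline bone
#' touches both members of a pair or neither -- so the result is exactly
#' bilaterally symmetric (an optional asymmetry rate relaxes this for
#' robustness experiments).
#'
#' Without a layout, orbits are activated in random order until the edge
#' count reaches \code{round(target_density * N(N-1)/2)}, so the realized
#' density lands on the target up to orbit granularity. With a
#' [planted_layout()], each orbit is kept with the within- or
#' between-block probability, planting recoverable community structure.
#' If the sampled graph is disconnected it is repaired by adding minimal
#' bridging orbits (recorded in attribute \code{"repaired_orbits"}).
#'
#' @param n_pairs number of bilateral bone pairs.
#' @param n_midline number of unpaired midline bones;
#'   \code{2 * n_pairs + n_midline >= 3}.
#' @param target_density desired edge density in (0, 1); default 0.25, the
#'   typical density of primate skull networks.
#' @param modular_layout optional [planted_layout()].
#' @param seed integer RNG seed; output is bit-reproducible given the seed.
#' @param asymmetry_rate probability that an activated sided orbit keeps
#'   only one of its two mirrored edges (default 0 = perfect symmetry).
#' @param bone_names optional list with \code{pairs} and \code{midline}
#'   base-name vectors (e.g. [primate_bone_names()]); generic names
#'   otherwise.
#' @param taxon taxon label for the generated network.
#' @return a validated [skull_network()].
#' @examples
#' net <- generate_skull(n_pairs = 9, n_midline = 5, seed = 1,
#'                       bone_names = primate_bone_names())
#' complexity_profile(net)
#' @export
generate_skull <- function(n_pairs, n_midline, target_density = 0.25,
                           modular_layout = NULL, seed = 1,
                           asymmetry_rate = 0, bone_names = NULL,
                           taxon = paste0("synthetic_", seed)) {
  n <- 2 * n_pairs + n_midline
  if (n < 3) stop("need at least 3 bones in total", call. = FALSE)
  if (target_density <= 0 || target_density >= 1)
    stop("target_density must be in (0,1)", call. = FALSE)
  if (is.null(bone_names)) {
    pair_names <- sprintf("p%02d", seq_len(n_pairs))
    mid_names <- sprintf("m%02d", seq_len(n_midline))
  } else {
    pair_names <- bone_names$pairs[seq_len(n_pairs)]
    mid_names <- bone_names$midline[seq_len(n_midline)]
  }
  bones <- c(paste0(rep(pair_names, each = 2), c("_l", "_r")), mid_names)
  left <- function(i) 2 * i - 1
  right <- function(i) 2 * i
  mid <- function(i) 2 * n_pairs + i

  # symmetry orbits: each entry is a 2-column matrix of node-index pairs
  orbits <- list()
  units <- integer(0)  # (unit_a, unit_b) per orbit, for planted layouts
  add_orbit <- function(pairs, ua, ub) {
    orbits[[length(orbits) + 1]] <<- pairs
    units <<- rbind(units, c(ua, ub))
  }
  if (n_pairs >= 2) {
    for (a in seq_len(n_pairs - 1)) {
      for (b in seq(a + 1, n_pairs)) {
        add_orbit(rbind(c(left(a), left(b)), c(right(a), right(b))), a, b)
        add_orbit(rbind(c(left(a), right(b)), c(right(a), left(b))), a, b)
      }
    }
  }
  for (a in seq_len(n_pairs))            # left-right contact of one pair
    add_orbit(rbind(c(left(a), right(a))), a, a)
  if (n_pairs > 0 && n_midline > 0) {
    for (a in seq_len(n_pairs)) {
      for (m in seq_len(n_midline)) {
        add_orbit(rbind(c(left(a), mid(m)), c(right(a), mid(m))),
                  a, n_pairs + m)
      }
    }
  }
  if (n_midline >= 2) {
    for (m1 in seq_len(n_midline - 1)) {
      for (m2 in seq(m1 + 1, n_midline)) {
        add_orbit(rbind(c(mid(m1), mid(m2))), n_pairs + m1, n_pairs + m2)
      }
    }
  }

  adj <- matrix(0, n, n, dimnames = list(bones, bones))
  activate <- function(adj, orbit_pairs, drop_one_side) {
    if (drop_one_side && nrow(orbit_pairs) == 2)
      orbit_pairs <- orbit_pairs[sample.int(2, 1), , drop = FALSE]
    adj[orbit_pairs] <- 1
    adj[orbit_pairs[, c(2, 1), drop = FALSE]] <- 1
    adj
  }
  repaired <- 0L
  adj <- with_seed(seed, {
    if (is.null(modular_layout)) {
      target_k <- round(target_density * n * (n - 1) / 2)
      ord <- sample.int(length(orbits))
      for (o in ord) {
        if (sum(adj) / 2 >= target_k) break
        adj <- activate(adj, orbits[[o]],
                        asymmetry_rate > 0 &&
                          stats::runif(1) < asymmetry_rate)
      }
    } else {
      blocks <- modular_layout$blocks
      if (length(blocks) != n_pairs + n_midline)
        stop("modular_layout covers ", length(blocks), " units but generator has ",
             n_pairs + n_midline, call. = FALSE)
      for (o in seq_along(orbits)) {
        p <- if (blocks[units[o, 1]] == blocks[units[o, 2]])
          modular_layout$p_within else modular_layout$p_between
        if (stats::runif(1) < p)
          adj <- activate(adj, orbits[[o]],
                          asymmetry_rate > 0 &&
                            stats::runif(1) < asymmetry_rate)
      }
    }
    # connectivity repair: bridge components with whole orbits so the
    # mirrored symmetry survives
    repeat {
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      comp <- igraph::components(g)
      if (comp$no == 1) break
      a <- min(which(comp$membership == 1)[1],
               which(comp$membership == 2)[1])
      b <- max(which(comp$membership == 1)[1],
               which(comp$membership == 2)[1])
      bridge <- which(vapply(orbits, function(o)
        any(o[, 1] == a & o[, 2] == b), logical(1)))[1]
      adj <- activate(adj, orbits[[bridge]], FALSE)
      repaired <- repaired + 1L
    }
    adj
  })
  net <- skull_network(adj, taxon = taxon)
  attr(net, "repaired_orbits") <- repaired
  net
}

#' Perturb a skull network by bone loss or fusion
#'
#' The two evolutionary operations that reshape skull networks: losing a
#' bone (node deletion) or fusing two adjacent bones into one (node merge:
#' neighborhoods union, the internal contact disappears, duplicate
#' contacts collapse). Both return a validated network; a loss that would
#' disconnect the skull, or a fusion of non-adjacent bones, is an error.
#'
#' @param net a [skull_network()].
#' @param op \code{"lose_bone"} or \code{"fuse_bones"}.
#' @param target the bone to lose, or the two adjacent bones to fuse.
#' @param fused_label label for the merged bone; defaults to the shared
#'   base name when fusing a left/right pair (e.g. \code{fro_l + fro_r ->
#'   fro}), otherwise the two labels joined by \code{"+"}.
#' @return the perturbed [skull_network()].
#' @export
perturb_network <- function(net, op = c("lose_bone", "fuse_bones"), target,
                            fused_label = NULL) {
  op <- match.arg(op)
  a <- net$adjacency
  missing <- setdiff(target, net$bones)
  if (length(missing) > 0)
    stop("unknown bone(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (op == "lose_bone") {
    if (length(target) != 1) stop("lose_bone takes one bone", call. = FALSE)
    keep <- setdiff(net$bones, target)
    a2 <- a[keep, keep, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(a2, mode = "undirected")
    if (igraph::components(g)$no > 1)
      stop("removing '", target, "' disconnects the network", call. = FALSE)
    return(skull_network(a2, taxon = net$taxon))
  }
  if (length(target) != 2) stop("fuse_bones takes two bones", call. = FALSE)
  if (a[target[1], target[2]] != 1)
    stop("cannot fuse non-adjacent bones '", target[1], "' and '",
         target[2], "'", call. = FALSE)
  if (is.null(fused_label)) {
    bases <- bone_base(target)
    fused_label <- if (bases[1] == bases[2]) bases[1]
                   else paste(target, collapse = "+")
  }
  others <- setdiff(net$bones, target)
  merged <- pmin(a[target[1], others] + a[target[2], others], 1)
  a2 <- rbind(cbind(a[others, others, drop = FALSE], merged),
              c(merged, 0))
  labs <- c(others, fused_label)
  dimnames(a2) <- list(labs, labs)
  skull_network(a2, taxon = net$taxon)
}

#' Generate a pure-birth (Yule) phylogeny
#'
#' Seeded wrapper around [ape::rphylo()] with birth rate 1 and death rate
#' 0: a fully bifurcating ultrametric tree. By default the tree is
#' rescaled to unit root-to-tip height so signal-test calibrations are
#' comparable across seeds.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer RNG seed.
#' @param rescale_height rescale total height to 1 (default TRUE).
#' @return a \code{"phylo"} tree with tips \code{t1..tn}.
#' @export
generate_tree <- function(n_tips, seed = 1, rescale_height = TRUE) {
  if (n_tips < 2) stop("need at least 2 tips", call. = FALSE)
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  if (rescale_height)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

#' Simulate a trait under Brownian motion on a tree
#'
#' Walks the tree from the root, adding to each branch an independent
#' normal increment with variance \code{sigma2} times the branch length;
#' tip values are returned. This is the null (and alternative) model for
#' calibrating the phylogenetic-signal tests: tip values covary in
#' proportion to shared path length.
#'
#' @param tree \code{"phylo"} tree with nonnegative branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length), > 0.
#' @param root_value trait value at the root.
#' @param seed integer RNG seed.
#' @return named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, root_value = 0, seed = 1) {
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "cladewise")   # parents before children
  x <- numeric(ntip + tr$Nnode)
  x[ntip + 1] <- root_value
  with_seed(seed, {
    inc <- stats::rnorm(nrow(tr$edge), 0, sqrt(sigma2 * tr$edge.length))
    for (e in seq_len(nrow(tr$edge)))
      x[tr$edge[e, 2]] <- x[tr$edge[e, 1]] + inc[e]
  })
  stats::setNames(x[seq_len(ntip)], tr$tip.label)
}
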
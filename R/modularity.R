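#' Topological overlap matrix of a skull network
#'
#' Topological overlap (TO) is a normalized pairwise similarity counting
#' the neighbors two bones share: TO_ij = J(n_i, n_j) / min_k(i, j), where
#' J is the number of common neighbors and min_k the smaller neighborhood
#' size. Two bones connected to all the same other bones have TO = 1; two
#' bones without any common neighbor have TO = 0. The dissimilarity
#' 1 - TO is the input to the hierarchical module search.
#'
#' Three conventions for the neighborhood bookkeeping are available:
#' \describe{
#'   \item{\code{open_neighborhood} (default)}{J counts common neighbors
#'     (which never include the pair itself) and min_k is the smaller of
#'     the two pair-excluded neighborhood sizes, min(k_i - A_ij,
#'     k_j - A_ij). Mutually adjacent bones sharing all other neighbors --
#'     e.g. left/right counterparts that articulate with each other --
#'     score exactly 1. If a pair-excluded neighborhood is empty
#'     (a pendant bone and its only contact) the overlap is 0.}
#'   \item{\code{raw_degree}}{denominator min(k_i, k_j) on raw degrees.}
#'   \item{\code{gtom1}}{the generalized topological overlap of
#'     Yip & Horvath at one step, (J + A_ij) / (min(k_i, k_j) + 1 - A_ij),
#'     the classic weighted-coexpression TOM.}
#' }
#'
#' @param net a connected [skull_network()] with at least 2 bones.
#' @param convention one of \code{"open_neighborhood"}, \code{"raw_degree"},
#'   \code{"gtom1"}.
#' @return An object of class \code{"to_matrix"}: the symmetric TO matrix
#'   (diagonal 1) with bone labels, plus the convention used.
#' @export
topological_overlap <- function(net,
                                convention = c("open_neighborhood",
                                               "raw_degree", "gtom1")) {
  convention <- match.arg(convention)
  a <- net$adjacency
  n <- nrow(a)
  if (n < 2) stop("topological overlap needs at least 2 bones", call. = FALSE)
  k <- rowSums(a)
  l <- a %*% a           # l[i,j] = common neighbors of i and j
  kmin <- outer(k, k, pmin)
  to <- switch(convention,
    open_neighborhood = {
      den <- kmin - a    # pair-excluded neighborhood sizes
      ifelse(den > 0, l / den, 0)
    },
    raw_degree = l / kmin,
    gtom1 = (l + a) / (kmin + 1 - a)
  )
  diag(to) <- 1
  to <- pmin(pmax(to, 0), 1)
  dimnames(to) <- list(net$bones, net$bones)
  structure(list(labels = net$bones, values = to, convention = convention),
            class = "to_matrix")
}

#' Newman's modularity Q of a partition
#'
#' Q = (1/2K) * sum_ij [A_ij - k_i k_j / 2K] * delta(m_i, m_j), the sum
#' running over all ordered bone pairs (including i = j), where K is the
#' number of contacts, k_i the degree of bone i and m_i its module.
#' Equivalently sum_c (e_c - a_c^2) over modules, with e_c the fraction of
#' edges inside module c and a_c the fraction of edge ends attached to c.
#' Q = 0 for the single-module partition; Q > 0 when within-module contacts
#' exceed the degree-preserving random expectation.
#'
#' @param net a [skull_network()].
#' @param assignment module membership: an integer/character vector in bone
#'   order, or named by bone label.
#' @return Q, a real number.
#' @export
newman_q <- function(net, assignment) {
  bones <- net$bones
  if (!is.null(names(assignment))) {
    missing <- setdiff(bones, names(assignment))
    if (length(missing) > 0)
      stop("assignment misses bone(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    assignment <- assignment[bones]
  }
  if (length(assignment) != length(bones) || anyNA(assignment))
    stop("assignment must cover every bone exactly once", call. = FALSE)
  a <- net$adjacency
  m2 <- sum(a)                       # 2K
  deg <- rowSums(a)
  q <- 0
  for (mod in unique(assignment)) {
    idx <- which(assignment == mod)
    e_c <- sum(a[idx, idx, drop = FALSE]) / m2
    a_c <- sum(deg[idx]) / m2
    q <- q + e_c - a_c^2
  }
  q
}

#' Identify connectivity modules by topological-overlap clustering
#'
#' The module-detection procedure for one skull: (1) compute the TO matrix;
#' (2) cluster bones hierarchically on the dissimilarity 1 - TO (average
#' linkage by default); (3) cut the dendrogram at every cluster count
#' 1..N and score each resulting partition with Newman's Q; (4) keep the
#' partition with the highest Q. Ties in Q are broken toward fewer modules,
#' then lower cut height, so the result is fully deterministic. The
#' modularity strength of the skull is M = n_modules x Q.
#'
#' The returned partition also carries the two-cluster "first split" of the
#' dendrogram (the facial/cranial macromodules, see [macromodules()]),
#' left/right specular module pairs ([detect_specular()]) and heuristic
#' anatomical labels ([label_modules()]).
#'
#' @param net a [skull_network()].
#' @param linkage \code{"average"} (default), \code{"complete"} or
#'   \code{"single"}.
#' @param to_convention passed to [topological_overlap()].
#' @return An object of class \code{"skull_partition"}: list with
#'   \code{assignment} (named integer vector), \code{n_modules}, \code{Q},
#'   \code{M}, \code{dendrogram} (an \code{hclust}), \code{q_by_k} (Q at
#'   every cut), \code{module_labels}, \code{specular_pairs}, and the
#'   conventions used.
#' @examples
#' net <- generate_skull(n_pairs = 9, n_midline = 5, seed = 1,
#'                       modular_layout = planted_layout(c(7, 7)))
#' part <- hierarchical_modules(net)
#' part
#' @export
hierarchical_modules <- function(net,
                                 linkage = c("average", "complete", "single"),
                                 to_convention = c("open_neighborhood",
                                                   "raw_degree", "gtom1")) {
  linkage <- match.arg(linkage)
  to_convention <- match.arg(to_convention)
  to <- topological_overlap(net, to_convention)
  n <- length(net$bones)
  hc <- stats::hclust(stats::as.dist(1 - to$values), method = linkage)
  # cut by cluster count, not height: reaches every partition cardinality
  # even when merge heights tie
  cuts <- stats::cutree(hc, k = seq_len(n))
  if (n == 1) cuts <- matrix(cuts, ncol = 1, dimnames = list(net$bones, 1))
  q_by_k <- vapply(seq_len(n), function(k) newman_q(net, cuts[, k]),
                   numeric(1))
  best_k <- which(q_by_k >= max(q_by_k) - 1e-12)[1]  # ties -> fewest modules
  assignment <- cuts[, best_k]
  names(assignment) <- net$bones
  part <- structure(
    list(taxon = net$taxon,
         assignment = assignment,
         n_modules = length(unique(assignment)),
         Q = q_by_k[best_k],
         M = length(unique(assignment)) * q_by_k[best_k],
         dendrogram = hc,
         q_by_k = q_by_k,
         linkage = linkage,
         to_convention = to_convention),
    class = "skull_partition")
  part$macromodules <- macromodules(part)
  part$specular_pairs <- detect_specular(part, net)
  part$module_labels <- label_modules(part)
  part
}

#' Modularity strength M of a partition
#'
#' M = n_modules x Q: the summary statistic combining how many connectivity
#' modules a skull has with how sharply they are delimited. M = 0 iff the
#' optimal partition is the trivial single module.
#'
#' @param partition a [hierarchical_modules()] result.
#' @return M, a real number.
#' @export
modularity_strength <- function(partition) {
  partition$n_modules * partition$Q
}

#' Macromodules: the first split of the module dendrogram
#'
#' Cuts the clustering dendrogram into exactly two clusters -- the "first
#' split", separating the two main regions of the skull (facial and cranial
#' in primates). When the optimal connectivity-module partition refines the
#' first split, each module nests inside exactly one macromodule; modules
#' straddling the split are flagged.
#'
#' @param partition a [hierarchical_modules()] result (dendrogram required).
#' @return A list with \code{members} (list of two bone-label vectors),
#'   and \code{containment}: a data frame with one row per connectivity
#'   module giving its macromodule (1, 2) or NA with
#'   \code{straddles = TRUE}.
#' @export
macromodules <- function(partition) {
  hc <- partition$dendrogram
  if (is.null(hc)) stop("partition carries no dendrogram", call. = FALSE)
  if (length(hc$labels) < 2) stop("need at least 2 bones", call. = FALSE)
  two <- stats::cutree(hc, k = 2)
  members <- split(names(two), two)
  names(members) <- NULL
  mods <- sort(unique(partition$assignment))
  contain <- vapply(mods, function(m) {
    inside <- unique(two[names(partition$assignment)[partition$assignment == m]])
    if (length(inside) == 1) inside else NA_integer_
  }, integer(1))
  list(members = members,
       containment = data.frame(module = mods,
                                macromodule = contain,
                                straddles = is.na(contain)))
}

#' Detect specular (mirror-image) module pairs
#'
#' In a bilaterally symmetric skull, a module made of left-side bones often
#' has a right-side mirror twin: the left and right midfacial modules, for
#' example. Two modules are specular when their sided bones map onto each
#' other exactly under the l/r suffix swap. Unpaired midline bones cannot
#' take sides; their assignment to one member of a specular pair is
#' arbitrary and they are reported as such.
#'
#' @param partition a [hierarchical_modules()] result.
#' @param net the [skull_network()] the partition belongs to (bone labels
#'   must follow the \code{"_l"}/\code{"_r"} convention for the detection
#'   to find anything).
#' @return A list of specular pairs, each a list with \code{modules}
#'   (the two module ids) and \code{arbitrary_bones} (unpaired bones inside
#'   either member). Empty list when no pair mirrors.
#' @export
detect_specular <- function(partition, net = NULL) {
  assignment <- partition$assignment
  bones <- names(assignment)
  mods <- sort(unique(assignment))
  swap_side <- function(b) {
    out <- b
    out[grepl("_l$", b)] <- sub("_l$", "_r", b[grepl("_l$", b)])
    out[grepl("_r$", b)] <- sub("_r$", "_l", b[grepl("_r$", b)])
    out
  }
  pairs <- list()
  for (i in seq_along(mods)) {
    for (j in seq_along(mods)) {
      if (j <= i) next
      bi <- bones[assignment == mods[i]]
      bj <- bones[assignment == mods[j]]
      si <- bi[bone_side(bi) != ""]
      sj <- bj[bone_side(bj) != ""]
      if (length(si) == 0 || length(sj) == 0) next
      if (setequal(swap_side(si), sj)) {
        arb <- c(bi[bone_side(bi) == ""], bj[bone_side(bj) == ""])
        pairs[[length(pairs) + 1]] <-
          list(modules = c(mods[i], mods[j]), arbitrary_bones = arb)
      }
    }
  }
  pairs
}

#' Label connectivity modules by anatomical anchor bones
#'
#' Heuristic naming of the four recurring module types of the primate
#' skull, by the bones that diagnose them: a module containing the
#' occipital (\code{occ}) is neurocranial; containing the ethmoid
#' (\code{eth}), midfacial; containing all the palatines (\code{pal}) but
#' neither previous anchor, palatal; containing a premaxilla (\code{pmx})
#' but no higher anchor, premaxillary; anything else is unlabeled. When two
#' anchors land in one module the higher-priority anchor wins
#' (occ > eth > pal > pmx) and the conflict is recorded. Modules whose
#' sided bones are all left (or all right) get an \code{"_l"}
#' (\code{"_r"}) suffix on the label.
#'
#' @param partition a [hierarchical_modules()] result whose bone labels use
#'   the standard abbreviations (occ, eth, pal, pmx, ...).
#' @return Named character vector, one label per module id; anchor
#'   conflicts, if any, in attribute \code{"conflicts"}.
#' @export
label_modules <- function(partition) {
  assignment <- partition$assignment
  bones <- names(assignment)
  mods <- sort(unique(assignment))
  all_pal <- bones[bone_base(bones) == "pal"]
  labels <- character(length(mods))
  names(labels) <- mods
  conflicts <- character(0)
  for (m in mods) {
    mb <- bones[assignment == m]
    bases <- bone_base(mb)
    hits <- c(neurocranial = "occ" %in% bases,
              midfacial = "eth" %in% bases,
              palatal = length(all_pal) > 0 && all(all_pal %in% mb),
              premaxillary = "pmx" %in% bases)
    if (!any(hits)) {
      labels[as.character(m)] <- "unlabeled"
      next
    }
    lab <- names(hits)[which(hits)[1]]        # priority occ > eth > pal > pmx
    if (sum(hits) > 1)
      conflicts <- c(conflicts,
                     paste0("module ", m, ": anchors {",
                            paste(names(hits)[hits], collapse = ","),
                            "} -> ", lab))
    sides <- bone_side(mb)
    sided <- sides[sides != ""]
    if (length(sided) > 0 && length(unique(sided)) == 1)
      lab <- paste0(lab, "_", unique(sided))
    labels[as.character(m)] <- lab
  }
  if (length(conflicts) > 0) attr(labels, "conflicts") <- conflicts
  labels
}

#' @export
print.skull_partition <- function(x, ...) {
  cat("Connectivity modules:", x$taxon, "\n")
  cat(sprintf("  %d module(s), Q = %.4f, M = %.4f  (TO: %s, linkage: %s)\n",
              x$n_modules, x$Q, x$M, x$to_convention, x$linkage))
  for (m in sort(unique(x$assignment))) {
    lab <- if (!is.null(x$module_labels)) x$module_labels[as.character(m)]
           else ""
    cat(sprintf("  [%s] %s: %s\n", m, lab,
                paste(names(x$assignment)[x$assignment == m],
                      collapse = " ")))
  }
  if (length(x$specular_pairs) > 0)
    cat("  specular pairs:",
        paste(vapply(x$specular_pairs,
                     function(p) paste(p$modules, collapse = "~"),
                     character(1)), collapse = ", "), "\n")
  invisible(x)
}
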
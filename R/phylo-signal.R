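#' Abouheif proximity matrix of a phylogeny
#'
#' Topology-only tip proximities used by Abouheif's test: the entry for
#' tips i, j is 1 over the product of the number of direct descendants of
#' every internal node on the path between them (the MRCA included, the
#' tips themselves excluded). Close relatives through few, small splits get
#' large weights. Branch lengths are ignored.
#'
#' @param tree a rooted \code{"phylo"} tree.
#' @return symmetric matrix with zero diagonal, tip labels as dimnames.
#' @export
abouheif_weights <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 3) stop("need at least 3 tips", call. = FALSE)
  nn <- ntip + tree$Nnode
  n_children <- tabulate(tree$edge[, 1], nbins = nn)
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  ancestors <- lapply(seq_len(ntip), function(tp) {
    p <- tp
    out <- integer(0)
    while (p != root) {
      p <- parent[p]
      out <- c(out, p)
    }
    out
  })
  w <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1)) {
    for (j in seq(i + 1, ntip)) {
      ai <- ancestors[[i]]
      aj <- ancestors[[j]]
      mrca <- ai[match(TRUE, ai %in% aj)]
      path <- c(ai[seq_len(match(mrca, ai))],          # i-side incl. MRCA
                aj[seq_len(match(mrca, aj) - 1)])      # j-side excl. MRCA
      w[i, j] <- w[j, i] <- 1 / prod(n_children[path])
    }
  }
  w
}

# shared machinery: permutation p-value with the add-one convention
perm_pvalue <- function(obs, perm, alternative) {
  m <- length(perm)
  switch(alternative,
    greater = (sum(perm >= obs) + 1) / (m + 1),
    less = (sum(perm <= obs) + 1) / (m + 1),
    two.sided = (sum(abs(perm) >= abs(obs)) + 1) / (m + 1))
}

check_trait <- function(tree, trait) {
  if (is.null(names(trait)))
    stop("trait values must be named by taxon", call. = FALSE)
  extra <- setdiff(names(trait), tree$tip.label)
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(extra) + length(miss) > 0)
    stop("trait/tree mismatch; missing from trait: {",
         paste(miss, collapse = ","), "}; not in tree: {",
         paste(extra, collapse = ","), "}", call. = FALSE)
  x <- trait[tree$tip.label]
  if (stats::var(x) == 0)
    stop("degenerate trait: zero variance across tips", call. = FALSE)
  x
}

#' Abouheif's test of phylogenetic signal
#'
#' Computes Abouheif's Cmean -- a Moran's-I-type autocorrelation of the
#' trait against the row-normalized [abouheif_weights()] proximity matrix
#' -- and a permutation p-value obtained by shuffling trait values across
#' tips. A significant result indicates that close relatives resemble each
#' other more than expected under random assignment, i.e. phylogenetically
#' constrained evolution of the parameter. The test is conventionally
#' one-sided for positive autocorrelation.
#'
#' @param tree rooted \code{"phylo"} tree (branch lengths not used).
#' @param trait named numeric vector, names matching the tip labels.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed recorded in the result; p-values are exactly
#'   reproducible given (seed, n_perm).
#' @param alternative \code{"greater"} (default), \code{"less"} or
#'   \code{"two.sided"}.
#' @param parameter optional name of the tested parameter, for reporting.
#' @return An object of class \code{"signal_test"} with fields
#'   \code{parameter}, \code{statistic} (Cmean), \code{p_value},
#'   \code{n_permutations}, \code{seed}, \code{method},
#'   \code{alternative}.
#' @export
abouheif_cmean <- function(tree, trait, n_perm = 1000, seed = 1,
                           alternative = c("greater", "less", "two.sided"),
                           parameter = deparse(substitute(trait))) {
  alternative <- match.arg(alternative)
  x <- check_trait(tree, trait)
  w <- abouheif_weights(tree)
  w <- w / rowSums(w)
  cmean_stat <- function(z) sum(z * (w %*% z)) / sum(z^2)
  z <- x - mean(x)
  obs <- cmean_stat(z)
  n <- length(z)
  perm <- with_seed(seed, {
    zp <- vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
    colSums(zp * (w %*% zp)) / colSums(zp^2)
  })
  structure(
    list(parameter = parameter, statistic = obs,
         p_value = perm_pvalue(obs, perm, alternative),
         n_permutations = n_perm, seed = seed,
         method = "abouheif", alternative = alternative),
    class = "signal_test")
}

#' Blomberg's K test of phylogenetic signal
#'
#' K compares how the trait variance partitions on the tree against the
#' Brownian-motion expectation: K = (MSE0/MSE) observed divided by
#' (MSE0/MSE) expected under BM, where MSE0 is the mean squared deviation
#' of tip values from the phylogenetically (GLS) estimated mean, and MSE
#' the phylogenetically corrected counterpart. K = 1 is the BM benchmark;
#' K < 1 less signal than BM, K > 1 more. Significance by tip-label
#' permutation, as in [abouheif_cmean()].
#'
#' @inheritParams abouheif_cmean
#' @param tree rooted \code{"phylo"} tree with strictly positive branch
#'   lengths.
#' @return A \code{"signal_test"} object (statistic = K).
#' @export
blomberg_k <- function(tree, trait, n_perm = 1000, seed = 1,
                       alternative = c("greater", "less", "two.sided"),
                       parameter = deparse(substitute(trait))) {
  alternative <- match.arg(alternative)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length <= 0))
    stop("Blomberg's K requires strictly positive branch lengths",
         call. = FALSE)
  x <- check_trait(tree, trait)
  n <- length(x)
  cmat <- ape::vcv(tree)[names(x), names(x)]
  inv <- solve(cmat)
  ones <- rep(1, n)
  denom1 <- as.numeric(ones %*% inv %*% ones)
  wgls <- as.numeric(inv %*% ones) / denom1   # GLS mean weights
  expected <- (sum(diag(cmat)) - n / denom1) / (n - 1)
  k_stat <- function(v) {
    r <- v - sum(wgls * v)
    (sum(r^2) / as.numeric(r %*% inv %*% r)) / expected
  }
  obs <- k_stat(x)
  perm <- with_seed(seed, {
    vp <- vapply(seq_len(n_perm), function(i) x[sample.int(n)], numeric(n))
    a <- drop(crossprod(wgls, vp))
    r <- sweep(vp, 2, a)
    (colSums(r^2) / colSums(r * (inv %*% r))) / expected
  })
  structure(
    list(parameter = parameter, statistic = obs,
         p_value = perm_pvalue(obs, perm, alternative),
         n_permutations = n_perm, seed = seed,
         method = "blomberg", alternative = alternative),
    class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  stat_name <- if (x$method == "abouheif") "Cmean" else "K"
  cat(sprintf("%s signal test on '%s': %s = %.4f, p = %.4g (%s, %d perms, seed %d)\n",
              tools::toTitleCase(x$method), x$parameter, stat_name,
              x$statistic, x$p_value, x$alternative, x$n_permutations,
              x$seed))
  invisible(x)
}
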
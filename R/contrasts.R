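#' Phylogenetic independent contrasts
#'
#' Felsenstein's standardized contrasts: recursive pruning of a fully
#' bifurcating tree, extending each pruned parent branch by
#' v1 v2 / (v1 + v2) and dividing each node's trait difference by the
#' square root of its expected variance. Returns n_tips - 1 contrasts,
#' mutually independent under Brownian motion. Wraps [ape::pic()] behind
#' strict input validation: polytomies and nonpositive branch lengths are
#' rejected up front.
#'
#' @param tree rooted, fully bifurcating \code{"phylo"} tree with strictly
#'   positive branch lengths.
#' @param trait named numeric vector, names matching tip labels.
#' @return numeric vector of n_tips - 1 standardized contrasts (named by
#'   internal node number).
#' @export
independent_contrasts <- function(tree, trait) {
  if (!ape::is.rooted(tree) ||
      tree$Nnode != length(tree$tip.label) - 1)
    stop("tree contains polytomies; resolve them before computing contrasts",
         call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length <= 0))
    stop("contrasts require strictly positive branch lengths", call. = FALSE)
  if (is.null(names(trait)))
    stop("trait values must be named by taxon", call. = FALSE)
  extra <- setdiff(names(trait), tree$tip.label)
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(extra) + length(miss) > 0)
    stop("trait/tree mismatch; missing from trait: {",
         paste(miss, collapse = ","), "}; not in tree: {",
         paste(extra, collapse = ","), "}", call. = FALSE)
  ape::pic(trait[tree$tip.label], tree, scaled = TRUE)
}

#' Pearson correlation of phylogenetic independent contrasts
#'
#' The comparative test of whether two parameters co-evolve: both traits
#' are converted to independent contrasts on the same tree and correlated.
#' Because the sign of each contrast is arbitrary, the default correlation
#' is computed through the origin (no intercept), with significance from
#' the t-distribution on n_contrasts - 1 degrees of freedom. A
#' with-intercept ordinary Pearson correlation is available for
#' sensitivity analysis.
#'
#' @param tree rooted, fully bifurcating \code{"phylo"} tree with positive
#'   branch lengths.
#' @param traits data frame of parameters, one row per taxon; row names (or
#'   a \code{taxon} column) give the taxa.
#' @param x,y column names of the two parameters to correlate.
#' @param alternative \code{"two.sided"} (default), \code{"greater"},
#'   \code{"less"}.
#' @param through_origin correlate contrasts with no intercept (default
#'   TRUE, the standard for contrasts).
#' @return An object of class \code{"pic_cor"}: list with \code{x},
#'   \code{y}, \code{r}, \code{p_value}, \code{n_contrasts}, \code{df},
#'   \code{method}, \code{alternative}.
#' @export
pic_correlation <- function(tree, traits, x, y,
                            alternative = c("two.sided", "greater", "less"),
                            through_origin = TRUE) {
  alternative <- match.arg(alternative)
  traits <- as.data.frame(traits)
  if ("taxon" %in% colnames(traits) && !(x == "taxon" || y == "taxon")) {
    rownames(traits) <- traits$taxon
  }
  for (col in c(x, y)) {
    if (!col %in% colnames(traits))
      stop("column '", col, "' not found in traits", call. = FALSE)
  }
  tx <- stats::setNames(traits[[x]], rownames(traits))
  ty <- stats::setNames(traits[[y]], rownames(traits))
  cx <- independent_contrasts(tree, tx)
  cy <- independent_contrasts(tree, ty)
  n <- length(cx)
  if (n < 3) stop("fewer than 3 contrasts; too few taxa", call. = FALSE)
  if (through_origin) {
    r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
    df <- n - 1
  } else {
    r <- stats::cor(cx, cy)
    df <- n - 2
  }
  tval <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(tval), df),
    greater = stats::pt(tval, df, lower.tail = FALSE),
    less = stats::pt(tval, df))
  structure(
    list(x = x, y = y, r = r, p_value = p, n_contrasts = n, df = df,
         method = if (through_origin) "PIC Pearson through origin"
                  else "PIC Pearson with intercept",
         alternative = alternative),
    class = "pic_cor")
}

#' @export
print.pic_cor <- function(x, ...) {
  cat(sprintf("%s: %s ~ %s, r = %.3f, p = %.4g (%d contrasts, %s)\n",
              x$method, x$x, x$y, x$r, x$p_value, x$n_contrasts,
              x$alternative))
  invisible(x)
}
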
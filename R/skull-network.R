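#' Construct a skull bone-contact network
#'
#' A skull network is an undirected, unweighted graph whose nodes are the
#' bones of one skull and whose links are physical bone-bone contacts
#' (sutures and synchondroses), coded 1/0 in a symmetric adjacency matrix.
#' Bone labels follow the convention \code{<base>_l} / \code{<base>_r} for
#' paired left/right bones (e.g. \code{"par_l"}, \code{"par_r"}) and a bare
#' base name for unpaired midline bones (e.g. \code{"occ"}).
#'
#' Validation enforces the modelling assumptions every downstream statistic
#' relies on: the matrix must be symmetric and strictly 0/1 with a zero
#' diagonal, bone labels must be unique, and the graph must be connected
#' (a skull is a single articulated unit; disconnection signals a coding
#' error and is rejected, not warned about).
#'
#' @param adjacency square numeric matrix of 0/1 contacts; row and column
#'   names, when present, must agree and are used as bone labels.
#' @param bones character vector of bone labels; defaults to the matrix
#'   dimnames.
#' @param taxon taxon name attached to the network.
#' @return An object of class \code{"skull_network"}: a list with elements
#'   \code{taxon}, \code{bones} and \code{adjacency}.
#' @examples
#' a <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' a["a", "b"] <- a["b", "a"] <- 1
#' a["b", "c"] <- a["c", "b"] <- 1
#' net <- skull_network(a, taxon = "toy")
#' net
#' @seealso [read_skull_network()], [complexity_profile()],
#'   [hierarchical_modules()]
#' @export
skull_network <- function(adjacency, bones = NULL, taxon = "unnamed") {
  adjacency <- as.matrix(adjacency)
  if (is.null(bones)) {
    bones <- rownames(adjacency)
    if (is.null(bones)) bones <- paste0("n", seq_len(nrow(adjacency)))
  }
  mode(adjacency) <- "numeric"
  dimnames(adjacency) <- list(bones, bones)
  net <- structure(
    list(taxon = as.character(taxon), bones = as.character(bones),
         adjacency = adjacency),
    class = "skull_network"
  )
  validate_skull_network(net)
  net
}

#' Validate a skull network
#'
#' Checks every invariant of the bone-contact model and stops with an
#' informative error on the first violation. Called by [skull_network()] and
#' by the readers; exported so that externally constructed objects can be
#' re-checked.
#'
#' @param net a \code{"skull_network"} object (or a bare list with the same
#'   fields).
#' @return \code{net}, invisibly, if valid.
#' @export
validate_skull_network <- function(net) {
  a <- net$adjacency
  bones <- net$bones
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("adjacency must be a square matrix", call. = FALSE)
  n <- nrow(a)
  if (length(bones) != n)
    stop("number of bone labels (", length(bones),
         ") does not match matrix size (", n, ")", call. = FALSE)
  if (anyDuplicated(bones))
    stop("duplicated bone labels: ",
         paste(unique(bones[duplicated(bones)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(a) || !all(a %in% c(0, 1))) {
    bad <- which(!(a %in% c(0, 1)) | is.na(a), arr.ind = TRUE)[1, ]
    stop("non-binary entry at [", bones[bad[1]], ", ", bones[bad[2]],
         "]: contacts must be coded 0/1", call. = FALSE)
  }
  if (any(diag(a) != 0))
    stop("nonzero diagonal at bone(s): ",
         paste(bones[diag(a) != 0], collapse = ", "),
         "; a bone cannot contact itself", call. = FALSE)
  asym <- which(a != t(a), arr.ind = TRUE)
  if (nrow(asym) > 0) {
    stop("asymmetric adjacency: A[", bones[asym[1, 1]], ", ",
         bones[asym[1, 2]], "] != A[", bones[asym[1, 2]], ", ",
         bones[asym[1, 1]], "]", call. = FALSE)
  }
  comp <- igraph::components(as_igraph(net))
  if (comp$no > 1) {
    parts <- split(bones, comp$membership)
    stop("network is disconnected (", comp$no, " components): ",
         paste(vapply(parts, function(p) paste0("{", paste(p, collapse = ","), "}"),
                      character(1)),
               collapse = " "), call. = FALSE)
  }
  invisible(net)
}

#' @export
print.skull_network <- function(x, ...) {
  cat("Skull network:", x$taxon, "\n")
  cat("  bones (N):", length(x$bones), "  contacts (K):",
      sum(x$adjacency) / 2, "\n")
  sides <- bone_side(x$bones)
  cat("  paired bones:", sum(sides != ""), " midline bones:",
      sum(sides == ""), "\n")
  invisible(x)
}

# igraph view of a skull network (internal plumbing; labels preserved)
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

# "_l"/"_r" side suffix of each bone label ("" for midline bones)
bone_side <- function(bones) {
  ifelse(grepl("_l$", bones), "l", ifelse(grepl("_r$", bones), "r", ""))
}

# bone label with the side suffix stripped
bone_base <- function(bones) sub("_[lr]$", "", bones)

# degree sequence in bone order
bone_degrees <- function(net) rowSums(net$adjacency)
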
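#' Read a skull network from a file
#'
#' Reads one taxon's bone-contact network from a labeled CSV adjacency
#' matrix (the interchange format used for published skull codings), a
#' tab-separated edge list, or GraphML, then validates it (symmetry,
#' 0/1 coding, zero diagonal, unique labels, connectivity).
#'
#' The CSV dialect is: first row and first column carry the bone labels,
#' cells are strictly \code{0}/\code{1}, comma-separated, UTF-8. Row and
#' column labels must agree. Deposited matrices in the wild sometimes use
#' different label spellings; \code{relabel} accepts a named character
#' vector (\code{c(old = "new")}) applied to the labels before validation,
#' so a normalization map can be documented alongside the data rather than
#' edited into it.
#'
#' @param path file to read.
#' @param format one of \code{"csv_matrix"}, \code{"edge_list"},
#'   \code{"graphml"}. Edge lists are two tab-separated label columns, one
#'   undirected edge per line; duplicate and reversed repeats collapse.
#' @param taxon taxon name; defaults to the file name without extension.
#' @param relabel optional named character vector mapping raw labels to
#'   normalized bone labels.
#' @return A validated [skull_network()].
#' @export
read_skull_network <- function(path,
                               format = c("csv_matrix", "edge_list", "graphml"),
                               taxon = NULL, relabel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(taxon)) taxon <- sub("\\.[^.]*$", "", basename(path))
  adj <- switch(format,
    csv_matrix = {
      m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE,
                                     fileEncoding = "UTF-8"))
      if (!identical(rownames(m), colnames(m)))
        stop("row and column labels differ in ", path, call. = FALSE)
      m
    },
    edge_list = {
      el <- utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "character", comment.char = "#")
      if (ncol(el) < 2) stop("edge list needs two tab-separated columns",
                             call. = FALSE)
      labs <- sort(unique(c(el[[1]], el[[2]])))
      m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
      m[cbind(el[[1]], el[[2]])] <- 1
      m[cbind(el[[2]], el[[1]])] <- 1
      m
    },
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      m <- as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
      if (!is.null(igraph::V(g)$name))
        dimnames(m) <- list(igraph::V(g)$name, igraph::V(g)$name)
      # GraphML multi-edges collapse to the simple 0/1 graph
      m[m > 1] <- 1
      m
    }
  )
  if (!is.null(relabel)) {
    labs <- rownames(adj)
    hit <- labs %in% names(relabel)
    labs[hit] <- relabel[labs[hit]]
    dimnames(adj) <- list(labs, labs)
  }
  skull_network(adj, taxon = taxon)
}

#' Write a skull network to a file
#'
#' Inverse of [read_skull_network()]: writes the validated network in any of
#' the three supported formats so that re-reading reproduces the same bones
#' and edge set.
#'
#' @param net a [skull_network()].
#' @param path destination file.
#' @param format one of \code{"csv_matrix"}, \code{"edge_list"},
#'   \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
write_skull_network <- function(net, path,
                                format = c("csv_matrix", "edge_list", "graphml")) {
  format <- match.arg(format)
  validate_skull_network(net)
  switch(format,
    csv_matrix = {
      df <- as.data.frame(net$adjacency)
      utils::write.csv(df, path, quote = FALSE, fileEncoding = "UTF-8")
    },
    edge_list = {
      idx <- which(upper.tri(net$adjacency) & net$adjacency == 1,
                   arr.ind = TRUE)
      el <- data.frame(from = net$bones[idx[, 1]], to = net$bones[idx[, 2]])
      utils::write.table(el, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    },
    graphml = {
      igraph::write_graph(as_igraph(net), path, format = "graphml")
    }
  )
  invisible(path)
}

#' Read a calibrated phylogeny from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()]. The comparative stage
#' expects a rooted tree whose tip labels match the taxon names of the skull
#' networks, with nonnegative branch lengths (typically in Myr from
#' molecular calibration).
#'
#' @param path Newick file. Alternatively pass the string itself via
#'   \code{text}.
#' @param text Newick string (overrides \code{path}).
#' @return An [ape::read.tree()] \code{"phylo"} object.
#' @export
read_newick_tree <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("give either path or text", call. = FALSE)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  }
  tr <- withCallingHandlers(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    warning = function(w) {
      stop("malformed Newick", if (!is.null(path)) paste0(" in ", path),
           ": ", conditionMessage(w), call. = FALSE)
    })
  if (is.null(tr))
    stop("malformed Newick", if (!is.null(path)) paste0(" in ", path),
         call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1)
      stop("expected a single tree, found ", length(tr), call. = FALSE)
    tr <- tr[[1]]
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  tr
}
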
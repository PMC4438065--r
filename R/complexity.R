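#' Connection density of a skull network
#'
#' D = 2K / (N(N-1)): the fraction of realized bone contacts out of all
#' possible pairs. A compactness proxy for morphological complexity.
#'
#' @param net a [skull_network()].
#' @return density in (0, 1].
#' @export
net_density <- function(net) {
  n <- length(net$bones)
  if (n < 2) stop("density undefined for fewer than 2 bones", call. = FALSE)
  sum(net$adjacency) / (n * (n - 1))
}

#' Average clustering coefficient of a skull network
#'
#' The mean over all bones of the Watts-Strogatz local clustering
#' coefficient c_i = 2 tau_i / (k_i (k_i - 1)), where tau_i counts the
#' triangles through bone i. Bones of degree < 2 contribute c_i = 0 rather
#' than being dropped, so the denominator of the average stays N. Measures
#' the richness of triangular contact motifs, a redundancy proxy for
#' complexity.
#'
#' @param net a [skull_network()].
#' @return mean clustering coefficient in [0, 1].
#' @export
net_clustering <- function(net) {
  ci <- igraph::transitivity(as_igraph(net), type = "local", isolates = "zero")
  # isolates = "zero" covers degree 0; degree-1 nodes also come back NaN
  ci[is.nan(ci)] <- 0
  mean(ci)
}

#' Degree heterogeneity of a skull network
#'
#' The dispersion of the bone degree sequence relative to its mean,
#' H = var(k) / mean(k) by default. Quantifies anisomerism: how unequal the
#' bones are in their number of contacts. H = 0 iff all bones have the same
#' degree. The early anatomical-network literature sometimes defines
#' heterogeneity as sd/mean (coefficient of variation); both conventions
#' are available and the one used is recorded by [complexity_profile()].
#'
#' @param net a [skull_network()].
#' @param variance_kind \code{"population"} (divide by N, default) or
#'   \code{"sample"} (divide by N-1).
#' @param dispersion \code{"variance_over_mean"} (default) or
#'   \code{"sd_over_mean"}.
#' @return heterogeneity, a nonnegative real.
#' @export
net_heterogeneity <- function(net,
                              variance_kind = c("population", "sample"),
                              dispersion = c("variance_over_mean",
                                             "sd_over_mean")) {
  variance_kind <- match.arg(variance_kind)
  dispersion <- match.arg(dispersion)
  k <- bone_degrees(net)
  n <- length(k)
  if (n < 2) stop("heterogeneity undefined for fewer than 2 bones",
                  call. = FALSE)
  v <- sum((k - mean(k))^2) /
    if (variance_kind == "population") n else n - 1
  num <- if (dispersion == "variance_over_mean") v else sqrt(v)
  num / mean(k)
}

#' Five-parameter complexity profile of a skull network
#'
#' Bundles the five morphological-complexity descriptors: number of bones
#' (N), number of contacts (K), density (D), average clustering coefficient
#' (C) and degree heterogeneity (H).
#'
#' @inheritParams net_heterogeneity
#' @return An object of class \code{"complexity_profile"}: a list with
#'   numeric fields \code{N}, \code{K}, \code{D}, \code{C}, \code{H}, plus
#'   \code{taxon} and \code{h_convention}.
#' @examples
#' net <- generate_skull(n_pairs = 9, n_midline = 5, seed = 1)
#' complexity_profile(net)
#' @export
complexity_profile <- function(net,
                               variance_kind = c("population", "sample"),
                               dispersion = c("variance_over_mean",
                                              "sd_over_mean")) {
  variance_kind <- match.arg(variance_kind)
  dispersion <- match.arg(dispersion)
  structure(
    list(taxon = net$taxon,
         N = length(net$bones),
         K = sum(net$adjacency) / 2,
         D = net_density(net),
         C = net_clustering(net),
         H = net_heterogeneity(net, variance_kind, dispersion),
         h_convention = paste(variance_kind, dispersion, sep = "/")),
    class = "complexity_profile")
}

#' @export
print.complexity_profile <- function(x, ...) {
  cat("Complexity profile:", x$taxon, "\n")
  cat(sprintf("  N = %d  K = %d  D = %.4f  C = %.4f  H = %.4f\n",
              x$N, x$K, x$D, x$C, x$H))
  cat("  (H convention:", x$h_convention, ")\n")
  invisible(x)
}
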
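#' Six-number summaries of the trait table
#'
#' Min, first quartile, median, mean, third quartile and max for every
#' parameter column, with quartiles by the linear-interpolation convention
#' (\code{stats::quantile} type 7, the convention of \code{summary()}).
#'
#' @param table data frame of numeric parameters (one row per taxon).
#' @return data frame with one row per parameter and columns
#'   \code{min, q1, median, mean, q3, max}.
#' @export
summarize_parameters <- function(table) {
  table <- as.data.frame(table)
  cols <- colnames(table)[vapply(table, is.numeric, logical(1))]
  if (length(cols) == 0 || nrow(table) == 0)
    stop("no numeric data to summarize", call. = FALSE)
  out <- t(vapply(cols, function(cn) {
    x <- table[[cn]]
    if (anyNA(x)) stop("missing values in column '", cn, "'", call. = FALSE)
    q <- stats::quantile(x, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    c(min = q[1], q1 = q[2], median = q[3], mean = mean(x), q3 = q[4],
      max = q[5])
  }, numeric(6)))
  as.data.frame(out)
}

#' Run the full comparative study
#'
#' Orchestrates the whole analysis over a set of taxa: per-skull module
#' detection ([hierarchical_modules()]) and complexity profiling
#' ([complexity_profile()]); assembly of the taxa x {M, N, K, D, C, H}
#' trait table and its six-number summary; Abouheif signal tests for all
#' six parameters; and the near-decomposability correlation battery --
#' Pearson correlations of independent contrasts of M against each of the
#' five complexity parameters. Raw p-values are reported (no multiplicity
#' correction, matching common practice for this battery); a Bonferroni
#' column is printed alongside, clearly marked as an extension.
#'
#' @param networks named list of [skull_network()] objects, or a character
#'   vector of CSV adjacency-matrix paths; taxon names come from the
#'   objects/file names and must match the tree tips exactly (a mismatch
#'   aborts; taxa are never silently intersected).
#' @param tree rooted bifurcating \code{"phylo"} tree, or a Newick file
#'   path.
#' @param to_convention,linkage passed to [hierarchical_modules()].
#' @param h_variance_kind,h_dispersion passed to [complexity_profile()].
#' @param n_permutations permutations per signal test (default 1000).
#' @param seed master seed; each signal test uses a distinct seed derived
#'   from it, recorded in its result.
#' @param cor_alternative sidedness of the PIC correlations (default
#'   two-sided).
#' @param out_dir optional directory: writes \code{report.json},
#'   \code{traits.tsv}, \code{summary.tsv}.
#' @return An object of class \code{"study_report"}: list with
#'   \code{partitions}, \code{profiles}, \code{traits},
#'   \code{summary}, \code{signal_tests}, \code{correlations},
#'   \code{provenance}.
#' @examples
#' # eight taxa whose bone counts vary like real primate skulls (N 21-24)
#' nets <- lapply(1:8, function(i)
#'   generate_skull(9, 3 + (i %% 4), seed = i, taxon = paste0("t", i)))
#' rep <- run_study(nets, generate_tree(8, seed = 99), n_permutations = 99)
#' rep
#' @export
run_study <- function(networks, tree,
                      to_convention = c("open_neighborhood", "raw_degree",
                                        "gtom1"),
                      linkage = c("average", "complete", "single"),
                      h_variance_kind = c("population", "sample"),
                      h_dispersion = c("variance_over_mean", "sd_over_mean"),
                      n_permutations = 1000, seed = 42,
                      cor_alternative = c("two.sided", "greater", "less"),
                      out_dir = NULL) {
  to_convention <- match.arg(to_convention)
  linkage <- match.arg(linkage)
  h_variance_kind <- match.arg(h_variance_kind)
  h_dispersion <- match.arg(h_dispersion)
  cor_alternative <- match.arg(cor_alternative)
  if (is.character(tree)) tree <- read_newick_tree(tree)
  if (is.character(networks)) {
    paths <- networks
    networks <- lapply(paths, read_skull_network, format = "csv_matrix")
  }
  taxa <- vapply(networks, function(n) n$taxon, character(1))
  if (anyDuplicated(taxa))
    stop("duplicated taxa: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  names(networks) <- taxa
  miss <- setdiff(tree$tip.label, taxa)
  extra <- setdiff(taxa, tree$tip.label)
  if (length(miss) + length(extra) > 0)
    stop("taxa/tree mismatch; tips without network: {",
         paste(miss, collapse = ","), "}; networks without tip: {",
         paste(extra, collapse = ","), "}", call. = FALSE)

  partitions <- lapply(networks, function(net) {
    tryCatch(hierarchical_modules(net, linkage, to_convention),
             error = function(e) stop("module detection failed for '",
                                      net$taxon, "': ", conditionMessage(e),
                                      call. = FALSE))
  })
  profiles <- lapply(networks, function(net) {
    tryCatch(complexity_profile(net, h_variance_kind, h_dispersion),
             error = function(e) stop("complexity failed for '", net$taxon,
                                      "': ", conditionMessage(e),
                                      call. = FALSE))
  })
  traits <- data.frame(
    M = vapply(partitions, function(p) p$M, numeric(1)),
    N = vapply(profiles, function(p) p$N, numeric(1)),
    K = vapply(profiles, function(p) p$K, numeric(1)),
    D = vapply(profiles, function(p) p$D, numeric(1)),
    C = vapply(profiles, function(p) p$C, numeric(1)),
    H = vapply(profiles, function(p) p$H, numeric(1)),
    row.names = taxa)

  params <- colnames(traits)
  signal_tests <- lapply(seq_along(params), function(i) {
    abouheif_cmean(tree, stats::setNames(traits[[params[i]]], taxa),
                   n_perm = n_permutations, seed = seed + i,
                   parameter = params[i])
  })
  names(signal_tests) <- params

  comp_params <- c("N", "K", "D", "C", "H")
  correlations <- lapply(comp_params, function(p)
    pic_correlation(tree, traits, x = "M", y = p,
                    alternative = cor_alternative))
  names(correlations) <- paste0("M_vs_", comp_params)

  report <- structure(
    list(partitions = partitions,
         profiles = profiles,
         traits = traits,
         summary = summarize_parameters(traits),
         signal_tests = signal_tests,
         correlations = correlations,
         provenance = list(
           package = "cranet",
           version = as.character(utils::packageVersion("cranet")),
           to_convention = to_convention,
           linkage = linkage,
           h_convention = paste(h_variance_kind, h_dispersion, sep = "/"),
           n_permutations = n_permutations,
           seed = seed,
           cor_alternative = cor_alternative,
           n_taxa = length(taxa))),
    class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Write a study report to disk
#'
#' Emits \code{report.json} (the full report), \code{traits.tsv} and
#' \code{summary.tsv} into a directory.
#'
#' @param report a [run_study()] result.
#' @param out_dir destination directory (created if absent).
#' @return \code{out_dir}, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cbind(taxon = rownames(report$traits), report$traits),
                     file.path(out_dir, "traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(parameter = rownames(report$summary),
                           report$summary),
                     file.path(out_dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  json <- list(
    provenance = report$provenance,
    traits = cbind(taxon = rownames(report$traits), report$traits),
    summary = cbind(parameter = rownames(report$summary), report$summary),
    partitions = lapply(report$partitions, function(p) list(
      taxon = p$taxon,
      assignment = as.list(p$assignment),
      n_modules = p$n_modules, Q = p$Q, M = p$M,
      module_labels = as.list(p$module_labels),
      specular_pairs = p$specular_pairs,
      macromodules = p$macromodules$members)),
    signal_tests = lapply(report$signal_tests, unclass),
    correlations = lapply(report$correlations, unclass))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Comparative skull-network study:", x$provenance$n_taxa, "taxa\n")
  cat("  conventions: TO =", x$provenance$to_convention,
      "| linkage =", x$provenance$linkage,
      "| H =", x$provenance$h_convention, "\n\n")
  cat("Parameter summaries (min / q1 / median / mean / q3 / max):\n")
  print(round(x$summary, 4))
  cat("\nPhylogenetic signal (Abouheif, ", x$signal_tests[[1]]$n_permutations,
      " permutations):\n", sep = "")
  for (st in x$signal_tests)
    cat(sprintf("  %s: Cmean = %7.4f, p = %.4g\n", st$parameter,
                st$statistic, st$p_value))
  nbat <- length(x$correlations)
  cat("\nPIC correlations, M vs complexity (raw p; Bonferroni x",
      nbat, "as an extension):\n")
  for (cr in x$correlations)
    cat(sprintf("  M ~ %s: r = %6.3f, p = %.4g (adj. %.4g)\n", cr$y, cr$r,
                cr$p_value, min(1, cr$p_value * nbat)))
  invisible(x)
}
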
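#' Run the full hybridization-aware species-tree pipeline
#'
#' Orchestrates the analysis end to end: phi test on the harmonized
#' posteriors; if lineage sorting alone is rejected, the sequential removal
#' search for the putative hybrid set; then species-tree inference by
#' minimizing deep coalescences on the remaining (non-hybrid) individuals,
#' using each locus' majority-rule consensus collapsed to its supported
#' topology.
#'
#' @param posteriors List of `gene_tree_posterior` objects, or a
#'   [synthetic_scenario()] (its pseudo-posteriors are generated first).
#' @param config A [phi_config()].
#' @param seed Master seed.
#' @param support Posterior-support threshold for the consensus collapse
#'   (default 0.95).
#' @param search_args List of extra arguments for [hybrid_search()].
#' @param out_dir Optional directory: JSON/TSV/Newick reports are written
#'   there.
#' @return An object of class `coalhyb_pipeline` with elements `phi`,
#'   `search` (or `NULL`), `species_tree` (an `mdc_fit`), `removed`,
#'   `seed`.
#' @export
run_pipeline <- function(posteriors, config = phi_config(), seed = 1,
                         support = 0.95, search_args = list(),
                         out_dir = NULL) {
  if (inherits(posteriors, "synthetic_scenario"))
    posteriors <- simulate_posteriors(posteriors, seed = seed)
  posteriors <- harmonize_posteriors(posteriors)
  phi <- phi_test(posteriors, config, seed = derive_seed(seed, 1),
                  harmonize = FALSE)
  search <- NULL
  removed <- character(0)
  kept <- posteriors
  if (phi$reject) {
    search <- do.call(hybrid_search,
                      c(list(posteriors = posteriors, config = config,
                             seed = derive_seed(seed, 2), harmonize = FALSE),
                        search_args))
    removed <- search$removed
    if (length(removed) &&
        length(setdiff(individuals_of(posteriors), removed)) >= 3)
      kept <- drop_individuals(posteriors, removed)
  }
  gene_trees <- lapply(kept, function(p)
    supported_consensus(p$trees, threshold = support))
  map <- stats::setNames(kept[[1]]$taxon_map$group,
                         kept[[1]]$taxon_map$leaf_label)
  species_tree <- mdc_species_tree(gene_trees, map)
  out <- structure(list(phi = phi, search = search,
                        species_tree = species_tree, removed = removed,
                        seed = seed, config = config),
                   class = "coalhyb_pipeline")
  if (!is.null(out_dir)) write_pipeline_reports(out, kept, out_dir)
  out
}

#' Majority-rule consensus collapsed to the supported topology
#'
#' Builds the majority-rule consensus of a posterior sample, attaches clade
#' frequencies as supports, and contracts every clade below the threshold.
#'
#' @param trees List of `phylo` trees on one leaf set.
#' @param threshold Support threshold (default 0.95).
#' @return A `phylo` with polytomies where support < threshold.
#' @export
supported_consensus <- function(trees, threshold = 0.95) {
  cons <- ape::consensus(as_multiphylo(trees), p = 0.5, rooted = TRUE)
  freq <- ape::prop.clades(cons, as_multiphylo(trees), rooted = TRUE)
  freq[is.na(freq)] <- 0
  cons$node.label <- freq / length(trees)
  cons$node.label[1] <- 1            # the root is always present
  collapse_unsupported(cons, threshold)
}

write_pipeline_reports <- function(x, kept, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    seed = x$seed,
    phi = x$phi$phi, reject = x$phi$reject,
    null_critical = as.list(x$phi$null_critical),
    observed_lower = as.list(x$phi$observed_lower),
    removed = x$removed,
    search_resolved = if (!is.null(x$search)) x$search$resolved else NA,
    mdc_cost = x$species_tree$cost,
    species_trees = vapply(x$species_tree$best_trees, ape::write.tree,
                           character(1)))
  jsonlite::write_json(report, file.path(out_dir, "pipeline_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (tr in seq_along(x$species_tree$best_trees))
    write_gene_trees(x$species_tree$best_trees[[tr]],
                     file.path(out_dir, sprintf("species_tree_%d.nwk", tr)))
  if (!is.null(x$search) && !is.null(x$search$random_controls))
    utils::write.table(x$search$random_controls,
                       file.path(out_dir, "random_controls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.coalhyb_pipeline <- function(x, ...) {
  cat("== coalhyb pipeline (seed ", x$seed, ") ==\n", sep = "")
  print(x$phi)
  if (!is.null(x$search)) print(x$search)
  else cat("Removal search skipped (lineage sorting not rejected).\n")
  print(x$species_tree)
  invisible(x)
}
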
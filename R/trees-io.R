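#' Read rooted trees from a Newick or NEXUS file
#'
#' Reads one tree per line (Newick) or a NEXUS trees block.  Internal node
#' labels, when numeric, are interpreted downstream as posterior supports.
#'
#' @param path Path to the tree file.
#' @param format `"newick"` (one tree per line) or `"nexus"` (trees block).
#' @return A list of `phylo` objects in file order.
#' @export
read_gene_trees <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  trees <- if (format == "newick") ape::read.tree(path) else ape::read.nexus(path)
  if (is.null(trees)) stop("could not parse any tree from ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(seq_along(trees), function(i) trees[[i]])  # uncompress labels
  lapply(trees, function(tr) {
    dup <- tr$tip.label[duplicated(tr$tip.label)]
    if (length(dup))
      stop("duplicate leaf labels in ", path, ": ", paste(unique(dup), collapse = ", "))
    tr
  })
}

#' Write trees as plain Newick, one per line
#'
#' Branch lengths are written with enough digits for an exact-topology,
#' >= 10 significant digit round trip.
#'
#' @param trees A `phylo` or list of `phylo` objects.
#' @param path Output file.
#' @export
write_gene_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  old <- options(digits = 15)
  on.exit(options(old))
  txt <- vapply(trees, function(tr) ape::write.tree(tr, digits = 12), character(1))
  writeLines(txt, path)
  invisible(path)
}

#' Read a taxon map
#'
#' Tab-delimited file with header
#' `leaf_label individual haplotype group ingroup` linking haplotype leaf
#' labels to individuals and putative groups (species).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with the five columns; `ingroup` is logical.
#' @export
read_taxon_map <- function(path) {
  tm <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_taxon_map(tm)
}

#' @rdname read_taxon_map
#' @param taxon_map A data frame to validate as a taxon map.
#' @export
validate_taxon_map <- function(taxon_map) {
  need <- c("leaf_label", "individual", "haplotype", "group", "ingroup")
  miss <- setdiff(need, names(taxon_map))
  if (length(miss)) stop("taxon map missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(taxon_map$leaf_label))
    stop("taxon map has duplicated leaf labels: ",
         paste(unique(taxon_map$leaf_label[duplicated(taxon_map$leaf_label)]), collapse = ", "))
  key <- paste(taxon_map$individual, taxon_map$haplotype)
  if (anyDuplicated(key))
    stop("duplicated (individual, haplotype) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  taxon_map$ingroup <- as.logical(taxon_map$ingroup)
  taxon_map
}

#' Bundle a posterior sample of gene trees for one locus
#'
#' @param locus Locus name.
#' @param trees List of `phylo` objects (>= 2), all on the same leaf set.
#' @param taxon_map Taxon map data frame (see [read_taxon_map()]).
#' @param units Unit tag for branch lengths (informational).
#' @return An object of class `gene_tree_posterior`.
#' @export
gene_tree_posterior <- function(locus, trees, taxon_map,
                                units = c("substitutions", "years", "generations")) {
  units <- match.arg(units)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 2) stop("a posterior needs at least 2 trees")
  labs <- sort(trees[[1]]$tip.label)
  same <- vapply(trees, function(tr) identical(sort(tr$tip.label), labs), logical(1))
  if (!all(same)) stop("all trees in posterior '", locus, "' must share one leaf set")
  taxon_map <- validate_taxon_map(taxon_map)
  unknown <- setdiff(labs, taxon_map$leaf_label)
  if (length(unknown))
    stop("leaves absent from taxon map: ", paste(unknown, collapse = ", "))
  structure(list(locus = locus, trees = trees, taxon_map = taxon_map, units = units),
            class = "gene_tree_posterior")
}

#' @export
print.gene_tree_posterior <- function(x, ...) {
  cat("Gene-tree posterior '", x$locus, "': ", length(x$trees), " trees, ",
      length(x$trees[[1]]$tip.label), " leaves (", x$units, ")\n", sep = "")
  invisible(x)
}

#' Prune a tree to a set of leaf labels
#'
#' Removes all other leaves, suppresses resulting unary nodes (summing branch
#' lengths) and collapses degree-one chains at the root.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain (non-empty subset).
#' @return The pruned `phylo`.
#' @export
prune_to_labels <- function(tree, keep) {
  if (!length(keep)) stop("'keep' must be non-empty")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) stop("unknown leaf labels: ", paste(unknown, collapse = ", "))
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Harmonize leaf sets across gene-tree posteriors
#'
#' Relabels every leaf to `individual_haplotype` form, drops outgroup leaves,
#' and prunes every tree to the intersection of leaf sets across loci so that
#' cross-gene tree distances are defined.  Haplotype suffixes are matched
#' literally across loci (the `"literal"` policy); the `"collapse"` policy
#' instead keeps one seeded random haplotype per individual per locus.
#'
#' @param posteriors List of `gene_tree_posterior` objects (>= 2).
#' @param policy Haplotype matching policy, `"literal"` or `"collapse"`.
#' @param seed Integer seed used by the `"collapse"` policy.
#' @return List of harmonized `gene_tree_posterior` objects sharing one leaf set.
#' @export
harmonize_posteriors <- function(posteriors, policy = c("literal", "collapse"),
                                 seed = NULL) {
  policy <- match.arg(policy)
  if (length(posteriors) < 2) stop("need at least 2 posteriors to harmonize")
  if (!is.null(seed)) set.seed(seed)
  relab <- lapply(posteriors, function(p) {
    tm <- p$taxon_map
    tm <- tm[tm$ingroup, , drop = FALSE]
    new <- ifelse(tm$haplotype %in% c("", "none", NA),
                  tm$individual, paste0(tm$individual, "_", tm$haplotype))
    map <- stats::setNames(new, tm$leaf_label)
    if (anyDuplicated(new))
      stop("ambiguous taxon map in locus '", p$locus, "': labels ",
           paste(unique(new[duplicated(new)]), collapse = ", "))
    if (policy == "collapse") {
      pick <- tapply(seq_len(nrow(tm)), tm$individual,
                     function(i) i[sample.int(length(i), 1)])
      keep_rows <- sort(unlist(pick, use.names = FALSE))
      map <- map[keep_rows]
      map[] <- tm$individual[keep_rows]
    }
    trees <- lapply(p$trees, function(tr) {
      tr <- prune_to_labels(tr, intersect(tr$tip.label, names(map)))
      tr$tip.label <- unname(map[tr$tip.label])
      tr
    })
    list(p = p, trees = trees, labels = trees[[1]]$tip.label, map = map)
  })
  common <- Reduce(intersect, lapply(relab, `[[`, "labels"))
  if (!length(common))
    stop("leaf-label intersection across loci is empty; nothing to compare")
  lapply(relab, function(r) {
    trees <- lapply(r$trees, prune_to_labels, keep = common)
    tm <- r$p$taxon_map[r$p$taxon_map$leaf_label %in% names(r$map), , drop = FALSE]
    tm$leaf_label <- unname(r$map[tm$leaf_label])
    tm <- tm[tm$leaf_label %in% common, , drop = FALSE]
    gene_tree_posterior(r$p$locus, trees, tm, units = r$p$units)
  })
}

# individuals present in a harmonized posterior set (ingroup only)
individuals_of <- function(posteriors) {
  tm <- posteriors[[1]]$taxon_map
  sort(unique(tm$individual[tm$ingroup]))
}

# leaf labels belonging to a set of individuals
leaves_of_individuals <- function(taxon_map, individuals) {
  taxon_map$leaf_label[taxon_map$individual %in% individuals]
}

# drop the given individuals (all their haplotypes) from every tree of every
# posterior; taxon maps updated accordingly
drop_individuals <- function(posteriors, individuals) {
  lapply(posteriors, function(p) {
    gone <- leaves_of_individuals(p$taxon_map, individuals)
    keep <- setdiff(p$trees[[1]]$tip.label, gone)
    if (length(keep) < 3) stop("removal would leave fewer than 3 leaves")
    trees <- lapply(p$trees, prune_to_labels, keep = keep)
    tm <- p$taxon_map[!(p$taxon_map$individual %in% individuals), , drop = FALSE]
    gene_tree_posterior(p$locus, trees, tm, units = p$units)
  })
}
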
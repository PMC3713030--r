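#' Collapse internal edges below a support threshold
#'
#' Keeps only the supported topology: every internal edge whose child node
#' carries a support value below the threshold is contracted into a
#' polytomy.  Polytomies are not auto-resolved.  The returned tree is
#' topology-only (branch lengths dropped).
#'
#' @param consensus A `phylo` whose internal nodes carry supports in `[0,1]`
#'   as `node.label` (the root label may be empty; it is kept).
#' @param threshold Minimum support to retain an edge (default 0.95).
#' @param assume_supported Treat missing/empty supports as supported rather
#'   than erroring.
#' @return A `phylo` with polytomies where support < threshold.
#' @export
collapse_unsupported <- function(consensus, threshold = 0.95,
                                 assume_supported = FALSE) {
  n <- length(consensus$tip.label)
  if (is.null(consensus$node.label)) {
    if (assume_supported) return(consensus)
    stop("tree carries no support values; set assume_supported = TRUE to keep it")
  }
  sup <- suppressWarnings(as.numeric(consensus$node.label))
  if (anyNA(sup[-1]) && !assume_supported)
    stop("non-numeric support on ", sum(is.na(sup[-1])), " internal node(s)")
  tr <- consensus
  child <- tr$edge[, 2]
  internal <- child > n
  keep_edge <- rep(TRUE, nrow(tr$edge))
  idx <- child[internal] - n           # node.label index of internal children
  s <- sup[idx]
  keep_edge[internal] <- is.na(s) | s >= threshold
  tr$edge.length <- ifelse(keep_edge, 1, 0)
  tr$node.label <- NULL
  out <- ape::di2multi(tr, tol = 0.5)
  out$edge.length <- NULL
  out
}

# logical leafset matrix (rows = nodes, cols = tips) for a rooted phylo
clade_matrix <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  m <- matrix(FALSE, nn, n)
  m[cbind(1:n, 1:n)] <- TRUE
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(eo))) m[eo[i, 1], ] <- m[eo[i, 1], ] | m[eo[i, 2], ]
  m
}

#' Deep-coalescence cost of a gene tree in a species tree
#'
#' The standard extra-lineage count: the gene tree is embedded in the rooted
#' species tree and, for every species-tree branch, the number of gene
#' lineages exiting it minus one is accrued.  A set of gene leaves can merge
#' into one lineage within a species-tree branch only if it forms a gene-tree
#' clade contained in that branch's species set, so the lineages exiting the
#' branch above node v are the maximal gene-tree clades whose leaves all map
#' into v's clade.  Gene-tree polytomies count as simultaneous multi-way
#' coalescences.
#'
#' @param species_tree Rooted `phylo` on species labels.
#' @param gene_tree Rooted `phylo` (polytomies allowed) on gene leaf labels.
#' @param map Named character vector `leaf label -> species`, or a taxon map
#'   data frame (uses its `group` column).
#' @return Non-negative integer cost.
#' @export
deep_coalescence_cost <- function(species_tree, gene_tree, map) {
  if (is.data.frame(map))
    map <- stats::setNames(map$group, map$leaf_label)
  gl <- gene_tree$tip.label
  sp <- unname(map[gl])
  if (anyNA(sp))
    stop("gene leaves missing from the map: ",
         paste(gl[is.na(sp)], collapse = ", "))
  if (!all(sp %in% species_tree$tip.label))
    stop("map assigns leaves to species absent from the species tree")
  ns <- length(species_tree$tip.label)
  ng <- length(gl)
  smat <- clade_matrix(species_tree)            # species clades
  gmat <- clade_matrix(gene_tree)               # gene clades
  # gene leaves -> species-index membership
  spidx <- match(sp, species_tree$tip.label)
  g_parent <- integer(ng + gene_tree$Nnode)
  g_parent[gene_tree$edge[, 2]] <- gene_tree$edge[, 1]
  g_parent[ng + 1L] <- 0L
  cost <- 0L
  for (v in seq_len(ns + species_tree$Nnode)) {
    if (v == ns + 1L) next                      # root has no parent branch
    allowed <- which(smat[v, ])                 # species inside clade v
    inside <- spidx %in% allowed                # gene leaves inside clade v
    if (!any(inside)) next
    # gene nodes fully inside clade v
    ok <- gmat[, inside, drop = FALSE]
    full <- rowSums(gmat) == rowSums(ok) & rowSums(ok) > 0
    # maximal: parent not fully inside (or node is the gene root)
    par_ok <- ifelse(g_parent == 0L, FALSE, full[pmax(g_parent, 1L)])
    exits <- sum(full & !par_ok)
    cost <- cost + exits - 1L
  }
  as.integer(cost)
}

#' Species-tree inference by minimizing deep coalescences
#'
#' Scores rooted species-tree topologies by the total deep-coalescence cost
#' across loci and returns all co-optimal trees.  Exhaustive over all
#' rooted topologies up to 7 species; larger problems use a
#' nearest-neighbour-interchange hill climb with restarts.
#'
#' @param gene_trees List of rooted `phylo` gene trees (supported
#'   topologies; polytomies allowed).
#' @param map Named vector or taxon map data frame mapping gene leaves to
#'   species.
#' @param species Optional character vector fixing the species set
#'   (default: all species appearing in the map for the supplied leaves).
#' @param exhaustive Force or forbid exhaustive search (default: automatic,
#'   exhaustive up to 7 species).
#' @param n_restarts Restarts for the heuristic search.
#' @param seed Seed for the heuristic search.
#' @return An object of class `mdc_fit`: `best_trees` (all co-optimal
#'   rooted trees), `cost`, `per_locus` cost matrix of the best tree(s),
#'   `mode`.
#' @export
mdc_species_tree <- function(gene_trees, map, species = NULL,
                             exhaustive = NULL, n_restarts = 10, seed = 1) {
  if (!length(gene_trees)) stop("no gene trees supplied")
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (is.data.frame(map))
    map <- stats::setNames(map$group, map$leaf_label)
  if (is.null(species)) {
    leaves <- unique(unlist(lapply(gene_trees, `[[`, "tip.label")))
    species <- sort(unique(unname(map[leaves])))
  }
  k <- length(species)
  if (k < 3) stop("need at least 3 species")
  if (is.null(exhaustive)) exhaustive <- k <= 7
  score <- function(st) vapply(gene_trees, function(gt)
    deep_coalescence_cost(st, gt, map), integer(1))
  if (exhaustive) {
    cands <- phangorn::allTrees(k, rooted = TRUE, tip.label = species)
    per <- vapply(cands, function(st) sum(score(st)), numeric(1))
    best <- which(per == min(per))
    fits <- lapply(best, function(i) cands[[i]])  # [[ restores tip labels
    mode <- "exhaustive"
  } else {
    set.seed(seed)
    best_cost <- Inf; fits <- list()
    for (r in seq_len(n_restarts)) {
      st <- ape::rtree(k, tip.label = sample(species))
      st$edge.length <- NULL
      cur <- sum(score(st))
      repeat {
        nb <- rooted_nni_neighbours(st)
        costs <- vapply(nb, function(x) sum(score(x)), numeric(1))
        if (min(costs) >= cur) break
        st <- nb[[which.min(costs)]]
        cur <- min(costs)
      }
      if (cur < best_cost) { best_cost <- cur; fits <- list(st) }
      else if (cur == best_cost &&
               !any(vapply(fits, function(f)
                 phangorn::RF.dist(f, st) == 0, logical(1))))
        fits <- c(fits, list(st))
    }
    per <- best_cost
    mode <- "heuristic"
  }
  per_locus <- vapply(gene_trees, function(gt)
    deep_coalescence_cost(fits[[1]], gt, map), integer(1))
  structure(list(best_trees = fits, cost = sum(per_locus),
                 per_locus = per_locus, mode = mode,
                 n_candidates = if (exhaustive) length(cands) else NA_integer_),
            class = "mdc_fit")
}

# all rooted NNI neighbours of a rooted binary tree (for the heuristic)
rooted_nni_neighbours <- function(tree) {
  n <- length(tree$tip.label)
  out <- list()
  internal_rows <- which(tree$edge[, 2] > n)
  for (row in internal_rows) {
    u <- tree$edge[row, 1]; v <- tree$edge[row, 2]
    vkids <- which(tree$edge[, 1] == v)
    sibs <- setdiff(which(tree$edge[, 1] == u), row)
    for (a in vkids) for (b in sibs) {
      tr <- tree
      tr$edge[a, 1] <- u
      tr$edge[b, 1] <- v
      attr(tr, "order") <- NULL
      out[[length(out) + 1L]] <- ape::reorder.phylo(tr, "cladewise")
    }
  }
  out
}

#' @export
print.mdc_fit <- function(x, ...) {
  cat("Minimize-deep-coalescences species tree (", x$mode, " search)\n", sep = "")
  cat("  total cost:", x$cost, " (per locus:",
      paste(x$per_locus, collapse = ", "), ")\n")
  cat("  co-optimal tree(s):", length(x$best_trees), "\n")
  for (tr in x$best_trees) cat("   ", ape::write.tree(tr), "\n")
  invisible(x)
}
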
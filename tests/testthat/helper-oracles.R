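# Independent brute-force oracles and small tree builders used across tests.

tree_from <- function(txt) ape::read.tree(text = txt)

# all non-trivial bipartitions of an unrooted tree, as canonical strings
# (each side sorted; the side containing the alphabetically first leaf kept)
oracle_bipartitions <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  ut <- if (ape::is.rooted(tree) && n > 2) ape::unroot(tree) else tree
  parts <- ape::prop.part(ut)
  out <- character(0)
  for (p in parts) {
    side <- sort(attr(parts, "labels")[p])
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (!labs[1] %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

# brute-force RF: symmetric difference of bipartition sets
oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# brute-force pruning oracle: rebuild the induced tree from leaf-to-leaf
# path lengths restricted to the kept set, via single-linkage on the
# cophenetic structure of the original tree
oracle_prune_paths <- function(tree, keep) {
  d <- ape::cophenetic.phylo(tree)[keep, keep, drop = FALSE]
  d
}

# independent deep-coalescence count: lineages exiting clade v equal
# |S_v| minus the lineage reductions from every gene coalescence fully
# inside S_v (for a node with c children the reduction is c - 1)
oracle_deep_coalescence <- function(species_tree, gene_tree, map) {
  ns <- length(species_tree$tip.label)
  gl <- gene_tree$tip.label
  sp <- unname(map[gl])
  smat <- coalhyb_clade_sets(species_tree)
  gsets <- coalhyb_clade_sets(gene_tree)
  nkids <- tabulate(gene_tree$edge[, 1],
                    nbins = length(gl) + gene_tree$Nnode)
  cost <- 0L
  for (v in seq_along(smat)) {
    if (v == ns + 1L) next
    species_in <- smat[[v]]
    leaves_in <- gl[sp %in% species_in]
    if (!length(leaves_in)) next
    reductions <- 0L
    for (u in seq_along(gsets)) {
      if (nkids[u] == 0) next
      if (all(gsets[[u]] %in% leaves_in))
        reductions <- reductions + nkids[u] - 1L
    }
    cost <- cost + (length(leaves_in) - reductions) - 1L
  }
  cost
}

# leaf-label sets below each node (tips included), by node id
coalhyb_clade_sets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  sets <- vector("list", nn)
  for (i in 1:n) sets[[i]] <- tree$tip.label[i]
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(eo)))
    sets[[eo[i, 1]]] <- c(sets[[eo[i, 1]]], sets[[eo[i, 2]]])
  sets
}

# every unrooted binary topology on the given leaves (15 for 5 leaves)
all_unrooted_topologies <- function(labels) {
  phangorn::allTrees(length(labels), rooted = FALSE, tip.label = labels)
}

# deterministic random coalescent-like tree for property tests
random_test_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# rooted-topology equality via canonical clade sets
coalhyb_same_rooted <- function(a, b) {
  can <- function(tree) sort(vapply(coalhyb_clade_sets(tree), function(x)
    paste(sort(x), collapse = "|"), character(1)))
  identical(can(a), can(b))
}
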
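#' Scaling configuration for chronograms
#'
#' Holds the calibration used to convert relative branch lengths into
#' generations: the age of the ingroup root in years and the generation time.
#' Defaults follow the Citrus calibration (root 5.9 Ma, 20-year generations,
#' hence a root depth of 295,000 generations).
#'
#' @param root_age_years Age of the root in years (> 0).
#' @param generation_time_years Generation time in years (> 0).
#' @param smoothing_method Tag for the ultrametricizing method.
#' @return An object of class `scaling_config`.
#' @export
scaling_config <- function(root_age_years = 5.9e6, generation_time_years = 20,
                           smoothing_method = "mean_path_length") {
  stopifnot(root_age_years > 0, generation_time_years > 0)
  structure(list(root_age_years = root_age_years,
                 generation_time_years = generation_time_years,
                 smoothing_method = smoothing_method),
            class = "scaling_config")
}

# node ages of an ultrametric-intended tree: distance below each node,
# computed as depth of deepest structure; returns vector over all node ids
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Make a tree ultrametric by mean-path-length smoothing
#'
#' Each node's age is set to the mean root-to-leaf path length beneath it,
#' measured from the node; child ages are then clipped so they never exceed
#' their parent's age.  The topology is unchanged, the output is exactly
#' ultrametric, and an already-ultrametric tree is returned with all node
#' ages preserved (the method is idempotent).
#'
#' @param tree A `phylo` with non-negative branch lengths and >= 1 leaf.
#' @param method Only `"mean_path_length"` is implemented; externally dated
#'   ultrametric trees can be supplied directly downstream.
#' @return An ultrametric `phylo`.
#' @export
make_ultrametric <- function(tree, method = "mean_path_length") {
  if (method != "mean_path_length")
    stop("unknown smoothing method: ", method)
  n <- length(tree$tip.label)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (n == 1) return(tree)
  depth <- node_depths(tree)
  if (max(depth) <= 0) stop("tree depth is zero; cannot smooth an all-zero tree")
  nnode <- n + tree$Nnode
  # postorder accumulation of (sum of leaf depths, leaf count) below each node
  sumd <- numeric(nnode); cnt <- integer(nnode)
  sumd[1:n] <- depth[1:n]; cnt[1:n] <- 1L
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(eo))) {
    p <- eo[i, 1]; ch <- eo[i, 2]
    sumd[p] <- sumd[p] + sumd[ch]
    cnt[p] <- cnt[p] + cnt[ch]
  }
  age <- sumd / cnt - depth       # mean leaf depth below minus own depth
  age[1:n] <- 0
  # preorder clipping: a child may not be older than its parent (negative
  # durations are disallowed; the number of clips is recorded)
  clipped <- 0L
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1]; ch <- pre[i, 2]
    if (age[ch] > age[p]) { age[ch] <- age[p]; clipped <- clipped + 1L }
  }
  out <- tree
  out$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  attr(out, "n_clipped") <- clipped
  out
}

#' Scale an ultrametric tree to generations
#'
#' Multiplies every branch length by one factor so that the root depth equals
#' `root_age_years / generation_time_years` generations.  A pure similarity
#' transform: ratios of branch lengths are unchanged.
#'
#' @param tree Ultrametric `phylo`.
#' @param cfg A [scaling_config()].
#' @param tol Relative ultrametricity tolerance.
#' @return A `chronogram`: a `phylo` in generations with attribute
#'   `root_depth_generations` and a provenance note.
#' @export
scale_to_generations <- function(tree, cfg = scaling_config(), tol = 1e-8) {
  n <- length(tree$tip.label)
  target <- cfg$root_age_years / cfg$generation_time_years
  if (n > 1) {
    depth <- node_depths(tree)
    tipd <- depth[1:n]
    d0 <- max(tipd)
    if (d0 <= 0) stop("tree depth is zero")
    if (diff(range(tipd)) > tol * d0)
      stop("input is not ultrametric; smooth it first (make_ultrametric)")
    tree$edge.length <- tree$edge.length * (target / d0)
  }
  structure(tree,
            class = c("chronogram", class(tree)),
            root_depth_generations = target,
            provenance = sprintf("%s; root %g yr / %g yr per generation",
                                 cfg$smoothing_method, cfg$root_age_years,
                                 cfg$generation_time_years))
}

#' Root depth of a chronogram, in generations
#' @param x A `chronogram`.
#' @export
root_depth <- function(x) {
  rd <- attr(x, "root_depth_generations")
  if (is.null(rd)) max(node_depths(x)) else rd
}
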
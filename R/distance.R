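#' Tree-to-tree distance
#'
#' Default metric is the unrooted Robinson-Foulds symmetric difference: the
#' number of bipartitions present in exactly one of the two trees.  It is
#' symmetric, zero iff the unrooted topologies agree, well defined for
#' polytomies, and bounded by 2(n-3) for binary unrooted n-leaf trees.
#' `"nrf"` divides by that bound; `"branch_score"` is the Kuhner-Felsenstein
#' branch-score distance (uses branch lengths).
#'
#' @param t1,t2 `phylo` objects on identical leaf-label sets.
#' @param metric `"rf"`, `"nrf"`, or `"branch_score"`.
#' @return A non-negative number.
#' @export
tree_distance <- function(t1, t2, metric = c("rf", "nrf", "branch_score")) {
  metric <- match.arg(metric)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets; harmonize them first ",
         "(see harmonize_posteriors)")
  switch(metric,
         rf = as.numeric(phangorn::RF.dist(t1, t2)),
         nrf = as.numeric(phangorn::RF.dist(t1, t2, normalize = TRUE)),
         branch_score = as.numeric(phangorn::KF.dist(t1, t2)))
}

#' All cross distances between two tree sets
#'
#' Computes every distance between members of `setA` and `setB`.  When the
#' two sets are the same object, self pairs are excluded and each unordered
#' pair is counted once (n(n-1)/2 values); otherwise all |A| x |B| values are
#' returned (two sets of 20 trees give the 400-combination pool used per
#' pairwise gene comparison).
#'
#' @param setA,setB Lists of `phylo` objects sharing one leaf set.
#' @param metric As in [tree_distance()].
#' @param label Optional pool label kept in the result.
#' @return An object of class `distance_pool`: list with `values`, `label`,
#'   `metric`, `n_a`, `n_b`.
#' @export
cross_distances <- function(setA, setB, metric = c("rf", "nrf", "branch_score"),
                            label = "") {
  metric <- match.arg(metric)
  if (inherits(setA, "phylo")) setA <- list(setA)
  if (inherits(setB, "phylo")) setB <- list(setB)
  same <- identical(setA, setB)
  labs <- sort(setA[[1]]$tip.label)
  for (tr in c(setA, if (!same) setB))
    if (!identical(sort(tr$tip.label), labs))
      stop("all trees must share one leaf set; harmonize them first")
  dfun <- switch(metric,
                 rf = function(x) phangorn::RF.dist(x),
                 nrf = function(x) phangorn::RF.dist(x, normalize = TRUE),
                 branch_score = function(x) phangorn::KF.dist(x))
  if (same) {
    vals <- as.numeric(dfun(as_multiphylo(setA)))
  } else {
    nA <- length(setA)
    m <- as.matrix(dfun(as_multiphylo(c(setA, setB))))
    vals <- as.numeric(m[seq_len(nA), nA + seq_along(setB)])
  }
  structure(list(values = vals, label = label, metric = metric,
                 n_a = length(setA), n_b = length(setB)),
            class = "distance_pool")
}

as_multiphylo <- function(trees) {
  class(trees) <- "multiPhylo"
  trees
}

#' @export
print.distance_pool <- function(x, ...) {
  cat("Distance pool", if (nzchar(x$label)) paste0("'", x$label, "'"), ":",
      length(x$values), x$metric, "distances,",
      sprintf("median %.3g, range [%.3g, %.3g]\n",
              stats::median(x$values), min(x$values), max(x$values)))
  invisible(x)
}
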
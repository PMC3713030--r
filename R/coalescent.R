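#' Coalescent simulation parameters
#'
#' @param ne_gene_copies Constant haploid effective size on every guide branch
#'   and above the root, in gene copies (default 8,000, the conservative
#'   ancestral value used for the Citrus test).
#' @param samples_per_tip Gene copies sampled per guide tip (default 1: guide
#'   tips are themselves haplotypes when the guide is an observed gene tree).
#' @return An object of class `coalescent_params`.
#' @export
coalescent_params <- function(ne_gene_copies = 8000, samples_per_tip = 1) {
  stopifnot(ne_gene_copies >= 1, samples_per_tip >= 1)
  structure(list(ne_gene_copies = ne_gene_copies,
                 samples_per_tip = samples_per_tip),
            class = "coalescent_params")
}

# Structured contained-coalescent engine.
#
# guide:   ultrametric phylo in generations (branch durations bound when
#          lineages may coalesce); tips are populations at time 0.
# samples: data.frame(label, tip) - one sampled gene copy per row, entering
#          the guide at its tip at age 0.
# moves:   optional data.frame(label, age, dest_tip): at `age` the lineage
#          carrying `label` relocates into the guide branch that contains
#          `age` on the path from `dest_tip` to the root (allele re-homing).
#
# Within each branch, k lineages coalesce with exponential waiting times at
# rate k(k-1)/(2 Ne) per generation; lineage sets merge at guide nodes; above
# the guide root coalescence continues at the same Ne until one lineage
# remains.  Returns an ultrametric phylo on `samples$label`.
contained_coalescent <- function(guide, ne, labels, tipidx, moves = NULL) {
  ntip_g <- length(guide$tip.label)
  nnode_g <- ntip_g + guide$Nnode
  root_g <- ntip_g + 1L
  depth <- node_depths(guide)
  gage <- max(depth) - depth            # guide node ages (tips ~ 0)
  parent_g <- integer(nnode_g)
  parent_g[guide$edge[, 2]] <- guide$edge[, 1]
  parent_g[root_g] <- 0L
  kids_g <- split(guide$edge[, 2], guide$edge[, 1])

  ns <- length(labels)
  if (ns == 0) stop("no samples to simulate")
  # coalescence records: node ids 1..ns are tips; internals appended in age order
  last_id <- 2L * ns - 1L
  out_age <- numeric(last_id)
  kid1 <- integer(last_id); kid2 <- integer(last_id)
  next_id <- ns + 1L

  pop <- rep(list(integer(0)), nnode_g) # lineages currently in each guide branch
  for (i in seq_len(ns)) pop[[tipidx[i]]] <- c(pop[[tipidx[i]]], i)
  active <- unique(tipidx)

  # event schedule: guide-node merges plus optional migrations, in age order
  ev_age <- gage[root_g:nnode_g]
  ev_node <- root_g:nnode_g
  ev_sample <- rep(NA_integer_, length(ev_age))
  ev_dest <- rep(NA_integer_, length(ev_age))
  if (!is.null(moves) && length(moves$age)) {
    ev_age <- c(ev_age, moves$age)
    ev_node <- c(ev_node, rep(NA_integer_, length(moves$age)))
    ev_sample <- c(ev_sample, moves$sample)
    ev_dest <- c(ev_dest, moves$dest)
  }
  # ties: migrations first, then merges deepest-first so a zero-length chain
  # of guide nodes (equal ages) still funnels child populations upward
  nanc <- integer(nnode_g)
  pre <- ape::reorder.phylo(guide, "cladewise")$edge
  for (i in seq_len(nrow(pre))) nanc[pre[i, 2]] <- nanc[pre[i, 1]] + 1L
  key <- ifelse(is.na(ev_node), -1e9, -nanc[pmax(ev_node, 1L)])
  o <- order(ev_age, key)
  ev_age <- ev_age[o]; ev_node <- ev_node[o]
  ev_sample <- ev_sample[o]; ev_dest <- ev_dest[o]

  rexp1 <- stats::rexp
  coalesce_in <- function(lins, t0, t1) {
    k <- length(lins)
    t <- t0
    while (k >= 2) {
      w <- rexp1(1, rate = k * (k - 1) / (2 * ne))
      if (t + w > t1) break
      t <- t + w
      ij <- sample.int(k, 2)
      id <- next_id; next_id <<- next_id + 1L
      out_age[id] <<- t
      kid1[id] <<- lins[ij[1]]; kid2[id] <<- lins[ij[2]]
      lins <- c(lins[-ij], id)
      k <- k - 1L
    }
    lins
  }

  t_now <- 0
  for (r in seq_along(ev_age)) {
    t_next <- ev_age[r]
    if (t_next > t_now) {
      for (v in active) {
        if (length(pop[[v]]) >= 2) pop[[v]] <- coalesce_in(pop[[v]], t_now, t_next)
      }
      t_now <- t_next
    }
    if (!is.na(ev_node[r])) {           # merge populations at a guide node
      v <- ev_node[r]
      for (ch in kids_g[[as.character(v)]]) {
        pop[[v]] <- c(pop[[v]], pop[[ch]]); pop[[ch]] <- integer(0)
      }
      active <- c(setdiff(active, kids_g[[as.character(v)]]), v)
    } else {                            # migration: re-home one lineage
      s <- ev_sample[r]
      lin <- lineage_carrying(s, kid1, kid2, ns, next_id - 1L)
      for (v in active) {
        hit <- match(lin, pop[[v]])
        if (!is.na(hit)) { pop[[v]] <- pop[[v]][-hit]; break }
      }
      d <- ev_dest[r]
      while (parent_g[d] != 0L && gage[parent_g[d]] <= ev_age[r]) d <- parent_g[d]
      pop[[d]] <- c(pop[[d]], lin)
      active <- unique(c(active, d))
    }
  }
  # above the guide root
  stopifnot(sum(lengths(pop[-root_g])) == 0)
  lins <- pop[[root_g]]
  if (length(lins) >= 2) lins <- coalesce_in(lins, t_now, Inf)
  stopifnot(length(lins) == 1)

  build_phylo_from_records(ns, out_age, kid1, kid2, labels)
}

# which current lineage contains sample s (follow merges from the leaf up)
lineage_carrying <- function(s, kid1, kid2, ns, last_id) {
  cur <- s
  repeat {
    parent <- NA_integer_
    if (last_id > ns) {
      for (id in seq.int(ns + 1L, last_id)) {
        if (kid1[id] == cur || kid2[id] == cur) { parent <- id; break }
      }
    }
    if (is.na(parent)) return(cur)
    cur <- parent
  }
}

# assemble an ape phylo from coalescence records (ids 1..ns are tips at age 0)
build_phylo_from_records <- function(ns, out_age, kid1, kid2, tip_labels) {
  if (ns == 1) {
    tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         edge.length = 0, tip.label = tip_labels,
                         Nnode = 1L), class = "phylo")
    return(tr)
  }
  last_id <- 2L * ns - 1L
  n_int <- ns - 1L
  # internal creation order is by increasing age; ape wants root = ns+1
  newid <- integer(last_id)
  newid[seq_len(ns)] <- seq_len(ns)
  newid[seq.int(ns + 1L, last_id)] <- ns + rev(seq_len(n_int))
  ids <- seq.int(ns + 1L, last_id)
  child <- c(kid1[ids], kid2[ids])
  par <- c(ids, ids)
  edge <- cbind(newid[par], newid[child])
  elen <- out_age[par] - out_age[child]
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = tip_labels, Nnode = n_int),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate one gene tree by coalescence contained in a guide chronogram
#'
#' Proceeds from the tips toward the root: within each guide branch of
#' duration t, k extant gene lineages coalesce with exponential waiting times
#' at rate k(k-1)/(2 Ne) per generation until the branch is exhausted;
#' lineage sets merge at guide nodes; above the guide root coalescence
#' continues at the same Ne until a single lineage remains.  Branch lengths
#' of the returned tree are in generations and the tree is ultrametric with
#' root depth >= the guide root depth.
#'
#' @param guide Ultrametric `phylo`/`chronogram` with branch lengths in
#'   generations.
#' @param params A [coalescent_params()].
#' @param seed Optional integer seed.
#' @return A binary rooted ultrametric `phylo`.  With `samples_per_tip = 1`
#'   leaves carry the guide tip labels; otherwise labels are
#'   `tip_1 ... tip_k`.
#' @export
simulate_contained_tree <- function(guide, params = coalescent_params(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ne <- params$ne_gene_copies
  if (ne < 1) stop("Ne must be >= 1")
  ntip <- length(guide$tip.label)
  if (ntip > 1) {
    tipd <- node_depths(guide)[1:ntip]
    if (diff(range(tipd)) > 1e-6 * max(tipd))
      stop("guide must be ultrametric (in generations)")
  }
  k <- params$samples_per_tip
  if (k == 1) {
    labels <- guide$tip.label
    tipidx <- seq_len(ntip)
  } else {
    labels <- paste0(rep(guide$tip.label, each = k), "_", seq_len(k))
    tipidx <- rep(seq_len(ntip), each = k)
  }
  contained_coalescent(guide, ne, labels, tipidx)
}

#' Simulate the per-gene null set of coalescent trees
#'
#' For each of the posterior draws of a locus: smooth to ultrametric, scale
#' to generations, then simulate exactly one contained coalescent tree.  The
#' resulting trees (one per draw, 20 by default) form the lineage-sorting
#' null for that locus.
#'
#' @param posterior A `gene_tree_posterior` (harmonized, ingroup only).
#' @param cfg A [scaling_config()].
#' @param params A [coalescent_params()].
#' @param seed Optional integer seed (deterministic output given seed).
#' @return A list of simulated `phylo` trees, in posterior order.
#' @export
simulate_null_set <- function(posterior, cfg = scaling_config(),
                              params = coalescent_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(posterior$trees, function(tr) {
    guide <- scale_to_generations(make_ultrametric(tr), cfg)
    simulate_contained_tree(guide, params)
  })
}
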
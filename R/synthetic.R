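#' Default four-species guide chronogram
#'
#' Rooted species chronogram (trifoliate,(pummelo,(citron,mandarin))) with an
#' ingroup depth of 295,000 generations (5.9 Ma at a 20-year generation
#' time).  Internal divergences are placed at 225,000 and 160,000
#' generations, many multiples of the default Ne of 8,000 gene copies, so
#' between-species lineage sorting is rare while within-species genealogies
#' vary freely.
#'
#' @param depth Root depth in generations.
#' @return A `chronogram`.
#' @export
default_species_tree <- function(depth = 295000) {
  f <- depth / 295000
  txt <- sprintf("(TRF:%.8g,(PUM:%.8g,(CIT:%.8g,MAN:%.8g):%.8g):%.8g);",
                 295000 * f, 225000 * f, 160000 * f, 160000 * f,
                 65000 * f, 70000 * f)
  tr <- ape::read.tree(text = txt)
  structure(tr, class = c("chronogram", class(tr)),
            root_depth_generations = depth,
            provenance = "default synthetic species chronogram")
}

#' Describe a hybridization event
#'
#' Allele re-homing: at the affected loci, all (or one) of the individual's
#' gene copies trace their ancestry into the donor lineage from the transfer
#' time backward, the minimal mechanism producing alleles drawn from
#' different parts of the tree at different genes.
#'
#' @param individual Individual id (e.g. `"MAN1"`).
#' @param donor Donor species label (must differ from the home species).
#' @param loci Integer vector of affected locus indices (non-empty).
#' @param time Transfer time in generations before present (< tree depth).
#' @param haplotypes Which haplotypes move: `"both"` (default) or one suffix
#'   (e.g. `"A"`) for a heterozygous hybrid.
#' @return An object of class `hybrid_event`.
#' @export
hybrid_event <- function(individual, donor, loci, time = 1000,
                         haplotypes = "both") {
  if (!length(loci)) stop("affected locus set must be non-empty")
  structure(list(individual = individual, donor = donor,
                 loci = as.integer(loci), time = time,
                 haplotypes = haplotypes),
            class = "hybrid_event")
}

#' Define a synthetic multi-locus coalescent scenario
#'
#' Fully specifies the study conditions emulated by the generator: a small
#' rooted species chronogram, a constant haploid effective size of 8,000
#' gene copies, 3 individuals per species with 2 haplotypes each, 3 unlinked
#' loci, optional hybridization events, and per-locus pseudo-posterior
#' samples of 20 trees whose topological uncertainty concentrates on short
#' branches.
#'
#' @param species_tree Guide `chronogram` (default [default_species_tree()]).
#' @param ne_gene_copies Haploid effective size (default 8,000).
#' @param n_individuals Individuals sampled per species (default 3).
#' @param n_haplotypes Haplotypes per individual (default 2).
#' @param n_loci Number of unlinked loci (default 3).
#' @param hybrids List of [hybrid_event()]s (default none).
#' @param n_post Pseudo-posterior draws per locus (default 20).
#' @param intensity Pseudo-posterior perturbation intensity (default 0.07,
#'   calibrated so the median within-posterior RF distance is about 2-4 on
#'   the default 24-leaf trees).
#' @param seed Master seed recorded in the scenario.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(species_tree = default_species_tree(),
                               ne_gene_copies = 8000,
                               n_individuals = 3, n_haplotypes = 2,
                               n_loci = 3, hybrids = list(),
                               n_post = 20, intensity = 0.07, seed = 1) {
  stopifnot(n_individuals >= 1, n_haplotypes >= 1, n_haplotypes <= 2,
            n_loci >= 2, n_post >= 2, intensity >= 0)
  if (inherits(hybrids, "hybrid_event")) hybrids <- list(hybrids)
  sp <- species_tree$tip.label
  depth <- root_depth(species_tree)
  inds <- unlist(lapply(sp, function(s) paste0(s, seq_len(n_individuals))))
  home <- stats::setNames(rep(sp, each = n_individuals), inds)
  for (h in hybrids) {
    if (!h$individual %in% inds) stop("unknown hybrid individual: ", h$individual)
    if (!h$donor %in% sp) stop("unknown donor species: ", h$donor)
    if (h$donor == home[[h$individual]])
      stop("donor must differ from the individual's home species")
    if (any(h$loci < 1 | h$loci > n_loci)) stop("hybrid event names an unknown locus")
    if (h$time >= depth) stop("transfer time must be below the tree depth")
  }
  suffixes <- c("A", "B")[seq_len(n_haplotypes)]
  taxon_map <- data.frame(
    leaf_label = if (n_haplotypes == 1) inds
                 else paste0(rep(inds, each = n_haplotypes), "_", suffixes),
    individual = rep(inds, each = n_haplotypes),
    haplotype = if (n_haplotypes == 1) "none" else suffixes,
    group = rep(unname(home), each = n_haplotypes),
    ingroup = TRUE, stringsAsFactors = FALSE)
  structure(list(species_tree = species_tree, ne_gene_copies = ne_gene_copies,
                 n_individuals = n_individuals, n_haplotypes = n_haplotypes,
                 n_loci = n_loci, hybrids = hybrids, n_post = n_post,
                 intensity = intensity, seed = seed,
                 taxon_map = taxon_map, home = home),
            class = "synthetic_scenario")
}

#' The default one-hybrid power scenario
#'
#' One mandarin individual carries re-homed alleles at two of the three loci
#' (to trifoliate, across the species-tree root, at locus 1; to pummelo at
#' locus 3; home at locus 2), transferred close to the present.  Every pair
#' of genes then shows incongruent placements for that individual - the
#' allele signature of a complex hybrid.  A single-locus displacement is
#' deliberately not the default: the test retains the null whenever any gene
#' pair is concordant, so such a hybrid is undetectable by construction.
#'
#' @param time Transfer time in generations (default 1,000).
#' @param ... Passed on to [synthetic_scenario()].
#' @export
default_hybrid_scenario <- function(time = 1000, ...) {
  synthetic_scenario(hybrids = list(
    hybrid_event("MAN1", "TRF", loci = 1, time = time),
    hybrid_event("MAN1", "PUM", loci = 3, time = time)), ...)
}

#' Simulate the true gene tree of each locus
#'
#' Each haplotype's containing population is its individual's home species
#' unless a hybrid event covers that (individual, locus), in which case the
#' affected gene copies re-home into the donor lineage from the transfer
#' time backward.  Gene trees are simulated by the contained coalescent in
#' the species chronogram.
#'
#' @param scenario A [synthetic_scenario()].
#' @param seed Integer seed (defaults to the scenario master seed).
#' @return A list of `n_loci` ultrametric `phylo` trees on the haplotype
#'   leaf labels, branch lengths in generations.
#' @export
generate_true_gene_trees <- function(scenario, seed = scenario$seed) {
  if (!is.null(seed)) set.seed(seed)
  tm <- scenario$taxon_map
  guide <- scenario$species_tree
  tipidx <- match(tm$group, guide$tip.label)
  lapply(seq_len(scenario$n_loci), function(locus) {
    mv_s <- integer(0); mv_d <- integer(0); mv_t <- numeric(0)
    for (h in scenario$hybrids) {
      if (!locus %in% h$loci) next
      rows <- which(tm$individual == h$individual &
                      (h$haplotypes == "both" | tm$haplotype == h$haplotypes))
      mv_s <- c(mv_s, rows)
      mv_d <- c(mv_d, rep(match(h$donor, guide$tip.label), length(rows)))
      mv_t <- c(mv_t, rep(h$time, length(rows)))
    }
    moves <- if (length(mv_s)) list(sample = mv_s, dest = mv_d, age = mv_t)
    contained_coalescent(guide, scenario$ne_gene_copies,
                         labels = tm$leaf_label, tipidx = tipidx,
                         moves = moves)
  })
}

#' Perturb a tree into a pseudo-posterior sample
#'
#' Emulates a Bayesian posterior of `n_post` trees: each draw multiplies
#' every branch length by independent lognormal noise (sdlog = intensity)
#' and applies a nearest-neighbour interchange at each internal edge with
#' probability `intensity * exp(-len/lambda)`, so topological uncertainty
#' concentrates on short branches.  `intensity = 0` returns exact copies.
#'
#' @param true_tree A rooted binary `phylo`.
#' @param n_post Number of draws (>= 2).
#' @param intensity Non-negative perturbation intensity.
#' @param seed Optional integer seed (byte-identical output given the seed).
#' @param lambda NNI length scale; default 5% of tree height.
#' @return A list of `n_post` `phylo` trees.
#' @export
make_pseudo_posterior <- function(true_tree, n_post = 20, intensity = 0.07,
                                  seed = NULL, lambda = NULL) {
  stopifnot(n_post >= 2, intensity >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (intensity == 0) return(rep(list(true_tree), n_post))
  if (is.null(lambda)) lambda <- 0.05 * max(node_depths(true_tree))
  lapply(seq_len(n_post), function(i)
    perturb_tree(true_tree, intensity, lambda))
}

# one pseudo-posterior draw: seeded NNIs on short internal edges + lognormal
# branch-length noise
perturb_tree <- function(tree, intensity, lambda) {
  tr <- tree
  n <- length(tr$tip.label)
  root <- n + 1L
  internal_rows <- which(tr$edge[, 2] > n)
  p_nni <- pmin(1, intensity) * exp(-tr$edge.length[internal_rows] / lambda)
  hit <- internal_rows[stats::runif(length(internal_rows)) < p_nni]
  for (row in hit) {
    u <- tr$edge[row, 1]; v <- tr$edge[row, 2]
    vkids <- which(tr$edge[, 1] == v)
    sibs <- setdiff(which(tr$edge[, 1] == u), row)
    if (!length(vkids) || !length(sibs)) next
    a <- vkids[sample.int(length(vkids), 1)]   # child edge of v to move up
    b <- sibs[sample.int(length(sibs), 1)]     # sibling edge to move down
    tr$edge[a, 1] <- u
    tr$edge[b, 1] <- v
  }
  tr$edge.length <- tr$edge.length *
    exp(stats::rnorm(length(tr$edge.length), 0, intensity))
  attr(tr, "order") <- NULL   # edges were edited in place; force real reorder
  ape::reorder.phylo(tr, "cladewise")
}

#' Generate the full pseudo-posterior dataset of a scenario
#'
#' Composes [generate_true_gene_trees()] and [make_pseudo_posterior()] into
#' the list of per-locus posteriors consumed by [phi_test()].
#'
#' @param scenario A [synthetic_scenario()].
#' @param seed Integer seed (defaults to the scenario master seed).
#' @return List of `gene_tree_posterior` objects, loci named `L1, L2, ...`.
#' @export
simulate_posteriors <- function(scenario, seed = scenario$seed) {
  true_trees <- generate_true_gene_trees(scenario, seed = seed)
  lapply(seq_along(true_trees), function(i) {
    trees <- make_pseudo_posterior(true_trees[[i]], scenario$n_post,
                                   scenario$intensity)
    gene_tree_posterior(paste0("L", i), trees, scenario$taxon_map,
                        units = "generations")
  })
}

#' Write a scenario's dataset and manifest to disk
#'
#' Emits one Newick file of `n_post` trees per locus, the taxon map TSV, and
#' a JSON manifest holding every parameter and the master seed, sufficient
#' to regenerate the files bit-identically via [scenario_from_manifest()].
#'
#' @param scenario A [synthetic_scenario()].
#' @param outdir Writable output directory (created if absent).
#' @return Invisibly, the vector of written file paths.
#' @export
emit_scenario <- function(scenario, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  posts <- simulate_posteriors(scenario)
  paths <- character(0)
  for (p in posts) {
    f <- file.path(outdir, paste0(p$locus, ".nwk"))
    write_gene_trees(p$trees, f)
    paths <- c(paths, f)
  }
  tm_path <- file.path(outdir, "taxon_map.tsv")
  utils::write.table(scenario$taxon_map, tm_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  man <- list(species_tree = ape::write.tree(scenario$species_tree),
              ne_gene_copies = scenario$ne_gene_copies,
              n_individuals = scenario$n_individuals,
              n_haplotypes = scenario$n_haplotypes,
              n_loci = scenario$n_loci, n_post = scenario$n_post,
              intensity = scenario$intensity, seed = scenario$seed,
              hybrids = lapply(scenario$hybrids, unclass))
  man_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, tm_path, man_path))
}

#' Rebuild a scenario from an emitted manifest
#'
#' @param path Path to a `manifest.json` written by [emit_scenario()].
#' @return The reconstructed [synthetic_scenario()].
#' @export
scenario_from_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- ape::read.tree(text = man$species_tree)
  sp_tree <- structure(tr, class = c("chronogram", class(tr)),
                       root_depth_generations = max(node_depths(tr)),
                       provenance = "restored from manifest")
  hybrids <- list()
  if (length(man$hybrids)) {
    hy <- man$hybrids
    hybrids <- lapply(seq_len(nrow(hy)), function(i)
      hybrid_event(hy$individual[i], hy$donor[i], unlist(hy$loci[i]),
                   hy$time[i], hy$haplotypes[i]))
  }
  synthetic_scenario(species_tree = sp_tree,
                     ne_gene_copies = man$ne_gene_copies,
                     n_individuals = man$n_individuals,
                     n_haplotypes = man$n_haplotypes,
                     n_loci = man$n_loci, hybrids = hybrids,
                     n_post = man$n_post, intensity = man$intensity,
                     seed = man$seed)
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic coalescent scenario:", length(x$species_tree$tip.label),
      "species,", x$n_individuals, "ind/species,", x$n_haplotypes,
      "haplotypes/ind,", x$n_loci, "loci\n")
  cat("  Ne =", x$ne_gene_copies, "gene copies; depth =",
      root_depth(x$species_tree), "generations; seed =", x$seed, "\n")
  if (length(x$hybrids)) {
    for (h in x$hybrids)
      cat(sprintf("  hybrid: %s <- %s at loci {%s}, t = %g\n", h$individual,
                  h$donor, paste(h$loci, collapse = ","), h$time))
  } else cat("  no hybridization events (pure lineage sorting)\n")
  invisible(x)
}
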
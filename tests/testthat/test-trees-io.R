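test_that("Newick parsing preserves order, branch lengths and degenerate cases", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((A:1,B:1):1,C:2);", "((A:1,C:1):1,B:2);"), tmp)
  trees <- read_gene_trees(tmp)
  expect_length(trees, 2)
  expect_equal(sort(trees[[1]]$tip.label), c("A", "B", "C"))
  root_kids <- trees[[1]]$edge[trees[[1]]$edge[, 1] == 4, 2]
  expect_length(root_kids, 2)
  expect_equal(sort(trees[[1]]$edge.length), c(1, 1, 1, 2))

  # single-leaf tree accepted
  writeLines("(A:1);", tmp)
  one <- read_gene_trees(tmp)
  expect_equal(one[[1]]$tip.label, "A")

  # a 20-line file yields 20 trees, in order
  writeLines(rep("((A:1,B:1):1,C:2);", 20), tmp)
  expect_length(read_gene_trees(tmp), 20)
})

test_that("duplicate leaf labels are rejected", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,A:1):1,C:2);", tmp)
  expect_error(read_gene_trees(tmp), "duplicate")
})

test_that("write/read round trip preserves topology and branch lengths", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  for (seed in 1:5) {
    tr <- random_test_tree(12, seed)
    tr$edge.length <- tr$edge.length * 295000 / max(ape::node.depth.edgelength(tr))
    write_gene_trees(tr, tmp)
    back <- read_gene_trees(tmp)[[1]]
    expect_equal(tree_distance(tr, back), 0)
    # leaf-to-leaf path lengths identify every branch length given the
    # (identical) topology; >= 10 significant digits survive the round trip
    labs <- tr$tip.label
    expect_equal(ape::cophenetic.phylo(back)[labs, labs],
                 ape::cophenetic.phylo(tr)[labs, labs], tolerance = 1e-10)
  }
})

test_that("pruning adds path lengths and is the induced-topology restriction", {
  tr <- tree_from("((A:1,B:1):1,C:2);")
  pr <- prune_to_labels(tr, c("A", "C"))
  expect_equal(sort(pr$tip.label), c("A", "C"))
  expect_equal(sum(pr$edge.length), 4)  # A:2 + C:2

  # identity on the full leaf set
  expect_identical(prune_to_labels(tr, tr$tip.label), tr)

  # property: pruned leaf-to-leaf path lengths equal the original ones
  for (seed in 1:6) {
    tr <- random_test_tree(8, seed)
    keep <- sort(sample(tr$tip.label, 5))
    pr <- prune_to_labels(tr, keep)
    expect_equal(sort(pr$tip.label), keep)
    expect_equal(ape::cophenetic.phylo(pr)[keep, keep],
                 ape::cophenetic.phylo(tr)[keep, keep], tolerance = 1e-12)
  }

  expect_error(prune_to_labels(tr, character(0)), "non-empty")
  expect_error(prune_to_labels(tr, c("A", "nope")), "unknown")
})

test_that("a 24-leaf tree minus one individual's haplotypes keeps 22 leaves", {
  sc <- synthetic_scenario(seed = 5)
  tt <- generate_true_gene_trees(sc, seed = 5)[[1]]
  keep <- setdiff(tt$tip.label, c("CIT1_A", "CIT1_B"))
  pr <- prune_to_labels(tt, keep)
  expect_equal(length(pr$tip.label), 22)
  expect_equal(ape::cophenetic.phylo(pr)[keep, keep],
               ape::cophenetic.phylo(tt)[keep, keep], tolerance = 1e-9)
})

test_that("harmonization intersects leaf sets, relabels, and is idempotent", {
  sc <- synthetic_scenario(seed = 3)
  post <- simulate_posteriors(sc, seed = 3)

  # identical leaf sets: relabeling only
  h <- harmonize_posteriors(post)
  expect_equal(sort(h[[1]]$trees[[1]]$tip.label),
               sort(post[[1]]$trees[[1]]$tip.label))

  # one locus missing an individual: intersection rule prunes everywhere
  post2 <- post
  keep <- setdiff(post[[2]]$trees[[1]]$tip.label, c("PUM3_A", "PUM3_B"))
  post2[[2]] <- gene_tree_posterior(
    post[[2]]$locus,
    lapply(post[[2]]$trees, prune_to_labels, keep = keep),
    post[[2]]$taxon_map[post[[2]]$taxon_map$leaf_label %in% keep, ],
    units = post[[2]]$units)
  h2 <- harmonize_posteriors(post2)
  for (p in h2)
    expect_false(any(c("PUM3_A", "PUM3_B") %in% p$trees[[1]]$tip.label))
  common <- sort(h2[[1]]$trees[[1]]$tip.label)
  for (p in h2) for (tr in p$trees)
    expect_equal(sort(tr$tip.label), common)

  # idempotent
  h3 <- harmonize_posteriors(h2)
  expect_equal(lapply(h3, function(p) sort(p$trees[[1]]$tip.label)),
               lapply(h2, function(p) sort(p$trees[[1]]$tip.label)))
})

test_that("outgroups are dropped and disjoint leaf sets error", {
  map1 <- data.frame(leaf_label = c("X_A", "X_B", "OUT"),
                     individual = c("X", "X", "OG"),
                     haplotype = c("A", "B", "none"),
                     group = c("sp1", "sp1", "out"),
                     ingroup = c(TRUE, TRUE, FALSE))
  t1 <- tree_from("((X_A:1,X_B:1):1,OUT:2);")
  p1 <- gene_tree_posterior("g1", list(t1, t1), map1)
  h <- harmonize_posteriors(list(p1, p1))
  expect_equal(sort(h[[1]]$trees[[1]]$tip.label), c("X_A", "X_B"))

  map2 <- data.frame(leaf_label = c("Y_A", "Y_B", "Z_A"),
                     individual = c("Y", "Y", "Z"),
                     haplotype = c("A", "B", "A"),
                     group = "sp1", ingroup = TRUE)
  t2 <- tree_from("((Y_A:1,Y_B:1):1,Z_A:2);")
  p2 <- gene_tree_posterior("g2", list(t2, t2), map2)
  expect_error(harmonize_posteriors(list(p1, p2)), "empty")
})

test_that("taxon map validation catches duplicates and bad columns", {
  tm <- data.frame(leaf_label = c("a", "a"), individual = c("i", "j"),
                   haplotype = c("A", "A"), group = "g", ingroup = TRUE)
  expect_error(validate_taxon_map(tm), "duplicated leaf labels")
  tm2 <- data.frame(leaf_label = c("a", "b"), individual = "i",
                    haplotype = "A", group = "g", ingroup = TRUE)
  expect_error(validate_taxon_map(tm2), "individual, haplotype")
  expect_error(validate_taxon_map(data.frame(leaf_label = "a")), "missing columns")
})

test_that("NEXUS trees blocks are read in order", {
  tmp <- withr::local_tempfile(fileext = ".nex")
  trees <- list(tree_from("((A:1,B:1):1,C:2);"), tree_from("((A:1,C:1):1,B:2);"))
  class(trees) <- "multiPhylo"
  ape::write.nexus(trees, file = tmp)
  back <- read_gene_trees(tmp, format = "nexus")
  expect_length(back, 2)
  expect_equal(tree_distance(back[[1]], trees[[1]]), 0)
  expect_equal(tree_distance(back[[2]], trees[[2]]), 0)
})
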
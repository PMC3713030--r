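test_that("scenario validation enforces the hybrid-event invariants", {
  expect_error(synthetic_scenario(hybrids = hybrid_event("MAN1", "MAN", 1)),
               "differ from the individual's home")
  expect_error(synthetic_scenario(hybrids = hybrid_event("XX1", "TRF", 1)),
               "unknown hybrid individual")
  expect_error(synthetic_scenario(hybrids = hybrid_event("MAN1", "TRF", 9)),
               "unknown locus")
  expect_error(synthetic_scenario(hybrids = hybrid_event("MAN1", "TRF", 1,
                                                         time = 4e5)),
               "below the tree depth")
  expect_error(hybrid_event("MAN1", "TRF", integer(0)), "non-empty")
})

test_that("true gene trees are reproducible and carry all haplotypes", {
  sc <- synthetic_scenario(seed = 12)
  a <- generate_true_gene_trees(sc)
  b <- generate_true_gene_trees(sc)
  expect_equal(lapply(a, ape::write.tree), lapply(b, ape::write.tree))
  expect_length(a, 3)
  expect_equal(sort(a[[1]]$tip.label), sort(sc$taxon_map$leaf_label))
})

test_that("hybrid haplotypes cluster with the donor at affected loci only", {
  # which side of the deepest split holds the trifoliate clade?
  trf_side <- function(tree) {
    root <- length(tree$tip.label) + 1L
    kids <- tree$edge[tree$edge[, 1] == root, 2]
    sets <- coalhyb_clade_sets(tree)
    for (k in kids) if ("TRF1_A" %in% sets[[k]]) return(sets[[k]])
    stop("no root child contains TRF1_A")
  }
  hits_donor <- 0; hits_home <- 0; n <- 25
  hyb <- c("MAN1_A", "MAN1_B")
  for (r in seq_len(n)) {
    sc <- synthetic_scenario(
      hybrids = hybrid_event("MAN1", "TRF", loci = 1, time = 100),
      seed = 6000 + r)
    tt <- generate_true_gene_trees(sc)
    # affected locus: the hybrid's alleles sit on the trifoliate side of
    # the root; unaffected locus: they stay on the home side
    if (all(hyb %in% trf_side(tt[[1]]))) hits_donor <- hits_donor + 1
    if (!any(hyb %in% trf_side(tt[[2]]))) hits_home <- hits_home + 1
  }
  expect_gte(hits_donor / n, 0.95)
  expect_gte(hits_home / n, 0.95)
})

test_that("pseudo-posteriors: exact copies at zero intensity, seeded output", {
  tt <- generate_true_gene_trees(synthetic_scenario(seed = 2))[[1]]
  p0 <- make_pseudo_posterior(tt, 20, 0)
  expect_length(p0, 20)
  expect_true(all(vapply(p0[-1], function(tr)
    tree_distance(tr, p0[[1]]) == 0, logical(1))))
  pa <- make_pseudo_posterior(tt, 5, 0.07, seed = 3)
  pb <- make_pseudo_posterior(tt, 5, 0.07, seed = 3)
  expect_identical(vapply(pa, ape::write.tree, character(1)),
                   vapply(pb, ape::write.tree, character(1)))
})

test_that("mean RF to the truth grows with perturbation intensity", {
  tt <- generate_true_gene_trees(synthetic_scenario(seed = 14))[[1]]
  mean_rf <- vapply(c(0.03, 0.12, 0.5), function(int) {
    set.seed(99)
    mean(vapply(make_pseudo_posterior(tt, 30, int), tree_distance,
                numeric(1), t2 = tt))
  }, numeric(1))
  expect_true(all(diff(mean_rf) > 0))
})

test_that("emitted scenarios regenerate bit-identically from their manifest", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sc <- default_hybrid_scenario(seed = 17, n_post = 5)
  files1 <- emit_scenario(sc, dir1)
  expect_setequal(basename(files1),
                  c("L1.nwk", "L2.nwk", "L3.nwk", "taxon_map.tsv",
                    "manifest.json"))
  expect_length(readLines(file.path(dir1, "L1.nwk")), 5)
  sc2 <- scenario_from_manifest(file.path(dir1, "manifest.json"))
  emit_scenario(sc2, dir2)
  for (f in c("L1.nwk", "L2.nwk", "L3.nwk", "taxon_map.tsv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  # both hybrid events listed in the manifest
  man <- jsonlite::read_json(file.path(dir1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(man$hybrids), 2)
  expect_setequal(man$hybrids$donor, c("TRF", "PUM"))
})
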
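test_that("support collapse contracts exactly the weak edges", {
  tr <- tree_from("(((A,B)0.99,(C,D)0.5)1.0,(E,F)0.97)root;")
  out <- collapse_unsupported(tr, threshold = 0.95)
  expect_setequal(out$tip.label, c("A", "B", "C", "D", "E", "F"))
  # (C,D) collapsed, (A,B) and (E,F) kept
  has_clade <- function(tree, tips) {
    sets <- coalhyb_clade_sets(tree)
    any(vapply(sets, function(s) setequal(s, tips), logical(1)))
  }
  expect_true(has_clade(out, c("A", "B")))
  expect_true(has_clade(out, c("E", "F")))
  expect_false(has_clade(out, c("C", "D")))

  # all supports 1.0: unchanged topology
  t2 <- tree_from("((A,B)1.0,(C,D)1.0)1.0;")
  expect_equal(tree_distance(collapse_unsupported(t2), t2), 0)

  # all internal supports below threshold: star tree
  t3 <- tree_from("(((A,B)0.5,C)0.5,(D,E)0.5)1.0;")
  star <- collapse_unsupported(t3)
  expect_equal(star$Nnode, 1)

  t4 <- tree_from("((A,B),C);")
  expect_error(collapse_unsupported(t4), "no support")
  expect_equal(tree_distance(collapse_unsupported(t4, assume_supported = TRUE),
                             t4), 0)
})

test_that("deep-coalescence cost: hand cases", {
  sp <- tree_from("((A,B),C);")
  map <- stats::setNames(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(deep_coalescence_cost(sp, tree_from("((A,B),C);"), map), 0)
  expect_equal(deep_coalescence_cost(sp, tree_from("((A,C),B);"), map), 1)
  # multiple alleles, concordant clustering: zero extra lineages
  sp2 <- tree_from("((X,Y),Z);")
  g2 <- tree_from("(((x1,x2),(y1,y2)),(z1,z2));")
  map2 <- stats::setNames(c("X", "X", "Y", "Y", "Z", "Z"),
                          c("x1", "x2", "y1", "y2", "z1", "z2"))
  expect_equal(deep_coalescence_cost(sp2, g2, map2), 0)
  expect_error(deep_coalescence_cost(sp, tree_from("((A,Q),B);"), map),
               "missing from the map")
})

test_that("cost equals the exhaustive-count oracle on all 4-leaf cases", {
  labs <- c("A", "B", "C", "D")
  map <- stats::setNames(labs, labs)
  sp_trees <- phangorn::allTrees(4, rooted = TRUE, tip.label = labs)
  g_trees <- phangorn::allTrees(4, rooted = TRUE, tip.label = labs)
  for (i in seq_along(sp_trees)) for (j in seq_along(g_trees)) {
    st <- sp_trees[[i]]; gt <- g_trees[[j]]
    expect_equal(deep_coalescence_cost(st, gt, map),
                 oracle_deep_coalescence(st, gt, map),
                 info = sprintf("species %d gene %d", i, j))
  }
})

test_that("cost is additive across loci and label-permutation invariant", {
  sp <- tree_from("((X,Y),Z);")
  g <- tree_from("(((x1,y1),x2),(z1,z2));")
  map <- stats::setNames(c("X", "X", "Y", "Z", "Z"),
                         c("x1", "x2", "y1", "z1", "z2"))
  c1 <- deep_coalescence_cost(sp, g, map)
  total <- sum(vapply(list(g, g, g), deep_coalescence_cost,
                      integer(1), species_tree = sp, map = map))
  expect_equal(total, 3 * c1)
  fit <- mdc_species_tree(list(g, g, g), map)
  expect_equal(fit$cost, sum(fit$per_locus))
  # permuting allele labels within a species leaves the cost unchanged
  g_swap <- g
  g_swap$tip.label[g_swap$tip.label == "x1"] <- "tmp"
  g_swap$tip.label[g_swap$tip.label == "x2"] <- "x1"
  g_swap$tip.label[g_swap$tip.label == "tmp"] <- "x2"
  expect_equal(deep_coalescence_cost(sp, g_swap, map), c1)
})

test_that("exhaustive MDC search recovers known minimal trees and ties", {
  map <- stats::setNames(c("A", "B", "C"), c("A", "B", "C"))
  tAB <- tree_from("((A,B),C);")
  tAC <- tree_from("((A,C),B);")
  # all loci identical: that tree, cost 0
  fit0 <- mdc_species_tree(list(tAB, tAB), map)
  expect_equal(fit0$cost, 0)
  expect_true(coalhyb_same_rooted(fit0$best_trees[[1]], tAB))
  # 2:1 vote: majority tree wins with cost 1
  fit1 <- mdc_species_tree(list(tAB, tAB, tAC), map)
  expect_equal(fit1$cost, 1)
  expect_length(fit1$best_trees, 1)
  expect_true(coalhyb_same_rooted(fit1$best_trees[[1]], tAB))
  # perfectly balanced conflict: co-optimal ties all reported
  fit2 <- mdc_species_tree(list(tAB, tAC), map)
  expect_equal(fit2$cost, 1)
  expect_gte(length(fit2$best_trees), 2)
  expect_error(mdc_species_tree(list(), map), "no gene trees")
})

test_that("exhaustive and heuristic searches agree on 4-species instances", {
  set.seed(8)
  labs <- paste0("s", 1:4)
  map <- stats::setNames(rep(labs, each = 2),
                         paste0(rep(labs, each = 2), "_", 1:2))
  for (rep in 1:3) {
    gts <- lapply(1:3, function(i) {
      tr <- ape::rtree(8)
      tr$tip.label <- sample(names(map))
      tr
    })
    ex <- mdc_species_tree(gts, map, exhaustive = TRUE)
    he <- mdc_species_tree(gts, map, exhaustive = FALSE, n_restarts = 20,
                           seed = rep)
    expect_equal(he$cost, ex$cost)
  }
})
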
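make_identical_posteriors <- function(n_loci = 3, seed = 1) {
  sc <- synthetic_scenario(seed = seed)
  tt <- generate_true_gene_trees(sc, seed = seed)[[1]]
  lapply(seq_len(n_loci), function(i)
    gene_tree_posterior(paste0("G", i), rep(list(tt), 20), sc$taxon_map,
                        units = "generations"))
}

test_that("identical posteriors across loci give phi < 0 (fail to reject)", {
  post <- make_identical_posteriors(seed = 21)
  ft <- phi_test(post, seed = 1)
  expect_true(all(vapply(ft$observed_pools, function(p)
    all(p$values == 0), logical(1))))
  expect_lt(ft$phi, 0)
  expect_false(ft$reject)
  expect_equal(unname(ft$phi), unname(min(ft$observed_lower) - max(ft$null_critical)))
})

test_that("pool sizes and determinism of the full test", {
  sc <- synthetic_scenario(seed = 31)
  post <- simulate_posteriors(sc, seed = 31)
  a <- phi_test(post, seed = 5)
  b <- phi_test(post, seed = 5)
  expect_equal(a$phi, b$phi)
  expect_equal(a$null_critical, b$null_critical)
  expect_length(a$null_pools[[1]]$values, 400)
  expect_length(a$observed_pools[[1]]$values, 400)
  expect_length(a$observed_lower, 3)   # three locus pairs
  expect_identical(a$reject, a$phi > 0)
})

test_that("phi is monotone in the critical and credibility quantiles", {
  sc <- synthetic_scenario(seed = 41)
  post <- simulate_posteriors(sc, seed = 41)
  # recompute phi from fixed pools under different quantile settings
  ft <- phi_test(post, seed = 6)
  phi_from_pools <- function(q_null, cred) {
    C <- vapply(ft$null_pools, function(p)
      quantile(p$values, q_null, type = 7, names = FALSE), numeric(1))
    L <- vapply(ft$observed_pools, function(p)
      quantile(p$values, (1 - cred) / 2, type = 7, names = FALSE), numeric(1))
    min(L) - max(C)
  }
  qs <- c(0.5, 0.8, 0.95, 1)
  phis <- vapply(qs, phi_from_pools, numeric(1), cred = 0.95)
  expect_true(all(diff(phis) <= 1e-12))        # non-increasing in null quantile
  creds <- c(0.5, 0.8, 0.95, 0.99)
  phis2 <- vapply(creds, function(cr) phi_from_pools(0.8, cr), numeric(1))
  expect_true(all(diff(phis2) <= 1e-12))       # non-increasing as lower bound drops
})

test_that("posteriors differing by one leaf placement keep all distances >= 2", {
  base <- tree_from("(((A:1,B:1):1,(C:1,D:1):1):1,E:3);")
  moved <- tree_from("(((A:1,C:1):1,(B:1,D:1):1):1,E:3);")
  tm <- data.frame(leaf_label = c("A", "B", "C", "D", "E"),
                   individual = c("A", "B", "C", "D", "E"),
                   haplotype = "none", group = "sp", ingroup = TRUE)
  pa <- gene_tree_posterior("ga", rep(list(base), 5), tm)
  pb <- gene_tree_posterior("gb", rep(list(moved), 5), tm)
  pool <- observed_pair(pa, pb, phi_config())
  expect_true(all(pool$values >= 2))
})

test_that("type-I error estimator is reproducible and respects bounds", {
  sc <- synthetic_scenario(seed = 51)
  r1 <- estimate_type1_error(sc, n_reps = 3, seed = 9)
  r2 <- estimate_type1_error(sc, n_reps = 3, seed = 9)
  expect_equal(attr(r1, "phis"), attr(r2, "phis"))
  expect_true(r1 >= 0 && r1 <= 1)
  single <- estimate_type1_error(sc, n_reps = 1, seed = 9)
  expect_true(as.numeric(single) %in% c(0, 1))
  expect_error(estimate_type1_error(sc, n_reps = 0), "n_reps")
  expect_error(estimate_type1_error(default_hybrid_scenario(), n_reps = 1),
               "zero hybrid")

  # a stricter critical quantile can only lower the rejection rate
  phis <- attr(r1, "phis")
  cfg_strict <- phi_config(null_critical_quantile = 0.99)
  r_strict <- mean(vapply(1:3, function(r) {
    post <- simulate_posteriors(sc, seed = coalhyb:::derive_seed(9, r))
    phi_test(post, cfg_strict, seed = coalhyb:::derive_seed(9, 3 + r))$phi > 0
  }, logical(1)))
  expect_lte(r_strict, mean(phis > 0))
})

test_that("phi test refuses fewer than two loci", {
  post <- make_identical_posteriors(n_loci = 1, seed = 61)
  expect_error(phi_test(post), "at least 2")
})
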
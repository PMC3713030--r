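#' Rank individuals by the effect of their sole removal on phi
#'
#' For each ingroup individual in turn: prune both of its haplotypes from
#' every tree of every locus, rebuild the coalescent nulls (pruned guides are
#' re-smoothed, re-scaled and re-simulated), recompute phi, and sort the
#' individuals by the resulting phi, smallest first (greatest reduction
#' first).  Ties are broken lexicographically on the individual id.
#'
#' @param posteriors Harmonized list of `gene_tree_posterior` objects with
#'   >= 3 individuals.
#' @param config A [phi_config()].
#' @param seed Integer seed; each candidate evaluation uses a derived seed.
#' @return A data frame with columns `individual` and `phi`, sorted
#'   ascending by `phi`; attribute `initial_phi` carries phi with nobody
#'   removed (`NA` reject flag noted when the initial test already fails to
#'   reject).
#' @export
rank_by_single_removal <- function(posteriors, config = phi_config(), seed = 1) {
  inds <- individuals_of(posteriors)
  if (length(inds) < 3) stop("need at least 3 individuals to rank")
  phi0 <- phi_test(posteriors, config, seed = derive_seed(seed, 0),
                   harmonize = FALSE)$phi
  # common random numbers across candidate evaluations: every candidate's
  # nulls are rebuilt from the same stream so ranking differences reflect
  # the removal, not Monte-Carlo noise
  seed_eval <- derive_seed(seed, 1)
  phis <- vapply(seq_along(inds), function(i) {
    pruned <- drop_individuals(posteriors, inds[i])
    phi_test(pruned, config, seed = seed_eval, harmonize = FALSE)$phi
  }, numeric(1))
  out <- data.frame(individual = inds, phi = phis, stringsAsFactors = FALSE)
  out <- out[order(out$phi, out$individual), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "initial_phi") <- phi0
  attr(out, "initial_reject") <- phi0 > 0
  out
}

#' Search for the smallest individual set whose removal yields phi <= 0
#'
#' Greedy sequential removal: individuals are ranked by single removal, the
#' top-ranked one is removed, and (by default) the remainder re-ranked after
#' each removal, until phi <= 0 - at which point lineage sorting alone can no
#' longer be rejected and the removed individuals are the putative hybrids.
#' Until phi <= 0, hybrids remain in the data set.
#'
#' @param posteriors List of `gene_tree_posterior` objects.
#' @param config A [phi_config()].
#' @param seed Integer seed.
#' @param rerank Re-rank remaining individuals after each removal (default
#'   `TRUE`); `FALSE` follows the initial ranking.
#' @param max_removals Safety cap (default: all but 3 individuals).
#' @param n_random Number of random equal-size control sets evaluated after
#'   the search (default 10; 0 to skip).
#' @param harmonize Harmonize leaf sets first.
#' @return An object of class `hybrid_search`: `removed` (the chosen set in
#'   removal order), `trajectory` (phi after each removal), `initial_phi`,
#'   `final_phi`, `resolved` flag, `ranking` (initial single-removal
#'   ranking), and `random_controls` (data frame of control sets and their
#'   phi).
#' @export
hybrid_search <- function(posteriors, config = phi_config(), seed = 1,
                          rerank = TRUE, max_removals = NULL,
                          n_random = 10, harmonize = TRUE) {
  if (harmonize) posteriors <- harmonize_posteriors(posteriors)
  inds <- individuals_of(posteriors)
  if (is.null(max_removals)) max_removals <- length(inds) - 3L
  ranking <- rank_by_single_removal(posteriors, config, seed)
  phi0 <- attr(ranking, "initial_phi")

  removed <- character(0)
  trajectory <- numeric(0)
  resolved <- phi0 <= 0
  current <- posteriors
  rank_now <- ranking
  step <- 0L
  while (!resolved && length(removed) < max_removals) {
    step <- step + 1L
    cand <- rank_now$individual[1]
    removed <- c(removed, cand)
    trajectory <- c(trajectory, rank_now$phi[1])
    if (rank_now$phi[1] <= 0) { resolved <- TRUE; break }
    current <- drop_individuals(current, cand)
    rank_now <- if (rerank) {
      rank_by_single_removal(current, config, derive_seed(seed, 1000 + step))
    } else {
      rank_now[rank_now$individual != cand, , drop = FALSE]
    }
  }
  final_phi <- if (length(trajectory)) trajectory[length(trajectory)] else phi0

  controls <- NULL
  if (n_random > 0 && length(removed) > 0 && length(removed) < length(inds)) {
    controls <- random_set_control(posteriors, config,
                                   set_size = length(removed),
                                   n_sets = n_random,
                                   seed = derive_seed(seed, 999999))
  }
  structure(list(removed = removed, trajectory = trajectory,
                 initial_phi = phi0, final_phi = final_phi,
                 resolved = resolved, ranking = ranking,
                 random_controls = controls, config = config),
            class = "hybrid_search")
}

#' Random equal-size removal control sets
#'
#' Draws `n_sets` distinct uniform random subsets of individuals of the
#' given size, removes each, and recomputes phi - the control showing that
#' the chosen set, not mere data reduction, drives phi below zero.
#'
#' @param posteriors Harmonized list of `gene_tree_posterior` objects.
#' @param config A [phi_config()].
#' @param set_size Size of each random set (< number of individuals).
#' @param n_sets Number of sets (default 10).
#' @param seed Integer seed.
#' @return Data frame with columns `set` (comma-joined individual ids),
#'   `phi`, `reject`.
#' @export
random_set_control <- function(posteriors, config = phi_config(),
                               set_size, n_sets = 10, seed = 1) {
  inds <- individuals_of(posteriors)
  if (set_size >= length(inds))
    stop("set_size must be smaller than the number of individuals")
  set.seed(seed)
  sets <- list()
  guard <- 0L
  while (length(sets) < n_sets && guard < 1000L) {
    guard <- guard + 1L
    s <- sort(sample(inds, set_size))
    key <- paste(s, collapse = ",")
    if (!key %in% names(sets)) sets[[key]] <- s
  }
  phis <- vapply(seq_along(sets), function(k) {
    pruned <- drop_individuals(posteriors, sets[[k]])
    phi_test(pruned, config, seed = derive_seed(seed, k),
             harmonize = FALSE)$phi
  }, numeric(1))
  data.frame(set = names(sets), phi = phis, reject = phis > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.hybrid_search <- function(x, ...) {
  cat("Sequential hybrid-removal search\n")
  cat(sprintf("  initial phi = %.4g (%s)\n", x$initial_phi,
              if (x$initial_phi > 0) "reject" else "fail to reject"))
  if (!length(x$removed)) {
    cat("  nothing removed: lineage sorting alone already not rejected\n")
  } else {
    cat("  removed", length(x$removed), "individual(s):",
        paste(x$removed, collapse = ", "), "\n")
    cat("  phi trajectory:", paste(sprintf("%.3g", x$trajectory),
                                   collapse = " -> "), "\n")
  }
  if (!x$resolved)
    cat("  NOT RESOLVED: phi stayed positive at the removal cap\n")
  if (!is.null(x$random_controls)) {
    cat(sprintf("  random controls: %d/%d sets keep phi > 0\n",
                sum(x$random_controls$reject), nrow(x$random_controls)))
  }
  invisible(x)
}
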
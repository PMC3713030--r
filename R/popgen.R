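#' Mean pairwise p-distance with complete deletion of indels
#'
#' Removes every alignment column containing a gap (`-`) or missing base
#' (`N`/`?`) in any compared sequence, then averages the proportion of
#' differing retained sites over all A x B sequence pairs.
#'
#' @param seqsA,seqsB Aligned sequences: a `DNAbin` matrix/list (see
#'   [ape::read.dna()]/[ape::read.FASTA()]) or a character matrix/vector of
#'   equal-length strings over `A,C,G,T,-,N`.
#' @return The mean pairwise proportion of differing sites.
#' @export
mean_p_distance <- function(seqsA, seqsB) {
  a <- as_char_matrix(seqsA)
  b <- as_char_matrix(seqsB)
  if (ncol(a) != ncol(b)) stop("alignments have different lengths")
  all_rows <- rbind(a, b)
  bad <- apply(all_rows, 2, function(col) any(col %in% c("-", "n", "?", "N")))
  if (all(bad)) stop("no columns retained after complete deletion of indels")
  a <- a[, !bad, drop = FALSE]
  b <- b[, !bad, drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    tot <- tot + mean(a[i, ] != b[j, ])
  tot / (nrow(a) * nrow(b))
}

as_char_matrix <- function(x) {
  if (inherits(x, "DNAbin")) {
    m <- as.character(as.matrix(x))
  } else if (is.character(x)) {
    if (length(unique(nchar(x))) != 1)
      stop("sequences must be aligned to equal length")
    m <- do.call(rbind, strsplit(x, ""))
  } else if (is.matrix(x)) {
    m <- x
  } else stop("unsupported sequence container: ", class(x)[1])
  tolower(m)
}

#' Mutation-rate chain: p-distance to per-year and per-generation rates
#'
#' Under neutral evolution of the non-coding sites, the per-year rate is
#' `mu_year = p / (2 T)` for two lineages that diverged `T` years ago, and
#' the per-generation rate is `mu_gen = mu_year * g` for a generation time
#' of `g` years.
#'
#' @param p Mean p-distance (> 0).
#' @param T_years Divergence time in years (default 5.9e6).
#' @param g_years Generation time in years (default 20).
#' @return List with `mu_per_year` and `mu_per_generation`.
#' @export
mu_chain <- function(p, T_years = 5.9e6, g_years = 20) {
  if (any(c(p, T_years, g_years) <= 0)) stop("all inputs must be positive")
  mu_y <- p / (2 * T_years)
  list(mu_per_year = mu_y, mu_per_generation = mu_y * g_years)
}

#' Effective population size from theta and the per-generation rate
#'
#' `Ne = theta / (4 mu_gen)`, in gene copies.  Credibility bounds on theta,
#' when supplied, are transformed identically.
#'
#' @param theta Population mutation parameter (> 0); optionally a vector
#'   `c(median, lower, upper)`.
#' @param mu_per_generation Per-generation mutation rate (> 0).
#' @return Ne (same shape as `theta`).
#' @export
ne_from_theta <- function(theta, mu_per_generation) {
  if (any(theta <= 0) || mu_per_generation <= 0)
    stop("theta and mu must be positive")
  theta / (4 * mu_per_generation)
}

#' Bundled Citrus effective-population-size inputs
#'
#' The per-locus calibration (mean p-distance between trifoliate orange and
#' sweet orange, tabulated per-year and per-generation rates) and per-group
#' theta medians with 95% bounds for the three informative nuclear loci
#' (HYB, LGT, MDH), together with the published Ne medians used as
#' cross-checks.  Note the HYB per-year rate is internally inconsistent
#' with its p-distance (p/(2T) gives 2.85e-9, not the tabulated 3.31e-9);
#' values are reproduced as tabulated, without correction.
#'
#' @return List of two data frames: `loci` and `theta`.
#' @export
citrus_ne_inputs <- function() {
  path <- system.file("extdata", "citrus_ne_inputs.tsv", package = "coalhyb",
                      mustWork = TRUE)
  lpath <- system.file("extdata", "citrus_locus_rates.tsv", package = "coalhyb",
                       mustWork = TRUE)
  list(loci = utils::read.delim(lpath), theta = utils::read.delim(path))
}

#' Per-locus, per-group Ne table
#'
#' Computes `Ne = theta / (4 mu_gen)` for every (locus, group) cell.  By
#' default the tabulated per-generation rate of each locus is used
#' (`mu = "given"`); `mu = "computed"` instead derives it from the locus
#' p-distance via [mu_chain()].
#'
#' @param theta_tbl Data frame with columns `locus`, `group`, `theta` and
#'   optionally `theta_lower`, `theta_upper`.
#' @param locus_tbl Data frame with columns `locus` and `mu_per_generation`
#'   (for `mu = "given"`) or `p_distance` (for `mu = "computed"`).
#' @param mu Which rate to use.
#' @param T_years,g_years Calibration for `mu = "computed"`.
#' @return The theta table with added columns `mu_per_generation`, `ne` and
#'   (when bounds present) `ne_lower`, `ne_upper`.
#' @export
ne_table <- function(theta_tbl, locus_tbl, mu = c("given", "computed"),
                     T_years = 5.9e6, g_years = 20) {
  mu <- match.arg(mu)
  mug <- if (mu == "given") {
    stats::setNames(locus_tbl$mu_per_generation, locus_tbl$locus)
  } else {
    stats::setNames(vapply(locus_tbl$p_distance, function(p)
      mu_chain(p, T_years, g_years)$mu_per_generation, numeric(1)),
      locus_tbl$locus)
  }
  if (anyNA(mug[theta_tbl$locus])) stop("locus missing from locus_tbl")
  out <- theta_tbl
  out$mu_per_generation <- unname(mug[out$locus])
  out$ne <- out$theta / (4 * out$mu_per_generation)
  if (!is.null(out$theta_lower))
    out$ne_lower <- out$theta_lower / (4 * out$mu_per_generation)
  if (!is.null(out$theta_upper))
    out$ne_upper <- out$theta_upper / (4 * out$mu_per_generation)
  out
}

#' Group means and overall mean of an Ne table
#'
#' The group mean is the arithmetic mean of the per-locus Ne of that group;
#' the overall mean is the mean of the group means.  Display rounding (Ne
#' to the nearest gene copy) is applied to the returned summaries.
#'
#' @param ne_tbl Data frame with columns `group` and a value column.
#' @param value Name of the value column (default `"ne"`).
#' @return List with `group_means` (named, rounded) and `overall_mean`
#'   (rounded mean of the unrounded group means).
#' @export
summarize_ne_table <- function(ne_tbl, value = "ne") {
  if (!value %in% names(ne_tbl)) stop("no column '", value, "' in table")
  v <- ne_tbl[[value]]
  if (anyNA(v)) stop("missing values in '", value, "'")
  grp <- tapply(v, ne_tbl$group, mean)
  if (any(tapply(v, ne_tbl$group, length) < 1)) stop("empty group")
  list(group_means = round(grp),
       overall_mean = round(mean(grp)))
}
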
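---
title: "Separating hybridization from lineage sorting with coalhyb"
author: "coalhyb authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating hybridization from lineage sorting with coalhyb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalhyb)
```

## The problem

Gene trees estimated from different nuclear loci of the same individuals
often disagree. In recently diverged groups two processes dominate the
discordance: **incomplete lineage sorting (ILS)** — ancestral polymorphism
persisting across speciation events so that gene-copy ancestry does not
track the species branching order — and **hybridization**, which places an
individual's alleles in entirely different clades at different loci.
Telling them apart matters: hybrid individuals mislead species-tree
inference, while ILS is accommodated by coalescent methods.

Most model-based approaches simulate the ILS null from an inferred species
tree. When hybrids are present, that species tree is itself suspect, and
the circularity can hide exactly the signal one is looking for. The test
implemented here avoids the species tree altogether: **each observed gene
tree acts as its own guide** ("a surrogate for the unknown species tree")
for coalescent simulation, so the null describes how different trees can
look given the genealogy actually observed at that locus, under lineage
sorting alone.

## The phi test

For each locus $g$ we have a posterior sample of $n$ rooted gene trees
(default $n = 20$). The machinery is:

1. **Chronogram construction.** Each posterior draw is made ultrametric by
   recursive mean-path-length smoothing (each node's age is the mean
   root-to-leaf distance beneath it, child ages clipped at the parent) and
   rescaled so the root depth equals
   $\textrm{root age} / \textrm{generation time}$ generations — by default
   $5.9\,\textrm{Myr} / 20\,\textrm{yr} = 295{,}000$ generations.
2. **Contained coalescent.** Within each chronogram, one gene tree is
   simulated by neutral coalescence: inside a guide branch, $k$ lineages
   coalesce with exponential waiting times at rate $k(k-1)/(2N_e)$ per
   generation ($N_e$ in haploid gene copies, default 8,000); lineage sets
   merge at guide nodes; above the root coalescence continues to a single
   lineage.
3. **Distance pools.** The per-locus *null pool* holds all
   $n \times n$ Robinson–Foulds distances between the $n$ simulated and the
   $n$ posterior trees (400 by default). The per-pair *observed pool*
   holds all $n \times n$ cross-locus distances between two loci's
   posterior draws.
4. **The statistic.** With $C(g)$ the 80% quantile of locus $g$'s null
   pool and $L(i,j)$ the 2.5% quantile (lower bound of the two-sided 95%
   credibility interval) of pair $(i,j)$'s observed pool,
   $$\phi \;=\; \min_{i<j} L(i,j) \;-\; \max_g C(g).$$
   $\phi > 0$ rejects lineage sorting alone. Equivalently, if **any** pair
   of loci's observed distances overlaps **any** locus' null, the null is
   retained — a deliberately conservative aggregation: a hybrid whose
   alleles are concordantly placed in two of three loci cannot trigger a
   rejection.

Quantiles are the linear-interpolation empirical estimator (type 7); with
400-value pools on the even-integer RF lattice this matters mostly for
small pools and is documented here for reproducibility.

After a rejection, `hybrid_search()` removes individuals sequentially:
each individual alone first (both haplotypes at all loci, the removal
granularity of the original design), ranked by the resulting $\phi$; then
greedy accumulation — re-ranking after each removal by default — until
$\phi \le 0$. Nulls are fully rebuilt after every removal (pruned guides
re-smoothed, re-scaled, re-simulated), because pruning changes the guide
trees. All candidate evaluations within a ranking round share one derived
random seed (common random numbers), so ranking differences reflect the
removals rather than Monte-Carlo noise. Ten random equal-size removal
sets provide the control that the *chosen* set, not mere data reduction,
disarms the rejection. Individuals still present when $\phi \le 0$ is
reached are regarded as free of detectable hybrid ancestry.

## Species trees by minimizing deep coalescences

With putative hybrids removed, `mdc_species_tree()` infers the species
tree that minimizes the total number of extra lineages needed to embed
each locus' supported topology (majority-rule consensus with clades below
posterior probability 0.95 collapsed; polytomies are *not* auto-resolved
and are treated as simultaneous multi-way coalescences). For a species
clade $v$ the lineages exiting its stem are the maximal gene-tree clades
whose leaves all map inside $v$; the cost sums (exits $-$ 1) over all
species-tree branches and all loci. Search is exhaustive over rooted
topologies up to seven species, and an NNI hill climb with restarts
beyond.

## Effective population size arithmetic

The $N_e$ module reproduces the calibration chain used to pick the
simulation $N_e$: a neutral p-distance $p$ between lineages that diverged
$T$ years ago gives $\mu_{yr} = p/(2T)$ per site per year,
$\mu_{gen} = \mu_{yr} \times g$ for generation time $g$, and
$N_e = \theta/(4\mu_{gen})$ gene copies from an externally estimated
$\theta$. p-distances use complete deletion: every column with a gap or
missing base in any compared sequence is dropped before averaging over
all between-group sequence pairs.

Two quirks of the bundled Citrus parameter table deserve note. First,
its footnote describes the generation-time correction as $\mu/20$, but
every tabulated corrected rate equals $\mu \times 20$ and the $N_e$
magnitudes require the multiplication; the package implements
$\mu_{gen} = \mu_{yr} \times g$. Second, the HYB locus' tabulated
per-year rate ($3.31\times10^{-9}$) is inconsistent with its own
p-distance ($0.0336/(2 \times 5.9\,\textrm{Ma}) = 2.85\times10^{-9}$),
while LGT and MDH are consistent; `ne_table()` therefore defaults to the
tabulated per-generation rates and exposes the recomputation for
comparison, without silently correcting either value. Tabulated $\theta$
values carry as few as two significant figures, so recomputed $N_e$
medians match the published ones to about 1% table-wide (0.1–0.5% for
well-resolved cells); group means and the overall mean of the published
medians are reproduced exactly (12,005 citron; 4,733 trifoliate; 7,284
overall).

## The synthetic scenario generator

Because the original sequence data require external Bayesian tree
estimation, the package ships a generator that emulates the study
conditions end to end:

* a four-species chronogram `(TRF,(PUM,(CIT,MAN)))` with root depth
  295,000 generations; the internal divergences are placed at 225,000 and
  160,000 generations — a choice made once so that internal branches span
  many multiples of $N_e$ and between-species ILS is rare, the
  "favourable conditions" regime for species-tree recovery;
* $N_e = 8{,}000$ gene copies everywhere, 3 individuals per species with
  2 haplotypes each, 3 unlinked loci (configurable 2+);
* optional **hybridization events**: at the affected loci an individual's
  gene copies re-home into a donor lineage from the transfer time
  backward. Lineages coalescing with the hybrid's alleles more recently
  than the transfer hitchhike along — the footprint of an introgressed
  allele spreading in the recipient population;
* **pseudo-posteriors**: each true gene tree is perturbed into 20 draws
  by lognormal branch-length noise and nearest-neighbour interchanges
  applied to internal edges with probability
  $\textrm{intensity} \times e^{-\ell/\lambda}$
  ($\lambda$ = 5% of tree height), so topological uncertainty
  concentrates on short branches. The default intensity 0.07 was
  calibrated once so that the median within-posterior RF distance on the
  default 24-leaf trees is 2–4, and then frozen.

The default *power scenario* (`default_hybrid_scenario()`) re-homes one
mandarin individual's alleles to trifoliate (across the root) at locus 1
and to pummelo at locus 3, leaving locus 2 at home, shortly before the
present. Every pair of loci then shows incongruent placements — the
allele signature of a complex hybrid. A single-locus displacement is
deliberately not the default: by the test's own conservative aggregation
(any concordant pair retains the null) such a hybrid is undetectable by
construction, so it would measure the aggregation rule, not the power.

What the generator does **not** emulate: sequence-level estimation error
(pseudo-posteriors stand in for Bayesian inference), recombination,
population structure or inbreeding within species (all gene copies of a
species are exchangeable draws), and clonal relatedness among cultivated
accessions. Passing tests therefore certify the simulation, distance and
decision machinery under a clean neutral coalescent — not robustness to
every feature of real sequence data.

## Calibration honesty: when is the test conservative?

The null is anchored to the observed gene tree: a contained re-simulation
can never coalesce two lineages below their guide MRCA, so simulated
trees are "delayed copies" of their guide. When within-species branch
durations are informative (comparable to $N_e$, as an honest generator at
the true $N_e$ produces), re-simulations resemble their guide more than
two independent gene-tree realizations resemble each other, the null
pools sit below the observed pools, and the 80%-versus-2.5% quantile rule
rejects far more than 5% of pure-ILS datasets — about 50% under this
package's default conditions (the contained simulator itself was verified
against msprime on identical guides). In regimes where distances saturate
(many weakly resolved tips) or collapse to zero (few taxa, long
branches), the same rule is conservative. The claimed sub-5% type-I
calibration is therefore regime-dependent, and the acceptance suite
reports the honestly measured rate rather than asserting the claim. For
the same reason the single-removal ranking discriminates hybrids from
non-hybrids only moderately at this signal-to-noise: removing almost any
individual shrinks distance pools, so the greedy search sometimes
terminates before reaching an injected hybrid.

## Numerical and design choices

* **Distance metric.** The original description never names its tree
  distance; unrooted RF symmetric difference is the default (the era's
  standard), with normalized RF and branch-score selectable for
  sensitivity analysis. Distances are computed after outgroup pruning so
  rooting noise cannot inflate them asymmetrically.
* **Haplotype matching across loci.** Suffixes A/B are arbitrary per
  locus; the default matches them literally (deterministic), and a
  seeded "collapse" policy keeping one haplotype per individual per locus
  is available.
* **Zero-length branches** are retained; ultrametric smoothing clips
  child ages at parents rather than allowing negative durations, and tied
  node ages are processed deepest-first in the simulator so zero-length
  chains still funnel lineages rootward.
* **Above-root coalescence** continues at the same $N_e$ (the guide tool's
  exact behaviour above the root is undocumented; this is the natural
  assumption).
* **Seeds.** Every stochastic entry point takes one seed; internal
  streams derive from it by a fixed integer recurrence, so results are
  bit-reproducible including the scenario manifests.
* **Problem sizes.** The shipped checks use 200 pure-ILS replicates for
  the type-I rate, 100/50 replicates for power and removal recovery,
  20,000 draws for the closed-form coalescent checks, and exhaustive
  enumeration (all 5-leaf topology pairs; all 4-species MDC cases) for
  the kernel oracles — sizes chosen to give stable Monte-Carlo estimates
  at desk scale.

## Limitations

Beyond the calibration caveat above: the test cannot detect hybrids whose
alleles are concordantly placed across all loci; removal granularity is
the individual, so allele-level mosaics are not resolved; the MDC
criterion ignores branch lengths; and no attempt is made to assign
parental lineages to detected hybrids — that remains an interpretive step
on the gene trees themselves.
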
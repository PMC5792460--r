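---
title: "Evaluating multi-locus DNA barcode libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-locus DNA barcode libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

## The problem

Forensic identification of traded timber needs a reference library of short,
recoverable DNA regions (barcodes) together with an honest assessment of how
well those regions separate the species of interest. For closely related
hardwood species the question is rarely "does a barcode work" but "which
locus, or which combination of loci, separates which species, at what
confidence, and from how little sequence". `barcodeval` implements the
standard evaluation battery used in such studies — distance summaries,
barcoding-gap assessment, nearest-neighbour identification, tree-based
monophyly scoring, exhaustive combination ranking and diagnostic-character
discovery — on any library of pre-aligned per-locus FASTA files plus a
specimen metadata table, and ships a calibrated simulator so that every stage
can be exercised and tested without sequence downloads.

## Distances

All distance-based stages work from pairwise distances computed under
*pairwise deletion*: for each sequence pair, every alignment column in which
either sequence carries a gap (`-`), a missing symbol (`N`, `?`) or an IUPAC
ambiguity code is dropped, and only unambiguous A/C/G/T columns are compared.
Dropping ambiguity codes as well as gaps is a deliberately conservative
choice; it makes every comparison deterministic at the cost of a few sites.

Two models are available. The p-distance is the raw proportion of differing
compared sites. The Kimura 2-parameter (K2P) distance corrects for multiple
hits while distinguishing transitions (A–G, C–T) from transversions:

$$ d = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\,\big], $$

with \(P\) and \(Q\) the transition and transversion proportions among
compared sites. The estimator is undefined when the logarithm's argument
leaves its domain (saturation) or when fewer than `min_overlap` sites
(default 20) survive pairwise deletion. Undefined distances are *flagged and
excluded* from all summaries and matching rather than silently propagated;
the per-pair minimum overlap of 20 sites guards the short mini-barcode
(~170 bp) against near-empty comparisons when missing data are heavy. K2P is
used for matching and gap analysis and the p-distance for neighbour-joining
trees, mirroring common practice; both pairings are configurable.

## Barcoding gap

Pairwise distances are split into intraspecific and interspecific classes.
The gap report gives the fraction of interspecific distances *strictly*
greater than the cutoff (default 0.05 substitutions/site) and of
intraspecific distances *strictly* below it, plus an overlap flag
(`max intra >= min inter`) and a shared-bin histogram. Strict inequalities
mean a distance exactly at the cutoff counts on neither side.

## Identification

`best_match()` assigns each query the species of its nearest neighbour(s).
Ties (within `tie_tolerance`, default 0 — exact ties only, for determinism)
across species make a query *ambiguous*. `best_close_match()` additionally
rejects queries whose nearest neighbour is farther than a threshold; the
threshold is the 95th percentile (linear interpolation) of all intraspecific
distances, the established convention for this method, with the percentile
configurable. A query whose species has no second sequence is a *singleton*:
it can never be matched correctly, so singletons are reported separately and
excluded from the success denominator — including them would deterministically
deflate every rate by the same amount. The success rate is
correct / (correct + ambiguous + incorrect + no match) × 100; the full
category breakdown is always returned so alternative conventions can be
recomputed from the output.

## Trees and the discrimination criterion

Unrooted neighbour-joining trees are built (via `ape`) from complete distance
matrices; undefined entries must be resolved first, and the pipeline does so
by iteratively pruning the specimen with the most undefined pairs. Negative
branch lengths are retained as computed (preserving additivity) and clamped
to zero only optionally in Newick output.

A species (or region) is *discriminated* when (i) some edge of the unrooted
tree separates exactly its specimens from all others and (ii) that cluster
contains at least one vouchered specimen — the voucher clause reflects that a
cluster anchored only by unverified material identifies nothing. Labels with
a single specimen are excluded from the overall rate. Bootstrap support is
computed by resampling alignment columns with replacement and counting, per
internal edge, the replicates containing the same bipartition; a zero-length
replicate edge is treated as unresolved and supports nothing, so an
alignment without signal reports support 0 everywhere. By default support
does not gate discrimination (`min_support = 0`); a gate can be switched on.

## Combinations

All \(2^k - 1\) non-empty locus subsets are evaluated. Concatenation is
complete-case by default — a specimen must be sequenced at every locus of the
combination — because distance methods react badly to large missing blocks;
an `N`-padding mode is available behind a flag (padded stretches vanish
under pairwise deletion anyway). Each combination gets the full battery
(summary, gap, both matching methods with its own derived threshold, NJ
discrimination) and the table is ranked by best-close-match success.

## Diagnostic blocks

For a species pair, a column is diagnostic when each species is fixed for a
different state, with the gap counting as a fifth state — this is what lets a
species-fixed deletion (e.g. a six-column block) surface as a contiguous
*indel* block, the basis of a degraded-DNA mini-barcode assay. Missing and
ambiguous symbols disqualify a column by default (`allow_missing = FALSE`);
the lenient mode ignores those members instead. Runs of consecutive
diagnostic columns are merged into blocks; coordinates are 1-based inclusive
alignment columns, and because published coordinates are sometimes given on
an ungapped sequence, each block also reports its start in each species' own
ungapped coordinates (counted on one reference sequence per species).

## The simulator

The generator exists so that every downstream stage has a library whose truth
is known. Sequences evolve under a two-parameter (transition/transversion,
\(\kappa\) default 2) substitution process — the same family the K2P
estimator assumes, so parameter-recovery tests are meaningful — along a
random species topology whose terminal edges are `inter_depth/2` with short
internal edges (`inter_depth/50`). This geometry makes every between-species
path close to the configured `inter_depth` (recovered within ±10% at
5000 sites) while keeping a guaranteed minimum species separation; a
mean-rescaled random-length tree cannot guarantee both. Specimens hang off
their species as a star of `intra_depth/2` branches, the species terminal
edge being shortened to compensate. Per-locus dropout is an exact rounded
count of recovered specimens, not a per-specimen coin flip, so recovery
rates are exactly reproducible in tests. Diagnostic indels are species-fixed
deletion blocks placed uniformly at random with per-species probability
`indel_rate`. Each locus gets an independent genealogy by default; a
`linked` flag shares one topology across loci (plastid-style inheritance).

`demo_library_config()` encodes a realistic six-species, 39-specimen,
four-locus hardwood study: aligned lengths 234/239/173/350 bp, per-locus
recovery 26/39–35/39, within-species divergence 0.0026–0.020 and
between-species 0.0073–0.080 substitutions/site, GC 27–66%, and 6–8 bp indel
blocks on the two non-coding loci only. These values are the generator's
fixed study conditions, not tuning knobs.

What the simulator does *not* emulate: rate heterogeneity across sites,
alignment error (its alignments are gap-free except for planted indels),
recombination, coalescent variance within species, and base-composition
biases beyond a single GC parameter. Passing tests on simulated libraries
therefore demonstrate the correctness of the computations and the behaviour
of the methods under idealized divergence structure — not that any particular
real marker will discriminate a given genus.

## Numerical choices and degenerate inputs

* Percentiles use linear interpolation (R's default type 7 quantile).
* Gap-report fractions use strict inequalities at the cutoff.
* Distance matrices with undefined entries are refused by tree building;
  the pruning order (most undefined pairs first, ties by first id) is
  deterministic.
* An all-identical alignment yields a zero distance matrix, an arbitrary but
  deterministic NJ resolution, and bootstrap supports of 0.
* All randomness flows from a single integer seed; per-locus and per-stage
  seeds are derived by fixed offsets so stages are individually
  reproducible.
* Test and example problem sizes (alignments of 100–5000 columns, libraries
  of 6–40 specimens, 50–100 replicate trees) were chosen as the smallest
  sizes at which the statistical checks are stable.

## Worked example

```{r example, eval = FALSE}
lib <- simulate_library(demo_library_config(seed = 1))
profile_library(lib)

dm <- distance_matrix(lib$loci$ITS2, model = "K2P")
summ <- summarize_pairwise(dm, lib$specimens)
glance(barcoding_gap(summ, cutoff = 0.05))
success_rate(best_close_match(dm, lib$specimens))

ranking <- evaluate_combinations(lib)
head(ranking)
autoplot(ranking)
```

The same battery runs end-to-end with `run_pipeline()`, which writes every
table (profiles, summaries, gap histograms, per-query outcomes, Newick
trees, combination ranking, diagnostic blocks, region clustering) plus a run
log into one directory, byte-identically on rerun with the same seed.

## Limitations

Only K2P and p-distances are implemented (no GTR/HKY estimation or model
selection); trees are NJ only (no likelihood or Bayesian inference); the
package consumes pre-aligned FASTA and never aligns; and the discrimination
criterion treats the tree as unrooted, so paraphyly with respect to a rooted
outgroup is not distinguishable from monophyly across the corresponding
edge.
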
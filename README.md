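# barcodeval

Evaluation of multi-locus DNA barcode reference libraries, written for the
situation faced in forensic timber identification: a set of candidate
barcode loci (e.g. ITS2, *matK*, *ndhF-rpl32*, *rbcL*) has been sequenced —
often with heavy locus-specific dropout, since wood is a DNA-poor tissue —
from a modest number of vouchered specimens of closely related species, and
one needs to know which locus or locus combination actually separates the
species, and whether a short "mini-barcode" carries a diagnostic character
for a critical species pair.

The package implements the standard evaluation battery on any library of
pre-aligned per-locus FASTA files plus a specimen metadata table:

* **Locus profiles** — recovery rate, aligned/ungapped length, GC, variable
  and parsimony-informative sites, gap-bearing columns.
* **Distances** — Kimura 2-parameter
  `d = -1/2 ln[(1-2P-Q) sqrt(1-2Q)]` and p-distance, under pairwise
  deletion (gaps, `N`, `?` and IUPAC ambiguity codes excluded per pair),
  with saturated or low-overlap pairs flagged undefined rather than
  propagated.
* **Barcoding gap** — fractions of interspecific distances strictly above
  and intraspecific strictly below a cutoff (default 0.05), overlap flag,
  histograms.
* **Identification** — TaxonDNA-style *best match* and *best close match*
  (threshold = 95th percentile of intraspecific distances), with
  correct/ambiguous/incorrect/no-match/singleton accounting.
* **Trees** — unrooted neighbour-joining (p-distance), column-resampling
  bootstrap, and a voucher-aware discrimination criterion: a species counts
  as discriminated only if some edge separates exactly its specimens and
  the cluster contains a vouchered specimen.
* **Combinations** — every non-empty locus subset (complete-case
  concatenation), ranked by best-close-match success.
* **Diagnostics** — species-pair diagnostic columns with the gap as a fifth
  state, merged into substitution/indel blocks for mini-barcode design.
* **Simulator** — a seed-deterministic multi-locus library generator
  (two-parameter substitution process on a species tree, exact-count
  dropout, species-fixed indel blocks) so the whole pipeline is testable
  offline; `demo_library_config()` encodes a realistic 6-species,
  39-specimen, 4-locus hardwood study.

## Worked example

```r
library(barcodeval)

lib <- simulate_library(demo_library_config(seed = 1))
profile_library(lib)
#>   locus      n_seqs recovery_rate aligned_length gc_ratio n_variable n_informative indel_columns
#> 1 ITS2           26          66.7            234     63.6         84            43             0
#> 2 matK           32          82.1            239     39.3         16             8             0
#> 3 ndhF-rpl32     35          89.7            173     29.4         16             1            12
#> 4 rbcL           27          69.2            350     42.3         37             2             0
```

Each row is one locus: 26 of 39 specimens yielded an ITS2 sequence (66.7%
recovery), its 234-column alignment has 84 variable and 43
parsimony-informative sites, and only the *ndhF-rpl32*-like mini-barcode
carries gap columns (its simulated species-fixed deletions).

```r
dm <- distance_matrix(lib$loci$ITS2, model = "K2P")
glance(barcoding_gap(summarize_pairwise(dm, lib$specimens), cutoff = 0.05))
#>   locus cutoff frac_inter_above frac_intra_below overlap
#> 1 ITS2    0.05              100              100 FALSE

success_rate(best_close_match(dm, lib$specimens))
#>   n_queries n_singleton n_correct n_ambiguous n_incorrect n_no_match success_pct
#> 1        26           1        25           0           0          0         100
```

For this library ITS2 shows a clean barcoding gap (every interspecific
distance above 0.05, every intraspecific below, no overlap) and best close
match identifies all 25 non-singleton queries correctly; the one specimen
whose species has no second ITS2 sequence is reported as a singleton and
excluded from the denominator.

```r
ranking <- evaluate_combinations(lib)
head(as_tibble(ranking)[, c("loci", "n_specimens", "bm_success", "bcm_success", "nj_discrimination")], 3)
#>   loci            n_specimens bm_success bcm_success nj_discrimination
#> 1 ITS2                     26        100         100               100
#> 2 ITS2+matK                22        100         100               100
#> 3 ITS2+ndhF-rpl32          25        100         100               100
```

All 15 subsets of the four loci are evaluated; `n_specimens` is the
complete-case count (a specimen must be sequenced at every locus of a
combination), and the table is ranked by best-close-match success.
`autoplot(ranking)`, `autoplot(gap_report)` and `tidy()`/`glance()` methods
give ggplot2 figures and tidy tables for every result type, and
`run_pipeline(pipeline_config(...))` writes the full report bundle
(profiles, summaries, histograms, per-query outcomes, Newick trees,
ranking, diagnostic blocks, region clustering, run log) to a directory,
byte-identically on rerun with the same seed.

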
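# Per-locus alignment characteristics: recovery, length, GC, variable and
# parsimony-informative sites, gap-bearing columns.

#' Profile one locus
#'
#' A variable site is a column with at least two distinct unambiguous
#' nucleotide states (gaps and missing/ambiguous characters carry no
#' state); a parsimony-informative site additionally has at least two
#' states each present in at least two sequences. The GC ratio pools all
#' unambiguous ungapped characters across sequences. Recovery is the
#' percentage of specimens with a sequence at the locus.
#'
#' @param locus An [aligned_locus()] with >= 2 rows.
#' @param specimens Specimen tibble for the library the locus belongs to.
#' @return A one-row tibble: `locus`, `n_seqs`, `recovery_rate`,
#'   `ungapped_min`, `ungapped_max`, `aligned_length`, `gc_ratio`,
#'   `n_variable`, `pct_variable`, `n_informative`, `pct_informative`,
#'   `indel_columns`.
#' @export
profile_locus <- function(locus, specimens) {
  if (locus$n < 2) abort("need at least 2 sequences", class = "insufficient_data")
  m <- locus_matrix(locus)
  ungapped <- rowSums(m != "-")
  base_counts <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    as.numeric(table(factor(col[col %in% BASES], levels = BASES)))
  }, numeric(4))
  rownames(base_counts) <- BASES
  n_states <- colSums(base_counts > 0)
  variable <- n_states >= 2
  informative <- colSums(base_counts >= 2) >= 2
  gc_num <- sum(base_counts[c("G", "C"), ])
  gc_den <- sum(base_counts)
  name <- locus$name
  n_seqs <- locus$n
  len <- locus$length
  tibble(
    locus = name,
    n_seqs = n_seqs,
    recovery_rate = 100 * n_seqs / nrow(specimens),
    ungapped_min = as.integer(min(ungapped)),
    ungapped_max = as.integer(max(ungapped)),
    aligned_length = len,
    gc_ratio = 100 * gc_num / gc_den,
    n_variable = as.integer(sum(variable)),
    pct_variable = 100 * sum(variable) / len,
    n_informative = as.integer(sum(informative)),
    pct_informative = 100 * sum(informative) / len,
    indel_columns = as.integer(sum(colSums(m == "-") > 0))
  )
}

#' Profile every locus in a library
#'
#' @param library A [barcode_library()].
#' @return A tibble with one [profile_locus()] row per locus.
#' @export
profile_library <- function(library) {
  dplyr::bind_rows(lapply(library$loci, profile_locus, specimens = library$specimens))
}
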
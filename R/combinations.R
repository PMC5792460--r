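# Concatenated multi-locus barcodes and exhaustive evaluation of all
# non-empty locus subsets with both identification methods and the
# tree-based discrimination criterion.

#' Concatenate loci into a supermatrix
#'
#' Complete-case by default: only specimens sequenced at every requested
#' locus are retained, and their sequences are joined in the listed locus
#' order. With `pad = TRUE`, specimens missing a locus are kept and the
#' missing stretch filled with `N` (treated as missing under pairwise
#' deletion).
#'
#' @param library A [barcode_library()].
#' @param subset Character vector of locus names, in concatenation order.
#' @param pad Pad missing loci with `N` instead of dropping specimens.
#' @return An [aligned_locus()] named by joining the subset with `+`.
#' @export
concatenate_loci <- function(library, subset, pad = FALSE) {
  if (length(subset) == 0) abort("empty locus subset", class = "invalid_argument")
  missing_loci <- setdiff(subset, names(library$loci))
  if (length(missing_loci) > 0) {
    abort(paste0("unknown locus: ", paste(missing_loci, collapse = ", ")),
      class = "key_error"
    )
  }
  loci <- library$loci[subset]
  ids <- if (pad) {
    Reduce(union, lapply(loci, function(l) names(l$seqs)))
  } else {
    Reduce(intersect, lapply(loci, function(l) names(l$seqs)))
  }
  # keep metadata order
  ids <- library$specimens$specimen_id[library$specimens$specimen_id %in% ids]
  if (length(ids) == 0) {
    abort("no specimen has all requested loci", class = "insufficient_data")
  }
  parts <- lapply(loci, function(l) {
    s <- l$seqs[ids]
    s[is.na(s)] <- strrep("N", l$length)
    unname(s)
  })
  seqs <- setNames(do.call(paste0, parts), ids)
  aligned_locus(seqs, paste(subset, collapse = "+"))
}

all_subsets <- function(loci) {
  unlist(
    lapply(seq_along(loci), function(k) combn(loci, k, simplify = FALSE)),
    recursive = FALSE
  )
}

evaluate_one_combination <- function(library, subset, model_matching, model_tree,
                                     cutoff, percentile, tie_tolerance,
                                     min_overlap, min_support, bootstrap_reps,
                                     seed, pad) {
  locus <- concatenate_loci(library, subset, pad = pad)
  dm <- distance_matrix(locus, model = model_matching, min_overlap = min_overlap)
  summary <- suppressWarnings(summarize_pairwise(dm, library$specimens))
  gs <- glance(summary)
  gap <- tryCatch(barcoding_gap(summary, cutoff = cutoff), error = function(e) NULL)
  threshold <- tryCatch(
    intraspecific_threshold(summary, percentile),
    error = function(e) NA_real_
  )
  bm <- suppressWarnings(best_match(dm, library$specimens, tie_tolerance))
  bm_rate <- tryCatch(success_rate(bm)$success_pct, error = function(e) NA_real_)
  bcm <- if (is.na(threshold)) {
    NULL
  } else {
    suppressWarnings(
      best_close_match(dm, library$specimens,
        threshold = threshold,
        tie_tolerance = tie_tolerance
      )
    )
  }
  bcm_rate <- if (is.null(bcm)) {
    NA_real_
  } else {
    tryCatch(success_rate(bcm)$success_pct, error = function(e) NA_real_)
  }
  dm_tree <- distance_matrix(locus, model = model_tree, min_overlap = min_overlap)
  dm_tree <- suppressMessages(prune_undefined(dm_tree))
  tree <- NULL
  disc <- NULL
  nj_rate <- NA_real_
  if (length(dm_tree$ids) >= 3) {
    if (bootstrap_reps > 0) {
      sub_locus <- aligned_locus(locus$seqs[dm_tree$ids], locus$name)
      tree <- suppressMessages(bootstrap_support(
        sub_locus,
        model = model_tree, n_reps = bootstrap_reps,
        seed = seed, min_overlap = min_overlap
      ))
    } else {
      tree <- neighbor_joining(dm_tree)
    }
    disc <- label_clusters(tree, library$specimens,
      label_field = "species",
      min_support = min_support
    )
    nj_rate <- disc$overall_rate
  }
  list(
    row = tibble(
      loci = locus$name,
      k = length(subset),
      n_specimens = locus$n,
      n_tree = length(dm_tree$ids),
      intra_mean = gs$intra_mean,
      inter_mean = gs$inter_mean,
      frac_inter_above = if (is.null(gap)) NA_real_ else gap$frac_inter_above,
      frac_intra_below = if (is.null(gap)) NA_real_ else gap$frac_intra_below,
      threshold = threshold,
      bm_success = bm_rate,
      bcm_success = bcm_rate,
      nj_discrimination = nj_rate,
      note = NA_character_
    ),
    detail = list(
      summary = summary, gap = gap, best_match = bm, best_close_match = bcm,
      tree = tree, discrimination = disc
    )
  )
}

#' Evaluate every locus combination
#'
#' Runs the full single-locus pipeline — K2P pairwise summary, barcoding
#' gap, best match, best close match (threshold derived per combination)
#' and p-distance NJ discrimination — on all `2^k - 1` non-empty locus
#' subsets, and ranks them by best-close-match success. Failures in one
#' combination are recorded in its `note`, not fatal.
#'
#' @param library A [barcode_library()].
#' @param model_matching Distance model for matching and gap analysis.
#' @param model_tree Distance model for NJ trees.
#' @param cutoff Barcoding-gap cutoff.
#' @param percentile Best-close-match threshold percentile.
#' @param tie_tolerance Tie tolerance for nearest-neighbour matching.
#' @param min_overlap Minimum compared sites per pair.
#' @param min_support Support gate for tree discrimination.
#' @param bootstrap_reps Bootstrap replicates for tree support (0 = none).
#' @param seed Seed for bootstrap resampling.
#' @param pad Use `N`-padded instead of complete-case concatenation.
#' @return A `combination_ranking` tibble (one row per subset, ranked);
#'   per-combination artifacts are in the `"details"` attribute, keyed by
#'   the `loci` label.
#' @export
evaluate_combinations <- function(library, model_matching = "K2P",
                                  model_tree = "p", cutoff = 0.05,
                                  percentile = 95, tie_tolerance = 0,
                                  min_overlap = 20, min_support = 0,
                                  bootstrap_reps = 0, seed = 1, pad = FALSE) {
  if (length(library$loci) < 1) abort("library has no loci", class = "invalid_argument")
  subsets <- all_subsets(names(library$loci))
  rows <- vector("list", length(subsets))
  details <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    res <- tryCatch(
      evaluate_one_combination(
        library, subsets[[i]], model_matching, model_tree, cutoff,
        percentile, tie_tolerance, min_overlap, min_support,
        bootstrap_reps, seed + i, pad
      ),
      error = function(e) {
        list(
          row = tibble(
            loci = paste(subsets[[i]], collapse = "+"),
            k = length(subsets[[i]]),
            n_specimens = NA_integer_, n_tree = NA_integer_,
            intra_mean = NA_real_, inter_mean = NA_real_,
            frac_inter_above = NA_real_, frac_intra_below = NA_real_,
            threshold = NA_real_, bm_success = NA_real_,
            bcm_success = NA_real_, nj_discrimination = NA_real_,
            note = conditionMessage(e)
          ),
          detail = NULL
        )
      }
    )
    rows[[i]] <- res$row
    details[[i]] <- res$detail
  }
  out <- dplyr::bind_rows(rows)
  names(details) <- out$loci
  ord <- order(-ifelse(is.na(out$bcm_success), -1, out$bcm_success),
    -ifelse(is.na(out$nj_discrimination), -1, out$nj_discrimination),
    -ifelse(is.na(out$bm_success), -1, out$bm_success),
    out$k
  )
  out <- out[ord, ]
  attr(out, "details") <- details
  class(out) <- c("combination_ranking", class(out))
  out
}
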
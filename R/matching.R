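# Nearest-neighbour species identification in the TaxonDNA style:
# "best match" assigns each query the species of its closest neighbour(s);
# "best close match" additionally rejects queries whose nearest neighbour
# lies beyond a library-wide intraspecific distance threshold.

#' Best-match identification
#'
#' For every sequence in the matrix, finds the minimum distance to any other
#' sequence. If all nearest neighbours (within `tie_tolerance` of the
#' minimum) are conspecific the query is `correct`; a mix of species is
#' `ambiguous`; all heterospecific is `incorrect`. A query whose species has
#' no other sequence at the locus is a `singleton` (it can never be matched
#' correctly). Queries with no defined distance at all are dropped with a
#' warning.
#'
#' @param dm A [distance_matrix()] result.
#' @param specimens Specimen tibble supplying species labels.
#' @param tie_tolerance Distances within this of the minimum count as ties.
#' @return A tibble: `query_id`, `species`, `category`, `nearest_ids`
#'   (comma-separated), `nearest_distance`.
#' @export
best_match <- function(dm, specimens, tie_tolerance = 0) {
  ids <- dm$ids
  if (length(ids) < 2) abort("need at least 2 sequences", class = "insufficient_data")
  sp <- species_of(ids, specimens)
  rows <- lapply(seq_along(ids), function(i) {
    d <- dm$d[i, -i]
    others <- ids[-i]
    osp <- sp[-i]
    singleton <- !any(osp == sp[i])
    if (all(is.na(d))) {
      return(tibble(
        query_id = ids[i], species = sp[i],
        category = if (singleton) "singleton" else NA_character_,
        nearest_ids = NA_character_, nearest_distance = NA_real_
      ))
    }
    dmin <- min(d, na.rm = TRUE)
    hit <- which(!is.na(d) & d <= dmin + tie_tolerance)
    category <- if (singleton) {
      "singleton"
    } else if (all(osp[hit] == sp[i])) {
      "correct"
    } else if (any(osp[hit] == sp[i])) {
      "ambiguous"
    } else {
      "incorrect"
    }
    tibble(
      query_id = ids[i], species = sp[i], category = category,
      nearest_ids = paste(others[hit], collapse = ","),
      nearest_distance = dmin
    )
  })
  out <- dplyr::bind_rows(rows)
  dropped <- out$query_id[is.na(out$category)]
  if (length(dropped) > 0) {
    warn(paste0(
      "queries with no defined distance excluded: ",
      paste(dropped, collapse = ", ")
    ))
    out <- out[!is.na(out$category), ]
  }
  out
}

#' Library-wide intraspecific distance threshold
#'
#' The given percentile (linear interpolation) of all defined intraspecific
#' pairwise distances; the standard best-close-match threshold uses the 95th.
#'
#' @param summary A [summarize_pairwise()] result.
#' @param percentile Percentile in (0, 100].
#' @return A distance (substitutions/site).
#' @export
intraspecific_threshold <- function(summary, percentile = 95) {
  stopifnot(percentile > 0, percentile <= 100)
  intra <- class_distances(summary, "intra")
  if (length(intra) == 0) {
    abort("no defined intraspecific distances", class = "insufficient_data")
  }
  unname(quantile(intra, percentile / 100, type = 7))
}

#' Best-close-match identification
#'
#' Identical to [best_match()] except that any non-singleton query whose
#' nearest distance exceeds the threshold becomes `no_match`. If `threshold`
#' is `NULL` it is computed as the `percentile`-th percentile of the
#' library's intraspecific distances.
#'
#' @inheritParams best_match
#' @param threshold Rejection distance; `NULL` to derive it from the data.
#' @param percentile Percentile used when deriving the threshold.
#' @return As [best_match()], plus a `threshold` attribute.
#' @export
best_close_match <- function(dm, specimens, threshold = NULL, percentile = 95,
                             tie_tolerance = 0) {
  if (is.null(threshold)) {
    threshold <- intraspecific_threshold(
      summarize_pairwise(dm, specimens), percentile
    )
  }
  out <- best_match(dm, specimens, tie_tolerance = tie_tolerance)
  demote <- out$category != "singleton" & out$nearest_distance > threshold
  out$category[demote] <- "no_match"
  attr(out, "threshold") <- threshold
  out
}

#' Identification success rates by category
#'
#' Success is the percentage of correct outcomes among all non-singleton
#' outcomes (correct, ambiguous, incorrect and no_match); singletons are
#' reported separately.
#'
#' @param outcomes Outcome tibble from [best_match()] or [best_close_match()].
#' @return A one-row tibble with counts per category and `success_pct`.
#' @export
success_rate <- function(outcomes) {
  counts <- table(factor(
    outcomes$category,
    levels = c("correct", "ambiguous", "incorrect", "no_match", "singleton")
  ))
  denom <- sum(counts[c("correct", "ambiguous", "incorrect", "no_match")])
  if (denom == 0) {
    abort("all outcomes are singletons", class = "insufficient_data")
  }
  tibble(
    n_queries = nrow(outcomes),
    n_singleton = as.integer(counts[["singleton"]]),
    n_correct = as.integer(counts[["correct"]]),
    n_ambiguous = as.integer(counts[["ambiguous"]]),
    n_incorrect = as.integer(counts[["incorrect"]]),
    n_no_match = as.integer(counts[["no_match"]]),
    success_pct = 100 * counts[["correct"]] / denom
  )
}
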
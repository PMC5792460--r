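# Pairwise K2P and p-distances under pairwise deletion, per-class summaries
# and barcoding-gap assessment.
#
# Pairwise deletion here drops, per pair, every column where either sequence
# carries a gap, 'N', '?' or an IUPAC ambiguity code; only unambiguous
# A/C/G/T columns are compared.

# Encode an alignment character matrix as integers A=1 C=2 G=3 T=4, NA else.
encode_bases <- function(m) {
  e <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_along(BASES)) e[m == BASES[i]] <- i
  e
}

#' Count site patterns between two aligned sequences
#'
#' Classifies each retained column of a sequence pair as identical,
#' transition (A<->G, C<->T) or transversion, after pairwise deletion of
#' columns with gaps, missing or ambiguous characters in either sequence.
#'
#' @param a,b Aligned sequences of equal length (character scalars).
#' @return A list with `n_compared`, `n_transition`, `n_transversion`.
#' @examples
#' site_pattern_counts("AAAA", "GACA") # 4 compared, 1 ts, 1 tv
#' @export
site_pattern_counts <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("sequences have unequal lengths", class = "alignment_error")
  }
  ea <- encode_bases(matrix(strsplit(toupper(a), "")[[1]], 1))[1, ]
  eb <- encode_bases(matrix(strsplit(toupper(b), "")[[1]], 1))[1, ]
  ok <- !is.na(ea) & !is.na(eb)
  ea <- ea[ok]
  eb <- eb[ok]
  diff <- ea != eb
  s <- ea[diff] + eb[diff]
  # among unequal base pairs, code sums 4 (A+G) and 6 (C+T) are transitions
  ts <- sum(s == 4L | s == 6L)
  list(
    n_compared = sum(ok),
    n_transition = ts,
    n_transversion = sum(diff) - ts
  )
}

#' Evolutionary distance from site-pattern counts
#'
#' K2P: `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with transition and
#' transversion proportions `P` and `Q`; p-distance: proportion of differing
#' compared sites. Returns `NA` (an undefined distance) when the K2P
#' logarithm is out of domain or fewer than `min_overlap` sites were
#' compared.
#'
#' @param counts Result of [site_pattern_counts()].
#' @param model `"K2P"` or `"p"`.
#' @param min_overlap Minimum compared sites for a defined distance.
#' @return A single distance (substitutions/site) or `NA`.
#' @export
pairwise_distance <- function(counts, model = c("K2P", "p"), min_overlap = 20) {
  model <- match.arg(model)
  n <- counts$n_compared
  if (n < min_overlap) {
    return(NA_real_)
  }
  P <- counts$n_transition / n
  Q <- counts$n_transversion / n
  if (model == "p") {
    return(P + Q)
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(NA_real_)
  }
  -0.5 * log(w1 * sqrt(w2))
}

# Distance matrix from an encoded alignment. Vectorised over columns per pair.
dist_from_encoded <- function(enc, model, min_overlap) {
  n <- nrow(enc)
  d <- matrix(NA_real_, n, n, dimnames = list(rownames(enc), rownames(enc)))
  diag(d) <- 0
  for (i in seq_len(n - 1)) {
    ea <- enc[i, ]
    for (j in (i + 1):n) {
      eb <- enc[j, ]
      ok <- !is.na(ea) & !is.na(eb)
      nc <- sum(ok)
      if (nc < min_overlap) next
      a <- ea[ok]
      b <- eb[ok]
      diff <- a != b
      s <- a[diff] + b[diff]
      ts <- sum(s == 4L | s == 6L)
      tv <- sum(diff) - ts
      if (model == "p") {
        d[i, j] <- d[j, i] <- (ts + tv) / nc
      } else {
        w1 <- 1 - 2 * ts / nc - tv / nc
        w2 <- 1 - 2 * tv / nc
        if (w1 > 0 && w2 > 0) {
          d[i, j] <- d[j, i] <- -0.5 * log(w1 * sqrt(w2))
        }
      }
    }
  }
  d
}

#' Pairwise distance matrix for a locus
#'
#' @param locus An [aligned_locus()] with at least 2 rows.
#' @param model `"K2P"` or `"p"`.
#' @param min_overlap Minimum compared sites per pair; pairs below it are
#'   recorded as undefined (`NA`).
#' @return A `dist_matrix` object: specimen ids, model, and a symmetric
#'   matrix with zero diagonal and `NA` for undefined pairs.
#' @export
distance_matrix <- function(locus, model = c("K2P", "p"), min_overlap = 20) {
  model <- match.arg(model)
  if (locus$n < 2) abort("need at least 2 sequences", class = "insufficient_data")
  enc <- encode_bases(locus_matrix(locus))
  d <- dist_from_encoded(enc, model, min_overlap)
  new_dist_matrix(d, model, locus$name)
}

new_dist_matrix <- function(d, model, locus = NULL) {
  structure(
    list(ids = rownames(d), model = model, locus = locus, d = d),
    class = "dist_matrix"
  )
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(
    "<dist_matrix> ", length(x$ids), " specimens, model ", x$model,
    ", ", sum(is.na(x$d[upper.tri(x$d)])), " undefined pair(s)\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn distance_matrix Long tibble of unordered pairs
#'   (`id1`, `id2`, `distance`; `NA` = undefined).
#' @param x A `dist_matrix`.
#' @param ... Unused.
#' @export
#' @method tidy dist_matrix
tidy.dist_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    id1 = x$ids[ut[, 1]],
    id2 = x$ids[ut[, 2]],
    distance = x$d[ut]
  )
}

#' Write a distance matrix as square tab-delimited text
#'
#' @param dm A `dist_matrix`.
#' @param path Output path.
#' @param format `"tsv"` (ids in first row/column) or `"phylip"` (square).
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(dm$d)
    df <- cbind(specimen_id = dm$ids, df)
    readr::write_tsv(df, path)
  } else {
    lines <- c(
      sprintf("%5d", length(dm$ids)),
      vapply(seq_along(dm$ids), function(i) {
        paste0(
          formatC(dm$ids[i], width = -10),
          paste(sprintf("%.6f", dm$d[i, ]), collapse = "  ")
        )
      }, character(1))
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Split pairwise distances into intra- and interspecific classes
#'
#' Routes every defined pair to the intraspecific (conspecific) or
#' interspecific class and computes min/max/mean per class. Undefined pairs
#' are excluded from the summary and counted.
#'
#' @param dm A `dist_matrix`.
#' @param specimens Specimen tibble supplying species labels for every id.
#' @return A `pairwise_summary` object. `tidy()` gives the per-pair table,
#'   `glance()` the class min/max/mean.
#' @export
summarize_pairwise <- function(dm, specimens) {
  pairs <- tidy.dist_matrix(dm)
  pairs$species1 <- species_of(pairs$id1, specimens)
  pairs$species2 <- species_of(pairs$id2, specimens)
  pairs$class <- ifelse(pairs$species1 == pairs$species2, "intra", "inter")
  n_undefined <- sum(is.na(pairs$distance))
  defined <- pairs[!is.na(pairs$distance), ]
  # species whose every conspecific pair is undefined contribute nothing
  intra_all <- pairs[pairs$class == "intra", ]
  if (nrow(intra_all) > 0) {
    all_na <- tapply(intra_all$distance, intra_all$species1, function(v) all(is.na(v)))
    lost <- names(all_na)[all_na]
    if (length(lost) > 0) {
      warn(paste0(
        "species with no defined intraspecific pair: ",
        paste(lost, collapse = ", ")
      ))
    }
  }
  stats <- defined |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$distance),
      max = max(.data$distance),
      mean = mean(.data$distance),
      .groups = "drop"
    )
  structure(
    list(
      pairs = pairs, stats = stats,
      n_undefined = n_undefined, model = dm$model, locus = dm$locus
    ),
    class = "pairwise_summary"
  )
}

#' @export
print.pairwise_summary <- function(x, ...) {
  cat("<pairwise_summary>", x$model, "\n")
  print(x$stats)
  invisible(x)
}

#' @export
#' @method tidy pairwise_summary
tidy.pairwise_summary <- function(x, ...) x$pairs

#' @export
#' @method glance pairwise_summary
glance.pairwise_summary <- function(x, ...) {
  g <- function(cl, f) {
    v <- x$stats[[f]][x$stats$class == cl]
    if (length(v) == 0) NA_real_ else v
  }
  tibble(
    locus = x$locus %||% NA_character_,
    model = x$model,
    n_intra = ifelse(is.na(g("intra", "n")), 0L, g("intra", "n")),
    intra_min = g("intra", "min"), intra_max = g("intra", "max"),
    intra_mean = g("intra", "mean"),
    n_inter = ifelse(is.na(g("inter", "n")), 0L, g("inter", "n")),
    inter_min = g("inter", "min"), inter_max = g("inter", "max"),
    inter_mean = g("inter", "mean"),
    n_undefined = x$n_undefined
  )
}

# Defined distances of one class.
class_distances <- function(summary, cl) {
  d <- summary$pairs$distance[summary$pairs$class == cl]
  d[!is.na(d)]
}

#' Assess the barcoding gap at a distance cutoff
#'
#' Reports the fraction of interspecific distances strictly above and
#' intraspecific distances strictly below the cutoff, whether the two
#' distributions overlap (max intra >= min inter), and a shared-bin
#' histogram of both classes.
#'
#' @param summary A [summarize_pairwise()] result with both classes present.
#' @param cutoff Distance cutoff (substitutions/site), default 0.05.
#' @param n_bins Histogram bins.
#' @return A `gap_report`; `glance()` gives the one-row summary, `tidy()`
#'   the histogram, `autoplot()` the overlaid distance histogram.
#' @export
barcoding_gap <- function(summary, cutoff = 0.05, n_bins = 30) {
  intra <- class_distances(summary, "intra")
  inter <- class_distances(summary, "inter")
  if (length(intra) == 0 || length(inter) == 0) {
    abort("need defined distances in both classes", class = "insufficient_data")
  }
  breaks <- seq(0, max(c(intra, inter, cutoff)) * 1.0001 + 1e-9, length.out = n_bins + 1)
  hi <- graphics::hist(intra, breaks = breaks, plot = FALSE)$counts
  he <- graphics::hist(inter, breaks = breaks, plot = FALSE)$counts
  structure(
    list(
      cutoff = cutoff,
      frac_inter_above = 100 * mean(inter > cutoff),
      frac_intra_below = 100 * mean(intra < cutoff),
      overlap = max(intra) >= min(inter),
      histogram = tibble(
        bin_low = breaks[-length(breaks)],
        bin_high = breaks[-1],
        intra = hi,
        inter = he
      ),
      locus = summary$locus
    ),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  cat(
    "<gap_report> cutoff ", x$cutoff, ": ",
    sprintf("%.1f%%", x$frac_inter_above), " inter above, ",
    sprintf("%.1f%%", x$frac_intra_below), " intra below, overlap ",
    x$overlap, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
#' @method tidy gap_report
tidy.gap_report <- function(x, ...) x$histogram

#' @export
#' @method glance gap_report
glance.gap_report <- function(x, ...) {
  tibble(
    locus = x$locus %||% NA_character_,
    cutoff = x$cutoff,
    frac_inter_above = x$frac_inter_above,
    frac_intra_below = x$frac_intra_below,
    overlap = x$overlap
  )
}
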
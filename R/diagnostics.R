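# Character-based mini-barcode analysis: alignment columns at which two
# species carry fixed, different states (the gap counting as a fifth state,
# so diagnostic deletions are captured), merged into contiguous blocks.

#' Species-diagnostic alignment columns between two species
#'
#' A column is diagnostic when every member of species A shares one state,
#' every member of species B shares one (different) state, and both states
#' are in `A/C/G/T/-`. By default any missing or ambiguous character
#' (`N`, `?`, IUPAC codes) in a member disqualifies the column; with
#' `allow_missing = TRUE` those members are ignored instead.
#'
#' @param locus An [aligned_locus()].
#' @param specimens Specimen tibble.
#' @param species_a,species_b The two species to contrast; both need at
#'   least one sequence at the locus.
#' @param allow_missing Ignore, rather than disqualify on, missing or
#'   ambiguous characters.
#' @return A tibble (`column`, `state_a`, `state_b`), 1-based alignment
#'   columns in ascending order, with the locus and species pair and one
#'   reference sequence per species attached as attributes.
#' @export
diagnostic_sites <- function(locus, specimens, species_a, species_b,
                             allow_missing = FALSE) {
  sp <- species_of(names(locus$seqs), specimens)
  rows_a <- which(sp == species_a)
  rows_b <- which(sp == species_b)
  if (length(rows_a) == 0 || length(rows_b) == 0) {
    absent <- c(species_a, species_b)[c(length(rows_a), length(rows_b)) == 0]
    abort(
      paste0("no sequences at ", locus$name, " for: ", paste(absent, collapse = ", ")),
      class = "insufficient_data"
    )
  }
  m <- locus_matrix(locus)
  states <- c(BASES, "-")
  fixed_state <- function(chars) {
    if (allow_missing) chars <- chars[chars %in% states]
    if (length(chars) == 0 || any(!chars %in% states)) {
      return(NA_character_)
    }
    u <- unique(chars)
    if (length(u) == 1) u else NA_character_
  }
  st_a <- apply(m[rows_a, , drop = FALSE], 2, fixed_state)
  st_b <- apply(m[rows_b, , drop = FALSE], 2, fixed_state)
  diag_cols <- which(!is.na(st_a) & !is.na(st_b) & st_a != st_b)
  out <- tibble(
    column = as.integer(diag_cols),
    state_a = unname(st_a[diag_cols]),
    state_b = unname(st_b[diag_cols])
  )
  attr(out, "locus") <- locus$name
  attr(out, "species_pair") <- c(species_a, species_b)
  attr(out, "ref_a") <- unname(locus$seqs[rows_a[1]])
  attr(out, "ref_b") <- unname(locus$seqs[rows_b[1]])
  out
}

#' Merge diagnostic columns into contiguous blocks
#'
#' Maximal runs of consecutive diagnostic columns become blocks; a block is
#' an `indel` when one species' state string is all gaps across it,
#' otherwise a `substitution`. Coordinates are 1-based inclusive alignment
#' columns; `start_ungapped_a`/`_b` give the block start in each species'
#' own ungapped coordinates (counted on one reference sequence per species;
#' for the deleted species this is the position after which the deletion
#' falls).
#'
#' @param sites Output of [diagnostic_sites()].
#' @return A tibble, one row per block: locus, species pair, `start`,
#'   `end`, `length`, `state_a`, `state_b`, `kind`, ungapped starts.
#' @export
diagnostic_blocks <- function(sites) {
  pair <- attr(sites, "species_pair") %||% c(NA_character_, NA_character_)
  locus <- attr(sites, "locus") %||% NA_character_
  empty <- tibble(
    locus = character(), species_a = character(), species_b = character(),
    start = integer(), end = integer(), length = integer(),
    state_a = character(), state_b = character(), kind = character(),
    start_ungapped_a = integer(), start_ungapped_b = integer()
  )
  if (nrow(sites) == 0) {
    return(empty)
  }
  ungapped_pos <- function(ref, col) {
    if (is.null(ref)) {
      return(NA_integer_)
    }
    chars <- strsplit(ref, "")[[1]]
    as.integer(sum(chars[seq_len(col)] != "-"))
  }
  run <- cumsum(c(1L, diff(sites$column) != 1L))
  blocks <- lapply(split(seq_len(nrow(sites)), run), function(idx) {
    s <- sites[idx, ]
    tibble(
      locus = locus,
      species_a = pair[1], species_b = pair[2],
      start = s$column[1],
      end = s$column[nrow(s)],
      length = nrow(s),
      state_a = paste(s$state_a, collapse = ""),
      state_b = paste(s$state_b, collapse = ""),
      kind = if (all(s$state_a == "-") || all(s$state_b == "-")) "indel" else "substitution",
      start_ungapped_a = ungapped_pos(attr(sites, "ref_a"), s$column[1]),
      start_ungapped_b = ungapped_pos(attr(sites, "ref_b"), s$column[1])
    )
  })
  dplyr::bind_rows(blocks)
}

#' Diagnostic blocks for every species pair at a locus
#'
#' Convenience scan over all unordered species pairs with sequences at the
#' locus.
#'
#' @inheritParams diagnostic_sites
#' @return A tibble of blocks (possibly empty) across all pairs.
#' @export
diagnostic_block_scan <- function(locus, specimens, allow_missing = FALSE) {
  sp <- sort(unique(species_of(names(locus$seqs), specimens)))
  if (length(sp) < 2) {
    return(diagnostic_blocks(tibble(
      column = integer(), state_a = character(), state_b = character()
    )))
  }
  pairs <- combn(sp, 2, simplify = FALSE)
  dplyr::bind_rows(lapply(pairs, function(p) {
    diagnostic_blocks(diagnostic_sites(
      locus, specimens, p[1], p[2],
      allow_missing = allow_missing
    ))
  }))
}
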
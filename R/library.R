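# Core containers: an aligned barcode locus and a multi-locus library.

# Alphabet handled throughout: unambiguous bases, IUPAC ambiguity codes,
# gap '-', missing 'N'/'?'. Only ACGT carry state information downstream.
BASES <- c("A", "C", "G", "T")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
MISSING <- c("N", "?")
ALPHABET <- c(BASES, IUPAC_AMBIG, MISSING, "-")

#' Construct an aligned barcode locus
#'
#' Bundles one barcode region's alignment: a named set of equal-length
#' sequences keyed by specimen id. Sequences are uppercased on construction.
#'
#' @param seqs Named character vector of aligned sequences (names are
#'   specimen ids). Allowed characters: `ACGT`, IUPAC ambiguity codes,
#'   `N`, `?` and the gap `-`.
#' @param name Locus label, e.g. `"ITS2"`.
#' @return An object of class `aligned_locus` with fields `name`, `seqs`,
#'   `length` (alignment columns) and `n` (sequences).
#' @examples
#' aligned_locus(c(s1 = "ACGT-", s2 = "ACGTA"), "demo")
#' @export
aligned_locus <- function(seqs, name) {
  if (length(seqs) == 0) abort("alignment has no sequences", class = "format_error")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("every sequence needs a specimen id", class = "format_error")
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    abort(
      paste0(
        "sequences are not aligned: lengths ",
        paste(unique(lens), collapse = ", ")
      ),
      class = "alignment_error"
    )
  }
  bad <- vapply(
    strsplit(seqs, ""),
    function(ch) any(!ch %in% ALPHABET),
    logical(1)
  )
  if (any(bad)) {
    abort(
      paste0("illegal characters in record(s): ", paste(names(seqs)[bad], collapse = ", ")),
      class = "format_error"
    )
  }
  structure(
    list(name = name, seqs = seqs, length = unname(lens[1]), n = length(seqs)),
    class = "aligned_locus"
  )
}

#' @export
print.aligned_locus <- function(x, ...) {
  cat(
    "<aligned_locus> ", x$name, ": ", x$n, " sequences x ",
    x$length, " columns\n",
    sep = ""
  )
  invisible(x)
}

#' @export
#' @method as_tibble aligned_locus
as_tibble.aligned_locus <- function(x, ...) {
  tibble(specimen_id = names(x$seqs), sequence = unname(x$seqs))
}

# Character matrix view (rows = specimens, cols = alignment columns).
locus_matrix <- function(locus) {
  m <- do.call(rbind, strsplit(unname(locus$seqs), ""))
  rownames(m) <- names(locus$seqs)
  m
}

#' Construct a barcode library
#'
#' A library joins a specimen metadata table with one or more aligned loci.
#' Validation checks id uniqueness and that every alignment row refers to a
#' known specimen.
#'
#' @param specimens Data frame with columns `specimen_id`, `species`,
#'   `vouchered` (logical), `region`, `tissue`.
#' @param loci List of [aligned_locus()] objects; names are taken from each
#'   locus' own `name`.
#' @return An object of class `barcode_library`.
#' @export
barcode_library <- function(specimens, loci) {
  specimens <- as_tibble(specimens)
  required <- c("specimen_id", "species", "vouchered", "region", "tissue")
  miss <- setdiff(required, names(specimens))
  if (length(miss) > 0) {
    abort(paste0("metadata lacks column(s): ", paste(miss, collapse = ", ")),
      class = "format_error"
    )
  }
  if (anyDuplicated(specimens$specimen_id)) {
    dup <- unique(specimens$specimen_id[duplicated(specimens$specimen_id)])
    abort(paste0("duplicate specimen_id: ", paste(dup, collapse = ", ")),
      class = "validation_error"
    )
  }
  if (any(!nzchar(specimens$species) | is.na(specimens$species))) {
    abort("every specimen needs a non-empty species", class = "validation_error")
  }
  if (inherits(loci, "aligned_locus")) loci <- list(loci)
  names(loci) <- vapply(loci, function(l) l$name, character(1))
  if (anyDuplicated(names(loci))) {
    abort("locus names must be unique", class = "validation_error")
  }
  for (l in loci) {
    unknown <- setdiff(names(l$seqs), specimens$specimen_id)
    if (length(unknown) > 0) {
      abort(
        paste0(
          "locus ", l$name, " has rows for unknown specimen(s): ",
          paste(unknown, collapse = ", ")
        ),
        class = "validation_error"
      )
    }
  }
  structure(list(specimens = specimens, loci = loci), class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(
    "<barcode_library> ", nrow(x$specimens), " specimens, ",
    length(x$loci), " loci\n",
    sep = ""
  )
  for (l in x$loci) {
    cat("  ", l$name, ": ", l$n, " x ", l$length, "\n", sep = "")
  }
  invisible(x)
}

# Species lookup vector for a set of specimen ids.
species_of <- function(ids, specimens) {
  sp <- setNames(specimens$species, specimens$specimen_id)
  out <- sp[ids]
  if (anyNA(out)) {
    abort(
      paste0(
        "specimen(s) missing from metadata: ",
        paste(ids[is.na(out)], collapse = ", ")
      ),
      class = "key_error"
    )
  }
  unname(out)
}
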
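# Reading and writing alignments, metadata, and whole libraries.

#' Read an aligned FASTA file as a locus
#'
#' The first whitespace-delimited token of each FASTA header is taken as the
#' specimen id; the remainder of the header is ignored. Sequences are
#' uppercased. All sequences must have equal length.
#'
#' @param path Path to an aligned FASTA file.
#' @param name Locus label; defaults to the file name without extension.
#' @return An [aligned_locus()].
#' @export
read_alignment <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "format_error")
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("not readable as FASTA: ", path), class = "format_error")
  )
  if (length(set) == 0) abort(paste0("empty FASTA: ", path), class = "format_error")
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  aligned_locus(seqs, name)
}

#' Write a locus as aligned FASTA
#'
#' @param locus An [aligned_locus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(locus, path) {
  set <- Biostrings::BStringSet(locus$seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read specimen metadata from TSV
#'
#' Expects a header with columns `specimen_id`, `species`, `vouchered`,
#' `region`, `tissue`. The voucher flag accepts true/false, 1/0, yes/no
#' (case-insensitive).
#'
#' @param path Path to a tab-separated metadata table.
#' @return A tibble, one row per specimen.
#' @export
read_specimens <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("specimen_id", "species", "vouchered", "region", "tissue")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort(paste0("metadata lacks column(s): ", paste(miss, collapse = ", ")),
      class = "format_error"
    )
  }
  if (anyDuplicated(df$specimen_id)) {
    dup <- unique(df$specimen_id[duplicated(df$specimen_id)])
    abort(paste0("duplicate specimen_id: ", paste(dup, collapse = ", ")),
      class = "validation_error"
    )
  }
  df$vouchered <- parse_flag(df$vouchered)
  df[required]
}

parse_flag <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "1", "yes")] <- TRUE
  out[lx %in% c("false", "0", "no")] <- FALSE
  if (anyNA(out)) {
    abort(
      paste0("unparseable voucher flag(s): ", paste(unique(x[is.na(out)]), collapse = ", ")),
      class = "format_error"
    )
  }
  out
}

#' Write specimen metadata as TSV
#'
#' @param specimens Specimen tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(specimens, path) {
  readr::write_tsv(specimens, path)
  invisible(path)
}

#' Write a whole library to a directory
#'
#' Emits `metadata.tsv` plus one aligned FASTA per locus (`<locus>.fasta`).
#'
#' @param library A [barcode_library()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_specimens(library$specimens, file.path(dir, "metadata.tsv"))
  for (l in library$loci) {
    write_alignment(l, file.path(dir, paste0(l$name, ".fasta")))
  }
  invisible(dir)
}

#' Read a library from a directory written by [write_library()]
#'
#' @param dir Directory containing `metadata.tsv` and per-locus FASTA files.
#' @return A [barcode_library()].
#' @export
read_library <- function(dir) {
  specimens <- read_specimens(file.path(dir, "metadata.tsv"))
  fastas <- sort(list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  loci <- lapply(fastas, read_alignment)
  barcode_library(specimens, loci)
}
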
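# Unrooted NJ trees, bootstrap bipartition support, and cluster scoring
# under the voucher-aware discrimination criterion: a label is discriminated
# only if some edge of the unrooted tree separates exactly its specimens
# from all others AND the cluster contains at least one vouchered specimen.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ agglomeration. The matrix must be complete; resolve
#' undefined entries first (see [prune_undefined()]). Negative branch
#' lengths are retained as computed.
#'
#' @param dm A [distance_matrix()] result with >= 3 taxa and no undefined
#'   entries.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (length(dm$ids) < 3) abort("need at least 3 taxa", class = "insufficient_taxa")
  if (anyNA(dm$d)) {
    abort("matrix has undefined entries; prune or impute first",
      class = "incomplete_matrix"
    )
  }
  ape::nj(stats::as.dist(dm$d))
}

#' Drop specimens until a distance matrix is complete
#'
#' Iteratively removes the specimen with the most undefined entries (ties:
#' first id) until no undefined entries remain.
#'
#' @param dm A `dist_matrix`.
#' @return A complete `dist_matrix`; removed ids are reported via a message
#'   and kept in the `"pruned"` attribute.
#' @export
prune_undefined <- function(dm) {
  d <- dm$d
  removed <- character(0)
  while (anyNA(d)) {
    na_count <- rowSums(is.na(d))
    worst <- which.max(na_count)
    removed <- c(removed, rownames(d)[worst])
    d <- d[-worst, -worst, drop = FALSE]
  }
  if (length(removed) > 0) {
    inform(paste0(
      "pruned specimen(s) with undefined distances: ",
      paste(removed, collapse = ", ")
    ))
  }
  out <- new_dist_matrix(d, dm$model, dm$locus)
  attr(out, "pruned") <- removed
  out
}

# Canonical key for an unrooted bipartition: the side not containing the
# alphabetically first tip, sorted and collapsed.
bipartition_key <- function(side, all_tips) {
  ref <- min(all_tips)
  if (ref %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = "\r")
}

# Bipartitions induced by internal edges: one entry per non-root internal
# node (tips of its clade), named by canonical key. min_length drops edges
# at or below that length (an unresolved edge carries no signal).
internal_bipartitions <- function(tree, min_length = NULL) {
  ntip <- ape::Ntip(tree)
  parts <- ape::prop.part(tree)
  nodes <- ntip + seq_along(parts)
  keep <- nodes != ntip + 1L # the basal node's "clade" is all tips
  if (!is.null(min_length)) {
    edge_len <- setNames(tree$edge.length, tree$edge[, 2])
    keep <- keep & (edge_len[as.character(nodes)] > min_length)
    keep[is.na(keep)] <- FALSE
  }
  sides <- lapply(parts[keep], function(idx) tree$tip.label[idx])
  keys <- vapply(sides, bipartition_key, character(1), all_tips = tree$tip.label)
  setNames(nodes[keep], keys)
}

#' NJ tree with bootstrap support
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `n_reps` times; each internal edge is annotated
#' with the percentage of replicate trees containing the same bipartition.
#' Zero-length replicate edges are treated as unresolved and never support a
#' bipartition, so an alignment without signal yields supports of 0.
#' Replicates whose resampled matrix has undefined distances are skipped and
#' reported.
#'
#' @param locus An [aligned_locus()] whose full-data distance matrix is
#'   complete.
#' @param model Distance model for tree building (default `"p"`).
#' @param n_reps Bootstrap replicates (>= 1).
#' @param seed Integer seed for column resampling.
#' @param min_overlap Passed to the distance computation.
#' @return The NJ tree with `node.label` holding support percentages
#'   (`NA` on the basal node).
#' @export
bootstrap_support <- function(locus, model = c("p", "K2P"), n_reps = 100,
                              seed = 1, min_overlap = 20) {
  model <- match.arg(model)
  if (n_reps < 1) abort("n_reps must be >= 1", class = "invalid_argument")
  enc <- encode_bases(locus_matrix(locus))
  d0 <- dist_from_encoded(enc, model, min_overlap)
  if (anyNA(d0)) {
    abort("undefined distances in full data; prune first", class = "incomplete_matrix")
  }
  tree <- ape::nj(stats::as.dist(d0))
  nodes0 <- internal_bipartitions(tree)
  counts <- setNames(numeric(length(nodes0)), names(nodes0))
  skipped <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(enc), ncol(enc), replace = TRUE)
      dr <- dist_from_encoded(enc[, cols, drop = FALSE], model, min_overlap)
      if (anyNA(dr)) {
        skipped <- skipped + 1L
        next
      }
      tr <- ape::nj(stats::as.dist(dr))
      seen <- names(internal_bipartitions(tr, min_length = 1e-12))
      hit <- intersect(seen, names(counts))
      counts[hit] <- counts[hit] + 1
    }
  })
  n_used <- n_reps - skipped
  if (skipped > 0) {
    inform(paste0(skipped, " bootstrap replicate(s) skipped (undefined distances)"))
  }
  support <- rep(NA_real_, ape::Nnode(tree))
  if (n_used > 0) {
    support[nodes0 - ape::Ntip(tree)] <- 100 * counts / n_used
  }
  tree$node.label <- support
  tree
}

label_of <- function(ids, specimens, field) {
  lk <- setNames(specimens[[field]], specimens$specimen_id)
  out <- lk[ids]
  if (anyNA(out) || any(!nzchar(out))) {
    abort(
      paste0(
        "leaf/leaves without a ", field, " label: ",
        paste(ids[is.na(out) | !nzchar(out)], collapse = ", ")
      ),
      class = "key_error"
    )
  }
  unname(out)
}

#' Score label clusters on an unrooted tree
#'
#' For each label (species or region), checks whether some edge of the
#' unrooted tree separates exactly that label's specimens from all others
#' (an exclusive cluster). A label is discriminated when it forms an
#' exclusive cluster containing at least one vouchered specimen and, when
#' the tree carries bootstrap supports and `min_support > 0`, the defining
#' edge's support reaches `min_support`. The overall rate is taken over
#' labels with at least two specimens.
#'
#' @param tree An unrooted `phylo`; every leaf must be in `specimens`.
#' @param specimens Specimen tibble.
#' @param label_field `"species"` or `"region"`.
#' @param min_support Minimum bootstrap support (%) required when supports
#'   are present; 0 disables the gate.
#' @return A `discrimination` object; `tidy()` gives the per-label table,
#'   `glance()` the overall rate.
#' @export
label_clusters <- function(tree, specimens, label_field = c("species", "region"),
                           min_support = 0) {
  label_field <- match.arg(label_field)
  tips <- tree$tip.label
  labs <- label_of(tips, specimens, label_field)
  vouch <- setNames(specimens$vouchered, specimens$specimen_id)[tips]
  bips <- internal_bipartitions(tree)
  supports <- tree$node.label
  has_supports <- !is.null(supports) && any(!is.na(suppressWarnings(as.numeric(supports))))
  if (has_supports) supports <- suppressWarnings(as.numeric(supports))
  per_label <- lapply(unique(labs), function(lb) {
    ids <- tips[labs == lb]
    n <- length(ids)
    if (n == length(tips)) {
      # a label covering every leaf has no separating edge
      return(tibble(
        label = lb, n = n, is_exclusive = FALSE, has_voucher = any(vouch[ids]),
        support = NA_real_, discriminated = FALSE
      ))
    }
    if (n == 1) {
      return(tibble(
        label = lb, n = n, is_exclusive = TRUE, has_voucher = any(vouch[ids]),
        support = NA_real_, discriminated = NA
      ))
    }
    if (n == length(tips) - 1) {
      # the complement is one leaf: its pendant edge separates the label
      return(tibble(
        label = lb, n = n, is_exclusive = TRUE, has_voucher = any(vouch[ids]),
        support = NA_real_, discriminated = any(vouch[ids])
      ))
    }
    key <- bipartition_key(ids, tips)
    node <- unname(bips[key])
    exclusive <- !is.na(node)
    sup <- if (exclusive && has_supports) supports[node - ape::Ntip(tree)] else NA_real_
    sup_ok <- !has_supports || min_support <= 0 ||
      (!is.na(sup) && sup >= min_support)
    tibble(
      label = lb, n = n, is_exclusive = exclusive,
      has_voucher = any(vouch[ids]), support = sup,
      discriminated = exclusive && any(vouch[ids]) && sup_ok
    )
  })
  tab <- dplyr::bind_rows(per_label)
  scored <- tab$n >= 2
  overall <- if (any(scored)) 100 * sum(tab$discriminated[scored]) / sum(scored) else NA_real_
  structure(
    list(
      table = tab, label_field = label_field,
      min_support = min_support, overall_rate = overall
    ),
    class = "discrimination"
  )
}

#' @export
print.discrimination <- function(x, ...) {
  cat(
    "<discrimination> by ", x$label_field, ": overall ",
    sprintf("%.1f%%", x$overall_rate), "\n",
    sep = ""
  )
  print(x$table)
  invisible(x)
}

#' @export
#' @method tidy discrimination
tidy.discrimination <- function(x, ...) x$table

#' @export
#' @method glance discrimination
glance.discrimination <- function(x, ...) {
  tibble(
    label_field = x$label_field,
    n_labels = nrow(x$table),
    n_scored = sum(x$table$n >= 2),
    min_support = x$min_support,
    overall_rate = x$overall_rate
  )
}

#' Write a tree as Newick
#'
#' @param tree A `phylo`, optionally with support node labels.
#' @param path Output path, or `NULL` to return the Newick string.
#' @param clamp_negative Clamp negative branch lengths to 0 in the output
#'   (the in-memory tree is never modified).
#' @param digits Branch-length digits.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL, clamp_negative = FALSE, digits = 6) {
  if (clamp_negative) tree$edge.length <- pmax(tree$edge.length, 0)
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    tree$node.label <- ifelse(is.na(lab), "", format(round(as.numeric(lab), 1)))
  }
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path)
  invisible(txt)
}
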
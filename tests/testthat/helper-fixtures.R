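# Shared fixtures, all built in code.

make_specimens <- function(ids, species, vouchered = TRUE, region = "Asia",
                           tissue = "heartwood") {
  tibble::tibble(
    specimen_id = ids,
    species = species,
    vouchered = rep_len(vouchered, length(ids)),
    region = rep_len(region, length(ids)),
    tissue = rep_len(tissue, length(ids))
  )
}

# A distance matrix object with prescribed entries, for matching tests.
make_dm <- function(d, ids, model = "K2P") {
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, model = model, locus = NULL, d = d), class = "dist_matrix")
}

# Symmetric random distance matrix over two species (no structure implied).
random_dm <- function(n, seed) {
  d <- withr::with_seed(seed, {
    m <- matrix(stats::runif(n * n, 0, 0.3), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    m
  })
  make_dm(d, sprintf("q%02d", seq_len(n)))
}

# Two well-separated species, two specimens each, one 40-column locus:
# species differ at 8 fixed sites, conspecifics at 1.
separated_library <- function() {
  base <- strrep("ACGT", 10)
  mut <- function(s, pos, to) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- to
    paste(ch, collapse = "")
  }
  a1 <- base
  a2 <- mut(base, 2, "A")
  b <- Reduce(function(s, p) mut(s, p, "T"), c(5, 9, 13, 17, 21, 25, 29, 33), base)
  b1 <- b
  b2 <- mut(b, 38, "A")
  specimens <- make_specimens(
    c("A1", "A2", "B1", "B2"),
    rep(c("sp_a", "sp_b"), each = 2)
  )
  barcode_library(
    specimens,
    list(aligned_locus(c(A1 = a1, A2 = a2, B1 = b1, B2 = b2), "L1"))
  )
}

# A three-locus library in which locus X alone separates the three species:
# Y leaves two species identical, Z is invariant.
constructed_library <- function() {
  specimens <- make_specimens(
    c("a1", "a2", "b1", "b2", "c1", "c2"),
    rep(c("a", "b", "c"), each = 2)
  )
  block <- function(ch) strrep(ch, 10)
  x <- c(
    a1 = paste0(block("A"), strrep("ACGT", 10)),
    a2 = paste0(block("A"), strrep("ACGT", 10)),
    b1 = paste0(block("G"), strrep("ACGT", 10)),
    b2 = paste0(block("G"), strrep("ACGT", 10)),
    c1 = paste0(block("T"), strrep("ACGT", 10)),
    c2 = paste0(block("T"), strrep("ACGT", 10))
  )
  ybase <- strrep("GTCA", 10)
  ych <- strsplit(ybase, "")[[1]]
  ych[c(3, 11, 23)] <- "T"
  yc <- paste(ych, collapse = "")
  y <- c(a1 = ybase, a2 = ybase, b1 = ybase, b2 = ybase, c1 = yc, c2 = yc)
  z <- stats::setNames(rep(strrep("TTGG", 15), 6), names(x))
  barcode_library(specimens, list(
    aligned_locus(x, "X"), aligned_locus(y, "Y"), aligned_locus(z, "Z")
  ))
}

# A pairwise_summary with prescribed class distance lists.
fake_summary <- function(intra, inter) {
  pairs <- tibble::tibble(
    id1 = sprintf("p%03d", seq_len(length(intra) + length(inter))),
    id2 = sprintf("q%03d", seq_len(length(intra) + length(inter))),
    distance = c(intra, inter),
    species1 = c(rep("a", length(intra)), rep("a", length(inter))),
    species2 = c(rep("a", length(intra)), rep("b", length(inter))),
    class = c(rep("intra", length(intra)), rep("inter", length(inter)))
  )
  stats <- pairs |>
    dplyr::group_by(class) |>
    dplyr::summarise(
      n = dplyr::n(), min = min(distance), max = max(distance),
      mean = mean(distance), .groups = "drop"
    )
  structure(
    list(pairs = pairs, stats = stats, n_undefined = 0, model = "K2P", locus = NULL),
    class = "pairwise_summary"
  )
}

# Brute-force exclusivity oracle: drop each edge in turn and flood-fill the
# remaining graph to get the two leaf sets it separates.
edge_splits_bruteforce <- function(tree) {
  edges <- tree$edge
  n_nodes <- max(edges)
  lapply(seq_len(nrow(edges)), function(e) {
    keep <- edges[-e, , drop = FALSE]
    adj <- lapply(seq_len(n_nodes), function(i) integer(0))
    for (r in seq_len(nrow(keep))) {
      adj[[keep[r, 1]]] <- c(adj[[keep[r, 1]]], keep[r, 2])
      adj[[keep[r, 2]]] <- c(adj[[keep[r, 2]]], keep[r, 1])
    }
    seen <- logical(n_nodes)
    stack <- edges[e, 2]
    while (length(stack) > 0) {
      v <- stack[[1]]
      stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, adj[[v]])
    }
    tree$tip.label[which(seen[seq_along(tree$tip.label)])]
  })
}
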
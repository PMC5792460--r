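# Seed-deterministic multi-locus barcode library simulator.
#
# Sequences evolve along a species tree under a two-parameter
# (transition/transversion) substitution process, the same process family the
# K2P estimator downstream assumes, so parameter-recovery checks are
# meaningful. Specimens hang off their species as a star of short branches;
# species-diagnostic indel blocks and per-locus dropout are overlaid
# afterwards.

#' Configure one simulated locus
#'
#' @param name Locus label.
#' @param length Alignment length in sites (>= 50).
#' @param inter_depth Expected substitutions/site separating two species.
#' @param intra_depth Expected substitutions/site separating conspecific
#'   specimens; must be below `inter_depth`.
#' @param kappa Transition/transversion rate ratio (dimensionless, default 2).
#' @param indel_rate Per-species probability of carrying one diagnostic
#'   deletion block.
#' @param indel_length Length of that block in alignment columns.
#' @param recovery_rate Fraction of specimens that yield a sequence at this
#'   locus, in (0, 1]. Implemented as an exact rounded count.
#' @param gc Equilibrium G+C content in (0, 1).
#' @return A `locus_config` list.
#' @export
locus_config <- function(name, length, inter_depth, intra_depth,
                         kappa = 2, indel_rate = 0, indel_length = 6,
                         recovery_rate = 1, gc = 0.5) {
  stopifnot(
    is.character(name), nzchar(name),
    length >= 50,
    inter_depth > 0, intra_depth >= 0, intra_depth < inter_depth,
    kappa > 0,
    indel_rate >= 0, indel_rate <= 1, indel_length >= 1,
    recovery_rate > 0, recovery_rate <= 1,
    gc > 0, gc < 1
  )
  structure(
    list(
      name = name, length = as.integer(length), kappa = kappa,
      inter_depth = inter_depth, intra_depth = intra_depth,
      indel_rate = indel_rate, indel_length = as.integer(indel_length),
      recovery_rate = recovery_rate, gc = gc
    ),
    class = "locus_config"
  )
}

#' Configure a library simulation
#'
#' @param n_species Number of species (>= 2).
#' @param samples_per_species Integer vector of specimens per species,
#'   recycled to `n_species`.
#' @param loci List of [locus_config()] objects.
#' @param seed Integer master seed; every random draw derives from it.
#' @param linked If `TRUE` all loci share one species-tree topology (one
#'   plastid-style genealogy); default `FALSE`, independent genealogies.
#' @param species Optional species labels.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species, samples_per_species, loci, seed = 1,
                       linked = FALSE, species = NULL) {
  if (n_species < 2) abort("n_species must be >= 2", class = "invalid_argument")
  samples_per_species <- rep_len(as.integer(samples_per_species), n_species)
  if (any(samples_per_species < 1)) {
    abort("samples_per_species must all be >= 1", class = "invalid_argument")
  }
  if (inherits(loci, "locus_config")) loci <- list(loci)
  species <- species %||% sprintf("species_%02d", seq_len(n_species))
  structure(
    list(
      n_species = as.integer(n_species),
      samples_per_species = samples_per_species,
      loci = loci, seed = as.integer(seed), linked = linked,
      species = species
    ),
    class = "sim_config"
  )
}

#' Simulate a random species tree
#'
#' Draws a random unrooted binary topology and assigns branch lengths so any
#' two species are separated by approximately `inter_depth` substitutions per
#' site: terminal edges of `inter_depth / 2` joined by short internal edges.
#'
#' @param n_species Number of species (>= 2).
#' @param inter_depth Target between-species path length (substitutions/site).
#' @param seed Integer seed; the topology is deterministic given it.
#' @param labels Optional tip labels.
#' @return An `ape::phylo` tree with `n_species` tips.
#' @export
build_species_tree <- function(n_species, inter_depth, seed, labels = NULL) {
  if (n_species < 2) abort("need at least 2 species", class = "invalid_argument")
  labels <- labels %||% sprintf("species_%02d", seq_len(n_species))
  stopifnot(length(labels) == n_species)
  h <- inter_depth / 2
  if (n_species == 2) {
    txt <- sprintf("(%s:%.10f,%s:%.10f);", labels[1], h, labels[2], h)
    return(ape::read.tree(text = txt))
  }
  tr <- withr::with_seed(seed, ape::rtopology(n_species, rooted = FALSE))
  idx <- as.integer(sub("^t", "", tr$tip.label))
  tr$tip.label <- labels[idx]
  terminal <- tr$edge[, 2] <= n_species
  tr$edge.length[terminal] <- h
  tr$edge.length[!terminal] <- inter_depth / 50
  tr
}

# Graft each species' specimens onto the species tree as a star of branches
# of length intra_depth / 2, shortening the species' terminal edge by the
# same amount so specimen-to-other-species paths stay near inter_depth.
expand_to_specimen_tree <- function(tree, specimens, intra_depth) {
  unknown <- setdiff(unique(specimens$species), tree$tip.label)
  if (length(unknown) > 0) {
    abort(
      paste0("species not in tree: ", paste(unknown, collapse = ", ")),
      class = "key_error"
    )
  }
  d <- intra_depth / 2
  tr <- tree
  sub <- character(ape::Ntip(tr))
  for (i in seq_len(ape::Ntip(tr))) {
    ids <- specimens$specimen_id[specimens$species == tr$tip.label[i]]
    if (length(ids) == 0) {
      abort(paste0("no specimens for species ", tr$tip.label[i]), class = "key_error")
    }
    if (length(ids) == 1) {
      sub[i] <- ids
    } else {
      sub[i] <- paste0("(", paste0(ids, ":", format(d, scientific = FALSE), collapse = ","), ")")
      e <- which(tr$edge[, 2] == i)
      tr$edge.length[e] <- max(tr$edge.length[e] - d, 1e-9)
    }
    tr$tip.label[i] <- sprintf("ZPLACEHOLDER%dZ", i)
  }
  txt <- ape::write.tree(tr)
  for (i in seq_along(sub)) {
    txt <- sub(sprintf("ZPLACEHOLDER%dZ", i), sub[i], txt, fixed = TRUE)
  }
  ape::read.tree(text = txt)
}

k80_rates <- function(kappa) c(1, kappa, 1, 1, kappa, 1) # AC AG AT CG CT GT

#' Simulate one aligned locus over a specimen table
#'
#' @param tree Species tree (`phylo`; tips are species names).
#' @param cfg A [locus_config()].
#' @param specimens Specimen tibble (`specimen_id`, `species`, ...); every
#'   species must be a tree tip.
#' @param seed Integer seed.
#' @return An [aligned_locus()] with one row per recovered specimen.
#' @export
simulate_locus <- function(tree, cfg, specimens, seed) {
  spec_tree <- expand_to_specimen_tree(tree, specimens, cfg$intra_depth)
  bf <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  withr::with_seed(seed, {
    sim <- phangorn::simSeq(
      spec_tree,
      l = cfg$length, Q = k80_rates(cfg$kappa), bf = bf, type = "DNA"
    )
    m <- toupper(as.character(sim))
    # species-diagnostic deletion blocks
    for (sp in unique(specimens$species)) {
      if (stats::runif(1) < cfg$indel_rate) {
        start <- sample.int(cfg$length - cfg$indel_length + 1L, 1L)
        rows <- specimens$specimen_id[specimens$species == sp]
        m[rows, start:(start + cfg$indel_length - 1L)] <- "-"
      }
    }
    # dropout: exact rounded count of recovered specimens
    n_keep <- as.integer(round(cfg$recovery_rate * nrow(specimens)))
    keep <- sort(sample.int(nrow(specimens), n_keep))
    ids <- specimens$specimen_id[keep]
    seqs <- apply(m[ids, , drop = FALSE], 1, paste0, collapse = "")
    aligned_locus(seqs, cfg$name)
  })
}

#' Simulate a whole multi-locus barcode library
#'
#' Builds the specimen table, one species genealogy per locus (or a shared
#' one in linked mode) and the per-locus alignments. All specimens are
#' flagged as vouchered; species are split between two broad regions and
#' tissue types cycle through heartwood, sapwood, twig and leaf.
#'
#' @param cfg A [sim_config()].
#' @return A [barcode_library()]; the species trees used are attached as
#'   attribute `"true_trees"` and the config as `"config"`.
#' @export
simulate_library <- function(cfg) {
  n <- sum(cfg$samples_per_species)
  specimens <- tibble(
    specimen_id = sprintf("WD%03d", seq_len(n)),
    species = rep(cfg$species, cfg$samples_per_species),
    vouchered = TRUE,
    region = rep(
      ifelse(seq_len(cfg$n_species) <= ceiling(cfg$n_species / 2), "Asia", "Africa"),
      cfg$samples_per_species
    ),
    tissue = rep_len(c("heartwood", "sapwood", "twig", "leaf"), n)
  )
  trees <- list()
  loci <- list()
  for (i in seq_along(cfg$loci)) {
    lc <- cfg$loci[[i]]
    topo_seed <- if (isTRUE(cfg$linked)) cfg$seed else cfg$seed + 101L * i
    tr <- build_species_tree(cfg$n_species, lc$inter_depth, topo_seed, labels = cfg$species)
    trees[[lc$name]] <- tr
    loci[[i]] <- simulate_locus(tr, lc, specimens, seed = cfg$seed + 17L * i)
  }
  lib <- barcode_library(specimens, loci)
  attr(lib, "true_trees") <- trees
  attr(lib, "config") <- cfg
  lib
}

#' Demonstration library configuration
#'
#' A four-locus, six-species configuration mirroring a typical hardwood
#' barcoding study: 39 specimens (4-11 per species); loci shaped like ITS2,
#' matK, ndhF-rpl32 and rbcL with aligned lengths 234/239/173/350 bp,
#' per-locus recovery of 26/39, 32/39, 35/39 and 27/39 specimens, and
#' within-/between-species divergences matching the distances such studies
#' report (intra 0.0026-0.020, inter 0.0073-0.080). Indel blocks occur only
#' on the two non-coding loci; the ndhF-rpl32-like mini-barcode carries
#' 6-column diagnostic deletions.
#'
#' @param seed Integer master seed.
#' @return A [sim_config()].
#' @export
demo_library_config <- function(seed = 1) {
  sim_config(
    n_species = 6,
    samples_per_species = c(11, 8, 7, 5, 4, 4),
    loci = list(
      locus_config("ITS2", 234,
        inter_depth = 0.080, intra_depth = 0.020,
        indel_rate = 1 / 3, indel_length = 8, recovery_rate = 26 / 39, gc = 0.66
      ),
      locus_config("matK", 239,
        inter_depth = 0.0099, intra_depth = 0.0026,
        recovery_rate = 32 / 39, gc = 0.36
      ),
      locus_config("ndhF-rpl32", 173,
        inter_depth = 0.0091, intra_depth = 0.0045,
        indel_rate = 1 / 3, indel_length = 6, recovery_rate = 35 / 39, gc = 0.27
      ),
      locus_config("rbcL", 350,
        inter_depth = 0.0073, intra_depth = 0.0063,
        recovery_rate = 27 / 39, gc = 0.41
      )
    ),
    seed = seed
  )
}
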
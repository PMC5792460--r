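test_that("site patterns classify transitions, transversions and deletions", {
  expect_equal(
    site_pattern_counts("AAAA", "GACA"),
    list(n_compared = 4, n_transition = 1, n_transversion = 1)
  )
  expect_equal(
    site_pattern_counts("ACGT-A", "ACGTTA"),
    list(n_compared = 5, n_transition = 0, n_transversion = 0)
  )
  expect_equal(
    site_pattern_counts("ACGT", "ACGT"),
    list(n_compared = 4, n_transition = 0, n_transversion = 0)
  )
  # ambiguity codes and missing symbols are deleted pairwise
  expect_equal(site_pattern_counts("ACGT", "RCNT")$n_compared, 2)
  expect_error(site_pattern_counts("ACG", "ACGT"), class = "alignment_error")
})

test_that("K2P and p distances match their closed forms", {
  counts <- list(n_compared = 100, n_transition = 10, n_transversion = 5)
  expect_equal(
    pairwise_distance(counts, "K2P"),
    -0.5 * log(0.75 * sqrt(0.90)),
    tolerance = 1e-9
  )
  expect_equal(pairwise_distance(counts, "p"), 0.15, tolerance = 1e-12)
  # log-domain boundary and low overlap are undefined
  expect_true(is.na(pairwise_distance(
    list(n_compared = 100, n_transition = 50, n_transversion = 0), "K2P"
  )))
  expect_true(is.na(pairwise_distance(
    list(n_compared = 10, n_transition = 0, n_transversion = 0), "K2P"
  )))
  expect_equal(
    pairwise_distance(list(n_compared = 50, n_transition = 0, n_transversion = 0), "K2P"),
    0
  )
})

test_that("the distance matrix agrees with per-pair recomputation", {
  lib <- simulate_library(sim_config(
    3, 3, locus_config("L", 200, inter_depth = 0.08, intra_depth = 0.01),
    seed = 31
  ))
  loc <- lib$loci$L
  for (model in c("K2P", "p")) {
    dm <- distance_matrix(loc, model)
    for (i in 1:(loc$n - 1)) {
      for (j in (i + 1):loc$n) {
        expected <- pairwise_distance(
          site_pattern_counts(loc$seqs[[i]], loc$seqs[[j]]), model
        )
        expect_equal(dm$d[i, j], expected, tolerance = 1e-12)
        expect_equal(dm$d[j, i], dm$d[i, j])
      }
    }
  }
})

test_that("the K2P correction never falls below the p distance", {
  lib <- simulate_library(sim_config(
    4, 2, locus_config("L", 300, inter_depth = 0.1, intra_depth = 0.02),
    seed = 32
  ))
  k <- distance_matrix(lib$loci$L, "K2P")$d
  p <- distance_matrix(lib$loci$L, "p")$d
  ok <- !is.na(k)
  expect_true(all(k[ok] >= p[ok] - 1e-12))
})

test_that("K2P reduces to p for small divergence", {
  lib <- simulate_library(sim_config(
    3, 2, locus_config("L", 2000, inter_depth = 0.008, intra_depth = 0.001),
    seed = 33
  ))
  k <- distance_matrix(lib$loci$L, "K2P")$d
  p <- distance_matrix(lib$loci$L, "p")$d
  small <- !is.na(p) & p <= 0.01
  expect_true(any(small))
  expect_true(all(abs(k[small] - p[small]) < 1e-3))
})

test_that("distances agree with an established K2P implementation", {
  lib <- simulate_library(sim_config(
    4, 3, locus_config("L", 400, inter_depth = 0.07, intra_depth = 0.01),
    seed = 34
  ))
  loc <- lib$loci$L
  dm <- distance_matrix(loc, "K2P", min_overlap = 1)
  bin <- ape::as.DNAbin(strsplit(tolower(loc$seqs), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(dm$d[loc$n, 1], ref[loc$n, 1], tolerance = 1e-9)
  expect_equal(unname(dm$d), unname(ref[rownames(dm$d), colnames(dm$d)]),
    tolerance = 1e-9
  )
})

test_that("identical sequences give an all-zero matrix", {
  loc <- aligned_locus(
    setNames(rep(strrep("ACGT", 10), 3), c("a", "b", "c")), "L"
  )
  dm <- distance_matrix(loc)
  expect_true(all(dm$d == 0))
})

test_that("pairwise summaries route pairs by conspecificity", {
  d <- matrix(0.06, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.01
  d[3, 4] <- d[4, 3] <- 0.01
  diag(d) <- 0
  dm <- make_dm(d, c("a1", "a2", "b1", "b2"))
  specimens <- make_specimens(c("a1", "a2", "b1", "b2"), rep(c("a", "b"), each = 2))
  g <- glance(summarize_pairwise(dm, specimens))
  expect_equal(g$intra_mean, 0.01)
  expect_equal(g$inter_mean, 0.06)
  expect_equal(g$n_intra, 2)
  expect_equal(g$n_inter, 4)
})

test_that("a single-species matrix has no interspecific class", {
  d <- matrix(0.01, 3, 3)
  diag(d) <- 0
  dm <- make_dm(d, c("a1", "a2", "a3"))
  specimens <- make_specimens(c("a1", "a2", "a3"), rep("a", 3))
  g <- glance(summarize_pairwise(dm, specimens))
  expect_equal(g$n_inter, 0)
  expect_true(is.na(g$inter_mean))
  expect_error(barcoding_gap(summarize_pairwise(dm, specimens)),
    class = "insufficient_data"
  )
})

test_that("gap fractions use strict inequalities at the cutoff", {
  g1 <- barcoding_gap(fake_summary(c(0.01, 0.02), c(0.06, 0.07)), cutoff = 0.05)
  expect_equal(g1$frac_inter_above, 100)
  expect_equal(g1$frac_intra_below, 100)
  expect_false(g1$overlap)

  g2 <- barcoding_gap(fake_summary(0.06, 0.04), cutoff = 0.05)
  expect_equal(g2$frac_inter_above, 0)
  expect_equal(g2$frac_intra_below, 0)
  expect_true(g2$overlap)

  # values at the cutoff count on neither side
  g3 <- barcoding_gap(fake_summary(c(0.05, 0.01), c(0.05, 0.1)), cutoff = 0.05)
  expect_equal(g3$frac_inter_above, 50)
  expect_equal(g3$frac_intra_below, 50)
})

test_that("gap fractions equal direct counting on random distance lists", {
  for (s in 1:5) {
    set.seed(400 + s)
    intra <- runif(40, 0, 0.08)
    inter <- runif(60, 0.02, 0.2)
    g <- barcoding_gap(fake_summary(intra, inter), cutoff = 0.05)
    expect_equal(g$frac_inter_above, 100 * sum(inter > 0.05) / 60)
    expect_equal(g$frac_intra_below, 100 * sum(intra < 0.05) / 40)
    expect_equal(g$overlap, max(intra) >= min(inter))
    expect_equal(sum(g$histogram$intra), 40)
    expect_equal(sum(g$histogram$inter), 60)
  }
})

test_that("undefined pairs are excluded from summaries but counted", {
  d <- matrix(0.05, 3, 3)
  diag(d) <- 0
  d[1, 3] <- d[3, 1] <- NA
  dm <- make_dm(d, c("a1", "a2", "b1"))
  specimens <- make_specimens(c("a1", "a2", "b1"), c("a", "a", "b"))
  s <- summarize_pairwise(dm, specimens)
  expect_equal(s$n_undefined, 1)
  expect_equal(glance(s)$n_inter, 1)
})
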
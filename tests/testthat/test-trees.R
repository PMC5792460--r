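additive_dm <- function() {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3
  d["A", "C"] <- 5
  d["A", "D"] <- 6
  d["B", "C"] <- 6
  d["B", "D"] <- 7
  d["C", "D"] <- 7
  d <- d + t(d)
  make_dm(d, LETTERS[1:4])
}

test_that("NJ recovers the additive four-taxon tree exactly", {
  tree <- neighbor_joining(additive_dm())
  expect_equal(ape::Ntip(tree), 4)
  expect_equal(nrow(tree$edge), 2 * 4 - 3)
  # the unique realizing tree: AB|CD, leaf edges 1,2,3,4, internal edge 1
  paths <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(paths), unname(additive_dm()$d), tolerance = 1e-9)
  tip_edge <- function(lab) {
    tree$edge.length[tree$edge[, 2] == which(tree$tip.label == lab)]
  }
  expect_equal(vapply(LETTERS[1:4], tip_edge, numeric(1)),
    c(A = 1, B = 2, C = 3, D = 4),
    tolerance = 1e-9
  )
  internal <- tree$edge[, 2] > ape::Ntip(tree)
  expect_equal(tree$edge.length[internal], 1, tolerance = 1e-9)
})

test_that("three taxa are solved in closed form", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(make_dm(d, c("a", "b", "c")))
  tip_edge <- function(lab) {
    tree$edge.length[tree$edge[, 2] == which(tree$tip.label == lab)]
  }
  expect_equal(tip_edge("a"), 1, tolerance = 1e-9)
  expect_equal(tip_edge("b"), 2, tolerance = 1e-9)
  expect_equal(tip_edge("c"), 4, tolerance = 1e-9)
})

test_that("incomplete or tiny matrices are refused", {
  d <- additive_dm()$d
  d[1, 2] <- d[2, 1] <- NA
  expect_error(neighbor_joining(make_dm(d, LETTERS[1:4])), class = "incomplete_matrix")
  expect_error(neighbor_joining(make_dm(matrix(0, 2, 2), c("a", "b"))),
    class = "insufficient_taxa"
  )
})

test_that("pruning removes the specimens with most undefined entries", {
  d <- matrix(0.05, 4, 4)
  diag(d) <- 0
  d[1, 3] <- d[3, 1] <- NA
  d[1, 4] <- d[4, 1] <- NA
  dm <- make_dm(d, c("bad", "x", "y", "z"))
  pruned <- suppressMessages(prune_undefined(dm))
  expect_equal(pruned$ids, c("x", "y", "z"))
  expect_equal(attr(pruned, "pruned"), "bad")
})

test_that("NJ on exact path-length matrices recovers the generating topology", {
  for (s in 1:5) {
    n <- sample(6:10, 1)
    tr <- build_species_tree(n, 0.05, seed = 600 + s)
    d <- ape::cophenetic.phylo(tr)
    rec <- neighbor_joining(make_dm(d[tr$tip.label, tr$tip.label], tr$tip.label))
    expect_equal(phangorn::RF.dist(rec, tr), 0)
  }
})

test_that("a clean species split gets near-certain bootstrap support", {
  base <- strrep("ACGT", 50)
  flip <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- ifelse(ch[pos] == "A", "G", "A")
    paste(ch, collapse = "")
  }
  other <- Reduce(flip, seq(1, 200, by = 4), base) # 50 fixed differences
  seqs <- c(
    a1 = base, a2 = flip(base, 2), a3 = flip(base, 6), a4 = flip(base, 10),
    b1 = other, b2 = flip(other, 3), b3 = flip(other, 7), b4 = flip(other, 11)
  )
  loc <- aligned_locus(seqs, "L")
  tree <- bootstrap_support(loc, model = "p", n_reps = 100, seed = 42)
  specimens <- make_specimens(names(seqs), rep(c("sp_a", "sp_b"), each = 4))
  disc <- label_clusters(tree, specimens)
  sup <- disc$table$support[disc$table$label == "sp_a"]
  expect_gte(sup, 95)
  # determinism under the seed
  tree2 <- bootstrap_support(loc, model = "p", n_reps = 100, seed = 42)
  expect_identical(tree$node.label, tree2$node.label)
})

test_that("identical sequences yield zero support everywhere", {
  seqs <- setNames(rep(strrep("ACGT", 30), 5), paste0("s", 1:5))
  tree <- bootstrap_support(aligned_locus(seqs, "L"), n_reps = 50, seed = 1)
  expect_true(all(tree$node.label[!is.na(tree$node.label)] == 0))
})

test_that("the discrimination criterion needs exclusivity and a voucher", {
  tree <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1);")
  specimens <- make_specimens(c("A1", "A2", "B1", "B2"), rep(c("a", "b"), each = 2))
  res <- label_clusters(tree, specimens)
  expect_equal(res$overall_rate, 100)
  expect_true(all(res$table$discriminated))

  mixed <- ape::read.tree(text = "((A1:1,B1:1):1,(A2:1,B2:1):1);")
  res2 <- label_clusters(mixed, specimens)
  expect_equal(res2$overall_rate, 0)
  expect_false(any(res2$table$is_exclusive))

  no_voucher <- make_specimens(c("A1", "A2", "B1", "B2"),
    rep(c("a", "b"), each = 2),
    vouchered = c(FALSE, FALSE, TRUE, TRUE)
  )
  res3 <- label_clusters(tree, no_voucher)
  tab <- res3$table
  expect_true(tab$is_exclusive[tab$label == "a"])
  expect_false(tab$discriminated[tab$label == "a"])
  expect_true(tab$discriminated[tab$label == "b"])
  expect_equal(res3$overall_rate, 50)
})

test_that("monophyly scoring matches brute-force edge removal", {
  for (s in 1:10) {
    n <- sample(5:12, 1)
    tr <- withr::with_seed(700 + s, ape::rtopology(n, rooted = FALSE))
    tr$edge.length <- rep(1, nrow(tr$edge))
    labs <- withr::with_seed(800 + s, sample(letters[1:3], n, replace = TRUE))
    specimens <- make_specimens(tr$tip.label, labs)
    res <- label_clusters(tr, specimens)
    splits <- edge_splits_bruteforce(tr)
    for (lb in unique(labs)) {
      ids <- tr$tip.label[labs == lb]
      brute <- any(vapply(splits, function(side) {
        setequal(side, ids) || setequal(setdiff(tr$tip.label, side), ids)
      }, logical(1)))
      expect_equal(
        res$table$is_exclusive[res$table$label == lb], brute,
        info = paste("seed", s, "label", lb)
      )
      if (length(ids) >= 2 && length(ids) < n) {
        expect_equal(brute, ape::is.monophyletic(tr, ids))
      }
    }
  }
})

test_that("cluster scoring is invariant to leaf order and rerooting", {
  tr <- ape::read.tree(text = "((A1:1,A2:1):1,((B1:1,B2:1):1,(C1:1,C2:1):2):1);")
  specimens <- make_specimens(
    c("A1", "A2", "B1", "B2", "C1", "C2"),
    rep(c("a", "b", "c"), each = 2)
  )
  base <- label_clusters(tr, specimens)
  rot <- label_clusters(ape::rotateConstr(tr, rev(tr$tip.label)), specimens)
  rer <- label_clusters(ape::unroot(ape::root(tr, "B1")), specimens)
  base_tab <- dplyr::arrange(base$table, label)
  expect_equal(dplyr::arrange(rot$table, label), base_tab)
  expect_equal(dplyr::arrange(rer$table, label), base_tab)
})

test_that("region labels reuse the same criterion", {
  tree <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1);")
  specimens <- make_specimens(c("A1", "A2", "B1", "B2"),
    c("a", "a", "b", "b"),
    region = c("Asia", "Asia", "Africa", "Africa")
  )
  res <- label_clusters(tree, specimens, label_field = "region")
  expect_equal(res$overall_rate, 100)
})

test_that("newick output honours the negative-length clamp flag", {
  tr <- ape::read.tree(text = "((a:1,b:-0.5):1,(c:1,d:1):1);")
  raw <- write_newick(tr)
  expect_match(raw, "-0.5")
  clamped <- write_newick(tr, clamp_negative = TRUE)
  expect_false(grepl("-0.5", clamped))
  expect_match(raw, ";$")
})
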
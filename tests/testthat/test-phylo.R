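test_that("pairwise distances: identity, hand computation, gap handling", {
  rows <- c(a = "MRRE", b = "MRRE", c = "WWWW")
  d <- pairwise_distance(rows, min_shared = 2)
  expect_equal(d["a", "b"], 0)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  # hand-computed delta for a 2-residue pair: delta(a,b) =
  # (max(s(aa),s(bb)) - s(ab)) / (max(s(aa),s(bb)) + 8)
  m <- bhlhscan:::pam250_matrix()
  dAR <- (max(m["A", "A"], m["R", "R"]) - m["A", "R"]) /
    (max(m["A", "A"], m["R", "R"]) + 8)
  dNE <- (max(m["N", "N"], m["E", "E"]) - m["N", "E"]) /
    (max(m["N", "N"], m["E", "E"]) + 8)
  d2 <- pairwise_distance(c(x = "AN", y = "RE"), min_shared = 2)
  expect_equal(d2["x", "y"], mean(c(dAR, dNE)))

  # rows sharing no ungapped columns: error
  expect_error(pairwise_distance(c(a = "AA--", b = "--RR", c = "AARR"),
                                 min_shared = 2), "share fewer")
  # gap columns are skipped pairwise
  d3 <- pairwise_distance(c(a = "AN-", b = "AN-", c = "ANA"), min_shared = 2)
  expect_equal(d3["a", "b"], 0)
})

test_that("neighbor joining: three-point formulas, additive recovery", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")

  # NJ is consistent on additive matrices (quick check; the acceptance
  # suite runs the full 100-tree version)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- stats::runif(length(true$edge.length), 0.1, 1)
    dmat <- ape::cophenetic.phylo(true)
    rec <- nj_tree(dmat[true$tip.label, true$tip.label])
    expect_equal(ape::dist.topo(rec, true), 0, ignore_attr = TRUE)
  }

  # duplicate taxa rows produce a zero-length cherry
  rows <- c(a = "ARNDARNDARND", b = "ARNDARNDARND", c = "DNRADNRADNRA",
            d = "NNNNRRRRDDDD")
  d4 <- pairwise_distance(rows)
  t4 <- nj_tree(d4)
  mrca <- ape::getMRCA(t4, c("a", "b"))
  kids <- t4$edge[t4$edge[, 1] == mrca, 2]
  expect_setequal(t4$tip.label[kids], c("a", "b"))
  expect_equal(sum(t4$edge.length[t4$edge[, 2] %in% kids]), 0)
})

test_that("Fitch score agrees with the set-recursion oracle", {
  rows <- c(t1 = "A", t2 = "A", t3 = "C", t4 = "C")
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  expect_identical(fitch_score(tr, rows), 1L)
  expect_identical(fitch_score(tr, c(t1 = "AAA", t2 = "AAA", t3 = "AAA",
                                     t4 = "AAA")), 0L)
  set.seed(9)
  for (i in 1:15) {
    n <- sample(4:6, 1)
    rows <- random_rows(n, 12, gap_frac = if (i %% 3 == 0) 0.1 else 0)
    tr <- ape::rtree(n, rooted = FALSE, tip.label = names(rows))
    expect_identical(fitch_score(tr, rows), oracle_fitch(tr, rows))
  }
})

test_that("parsimony search reaches the optimum on small instances", {
  set.seed(21)
  hits <- 0
  for (i in 1:12) {
    rows <- evolved_rows(6, 30)
    trees <- phangorn::allTrees(6, rooted = FALSE, tip.label = names(rows))
    all_scores <- vapply(trees, fitch_score, integer(1), rows = rows)
    opt <- min(all_scores)
    got <- attr(mp_search(rows), "pscore")
    expect_gte(got, opt)
    if (got == opt) hits <- hits + 1
  }
  # on phylogenetically structured data NNI hill-climbing almost always
  # reaches the optimum (its gap on structureless data is documented)
  expect_gte(hits, 11)

  # an instance whose NJ tree is already optimal stays unchanged
  rows <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC", c = "RRRRRRRRRR",
            d = "RRRRRRRRRN")
  tr <- mp_search(rows)
  mrca <- ape::getMRCA(tr, c("a", "b"))
  kids <- tr$edge[tr$edge[, 1] == mrca, 2]
  expect_setequal(tr$tip.label[kids[kids <= 4]], c("a", "b"))
})

test_that("bootstrap supports a clean split at 100 and validates reps", {
  # two identical blocks with a clean 2-vs-2 signal
  rows <- c(a = strrep("AR", 10), b = strrep("AR", 10),
            c = strrep("RN", 10), d = strrep("RN", 10))
  tr <- bootstrap_support(rows, "nj", reps = 50, seed = 3)
  sets <- bhlhscan:::node_tip_sets(tr)
  k <- which(vapply(sets, function(s)
    identical(s, c("a", "b")) || identical(s, c("c", "d")), logical(1)))
  expect_true(length(k) >= 1)
  expect_true(all(tr$node.label[k] == 100))
  expect_error(bootstrap_support(rows, "nj", reps = 0), "positive")

  # supports lie in [0,100] and are seed-stable within a few points
  rs <- test_refset()
  rows2 <- rs$alignment[c("ase", "sc", "lsc", "ac", "nau", "da", "OsRa")]
  t1 <- bootstrap_support(rows2, "nj", reps = 200, seed = 1)
  t2 <- bootstrap_support(rows2, "nj", reps = 200, seed = 99)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 100, na.rm = TRUE))
  s1 <- sort(t1$node.label[!is.na(t1$node.label)])
  s2 <- sort(t2$node.label[!is.na(t2$node.label)])
  expect_true(all(abs(s1 - s2) <= 8))
  # determinism under the same seed
  t3 <- bootstrap_support(rows2, "nj", reps = 200, seed = 1)
  expect_identical(t1$node.label, t3$node.label)
})

test_that("outgroup rooting preserves supports and is idempotent", {
  tr <- ape::read.tree(text = "((A,B),(C,Out));")
  rt <- root_with_outgroup(tr, "Out")
  expect_true(ape::is.rooted(rt))
  sets <- bhlhscan:::node_tip_sets(rt)
  expect_true(any(vapply(sets, identical, logical(1), y = c("A", "B", "C"))))
  expect_error(root_with_outgroup(tr, "nope"), "not in tree")

  # supports survive rooting and re-rooting is structurally idempotent
  rows <- c(a = strrep("AR", 10), b = strrep("AR", 10),
            c = strrep("RN", 10), d = strrep("RN", 10),
            out = strrep("WC", 10))
  bt <- bootstrap_support(rows, "nj", reps = 50, seed = 2)
  r1 <- root_with_outgroup(bt, "out")
  cs <- clade_support(r1, c("a", "b"))
  expect_true(cs$monophyletic)
  expect_equal(cs$support, 100)
  r2 <- root_with_outgroup(r1, "out")
  expect_equal(ape::dist.topo(ape::unroot(r1), ape::unroot(r2)), 0,
               ignore_attr = TRUE)
  expect_identical(clade_support(r2, c("a", "b"))$support, cs$support)
})

test_that("clade support equals the edge-enumeration oracle", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(5:9, 1)
    tr <- ape::rtree(n)
    tr$node.label <- c(NA, round(stats::runif(tr$Nnode - 1, 0, 100)))
    # all pairs plus a few random subsets
    tips <- tr$tip.label
    sets <- c(utils::combn(tips, 2, simplify = FALSE),
              list(sample(tips, 3), tips))
    for (s in sets) {
      got <- clade_support(tr, s)
      want <- oracle_clade_support(tr, s)
      expect_identical(got$monophyletic, want$monophyletic)
      if (got$monophyletic) expect_equal(got$support, want$support)
    }
  }
  # the full leaf set is never reported monophyletic
  tr5 <- ape::rtree(5)
  expect_false(clade_support(tr5, tr5$tip.label)$monophyletic)
})
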
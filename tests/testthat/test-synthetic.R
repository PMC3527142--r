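test_that("mutate_motif respects rate, protection, and determinism", {
  ref <- bhlhscan:::BHLH_CONSENSUS
  expect_identical(mutate_motif(ref, 0, seed = 1), ref)
  expect_error(mutate_motif(ref, 1), "subst_rate")

  sites <- bhlhscan:::BHLH_CONSERVED_POSITIONS
  m <- mutate_motif(ref, 0.5, protect_conserved = TRUE,
                    site_positions = sites, seed = 4)
  ref_ch <- strsplit(ref, "")[[1]]
  m_ch <- strsplit(m, "")[[1]]
  expect_identical(m_ch[sites], ref_ch[sites])

  expect_identical(mutate_motif(ref, 0.3, seed = 7),
                   mutate_motif(ref, 0.3, seed = 7))
  expect_false(identical(mutate_motif(ref, 0.3, seed = 7),
                         mutate_motif(ref, 0.3, seed = 8)))
})

test_that("mutation rate matches expected Hamming distance (Monte Carlo)", {
  ref <- bhlhscan:::BHLH_CONSENSUS
  rate <- 0.1
  n <- 1000
  ref_ch <- strsplit(ref, "")[[1]]
  d <- vapply(seq_len(n), function(s) {
    sum(strsplit(mutate_motif(ref, rate, protect_conserved = FALSE,
                              seed = s), "")[[1]] != ref_ch)
  }, numeric(1))
  expected <- rate * nchar(ref)
  se <- sqrt(nchar(ref) * rate * (1 - rate) / n)
  expect_lt(abs(mean(d) - expected), 3 * se)
})

test_that("synthesize_contig plants recoverable gene structures", {
  motif <- bhlhscan:::BHLH_CONSENSUS
  # no introns: one segment, exact translation
  sim0 <- synthesize_contig(motif, strand = "+", seed = 3)
  expect_identical(nrow(sim0$truth$segments), 1L)
  expect_identical(bhlhscan:::splice_translate(sim0$truth, sim0$contig), motif)

  # one basic intron of 805 bp, as in the repertoire table
  sim1 <- synthesize_contig(motif, 805L, "basic", strand = "+", seed = 3)
  expect_identical(sim1$truth$introns$region, "basic")
  expect_identical(sim1$truth$introns$length_bp, 805L)
  expect_identical(bhlhscan:::splice_translate(sim1$truth, sim1$contig), motif)
  # canonical ends
  ct <- sim1$contig[[1]]
  s1 <- sim1$truth$segments
  expect_identical(substring(ct, s1$end[1] + 1, s1$end[1] + 2), "GT")
  expect_identical(substring(ct, s1$start[2] - 2, s1$start[2] - 1), "AG")

  # minus strand: splice-then-translate still recovers the motif
  sim2 <- synthesize_contig(motif, c(120L, 500L), c("basic", "loop"),
                            strand = "-", seed = 9)
  expect_identical(sim2$truth$strand, "-")
  expect_identical(bhlhscan:::splice_translate(sim2$truth, sim2$contig), motif)
  expect_true(all(diff(sim2$truth$segments$start) < 0))

  expect_error(synthesize_contig(motif, 3L, "loop", seed = 1), ">= 4")
})

test_that("benchmark generation is reproducible and carries truth", {
  rs <- test_refset()
  b1 <- make_benchmark(rs, n_genes = 4, subst_rate = 0.05, seed = 21)
  b2 <- make_benchmark(rs, n_genes = 4, subst_rate = 0.05, seed = 21)
  expect_identical(b1$contigs, b2$contigs)
  expect_identical(b1$truth_table, b2$truth_table)
  expect_identical(nrow(b1$truth_table), 4L)
  expect_true(b1$decoy_contig %in% names(b1$contigs))
  # every truth model splices back to its recorded motif
  for (g in names(b1$truth)) {
    tr <- b1$truth[[g]]
    expect_identical(bhlhscan:::splice_translate(tr, b1$contigs), tr$motif_aa)
  }
  b3 <- make_benchmark(rs, n_genes = 4, subst_rate = 0.05, seed = 22)
  expect_false(identical(b1$contigs, b3$contigs))
})

test_that("decoy motif fails the conserved-site statistic by construction", {
  rs <- test_refset()
  spec <- derive_site_spec(rs)
  bm <- make_benchmark(rs, n_genes = 2, subst_rate = 0.05, seed = 5)
  prof <- build_profile(rs)
  row75 <- align_to_profile(bm$decoy_motif, prof)$row75
  sc <- score_conserved_sites(row75, spec)
  expect_lt(sc$matches, 10)
})
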
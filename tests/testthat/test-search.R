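test_that("six-frame translation covers both strands at all offsets", {
  fr <- six_frame_translate("ATGGCC")
  expect_identical(unname(fr["+1"]), "MA")
  # revcomp of ATGGCC is GGCCAT -> GH
  expect_identical(unname(fr["-1"]), "GH")
  fr7 <- six_frame_translate("ATGGCCA")
  for (k in 1:3) {
    expect_identical(nchar(fr7[[paste0("+", k)]]), (7L - (k - 1L)) %/% 3L)
    expect_identical(nchar(fr7[[paste0("-", k)]]), (7L - (k - 1L)) %/% 3L)
  }
  expect_identical(unname(six_frame_translate("ATGTAA")["+1"]), "M*")
})

test_that("local alignment matches PAM250 on identities and the oracle on
           random pairs", {
  m <- bhlhscan:::pam250_matrix()
  al <- local_align("RRE", "RRE")
  expect_equal(al$score, m["R", "R"] * 2 + m["E", "E"])
  expect_identical(c(al$q_start, al$q_end), c(1L, 3L))

  # no positive-scoring pair
  al0 <- local_align("W", "P")
  expect_identical(al0$score, 0)

  set.seed(42)
  for (i in 1:25) {
    q <- paste(sample(bhlhscan:::AA20, 12, TRUE), collapse = "")
    t <- paste(sample(bhlhscan:::AA20, 12, TRUE), collapse = "")
    expect_equal(local_align(q, t)$score, oracle_local_score(q, t),
                 info = paste(q, t))
  }
})

test_that("scan finds planted motifs, maps coordinates, ignores noise", {
  rs <- test_refset()
  cfg <- bhlh_config(seed = 2)
  motif <- gsub("-", "", rs$alignment[["twi"]])
  sim <- synthesize_contig(motif, strand = "-", flank_len = 300, seed = 8,
                           contig_id = "c1")
  hits <- scan_genome(rs, sim$contig, cfg)
  expect_gt(nrow(hits), 0)
  top <- hits[which.max(hits$score), ]
  expect_identical(top$query, "twi")
  expect_identical(top$strand, "-")
  # coordinate round-trip: re-translating the genomic span gives the hit
  sub <- substring(sim$contig[[1]], min(top$g_start, top$g_end),
                   max(top$g_start, top$g_end))
  aa <- bhlhscan:::translate_dna(bhlhscan:::revcomp(sub))
  expect_identical(aa, substring(motif, top$q_start, top$q_end))
  # exact planted motif attains its self-score
  expect_equal(top$score, bhlhscan:::pam_self_score(motif))

  # random DNA yields nothing at a high threshold
  set.seed(1)
  junk <- stats::setNames(paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                                collapse = ""), "junk")
  cfg_hi <- bhlh_config(anchor_min_frac = 0.6, secondary_min_score = 60,
                        seed = 2)
  expect_identical(nrow(scan_genome(rs, junk, cfg_hi)), 0L)
  # empty contig set is an empty result, not an error
  expect_identical(nrow(scan_genome(rs, character(0), cfg)), 0L)
})

test_that("hit deduplication collapses, merges, and is idempotent", {
  h <- function(contig, frame, g1, g2, score, query, strand = "+")
    data.frame(contig = contig, frame = frame, query = query, score = score,
               q_start = 1L, q_end = 10L, t_start = 1L, t_end = 10L,
               g_start = g1, g_end = g2, strand = strand)
  # identical span, two queries -> one hit (best score wins)
  hits <- rbind(h("c1", "+1", 10, 39, 100, "b"), h("c1", "+1", 10, 39, 90, "a"))
  dd <- deduplicate_hits(hits)
  expect_identical(nrow(dd), 1L)
  expect_identical(dd$query, "b")
  # same span, tie score -> first query alphabetically
  hits2 <- rbind(h("c1", "+1", 10, 39, 90, "b"), h("c1", "+1", 10, 39, 90, "a"))
  expect_identical(deduplicate_hits(hits2)$query, "a")
  # identical span on different contigs -> kept apart
  hits3 <- rbind(h("c1", "+1", 10, 39, 90, "a"), h("c2", "+1", 10, 39, 90, "a"))
  expect_identical(nrow(deduplicate_hits(hits3)), 2L)
  # 90% overlap -> union span
  hits4 <- rbind(h("c1", "+1", 10, 109, 90, "a"), h("c1", "+1", 20, 119, 80, "b"))
  dd4 <- deduplicate_hits(hits4)
  expect_identical(nrow(dd4), 1L)
  expect_identical(c(dd4$g_start, dd4$g_end), c(10, 119))
  # idempotence
  expect_identical(deduplicate_hits(dd4), dd4)
})

test_that("in-frame extension completes truncated hits and respects edges", {
  rs <- test_refset()
  cfg <- bhlh_config(seed = 3)
  motif <- gsub("-", "", rs$alignment[["da"]])
  sim <- synthesize_contig(motif, strand = "+", flank_len = 200, seed = 12,
                           contig_id = "c1")
  hits <- scan_genome(rs, sim$contig, cfg)
  top <- hits[hits$query == "da", ][1, ]
  # truncate the hit by 4 N-terminal residues; extension must restore them
  trunc <- top
  trunc$q_start <- trunc$q_start + 4L
  trunc$g_start <- trunc$g_start + 12L
  cand <- extend_motif(trunc, sim$contig[[1]], motif, cfg)
  expect_true(cand$complete)
  expect_identical(cand$motif_aa, motif)
  expect_identical(cand$gene_model$segments$start,
                   sim$truth$segments$start)

  # hit at the contig edge cannot complete: flag retained
  short <- substring(sim$contig[[1]], sim$truth$segments$start[1] + 9L)
  hits2 <- scan_genome(rs, stats::setNames(short, "c2"), cfg)
  top2 <- hits2[hits2$query == "da", ][1, ]
  cand2 <- extend_motif(top2, short, motif, cfg)
  expect_false(cand2$complete)
})

test_that("splice-aware joining recovers planted introns exactly", {
  rs <- test_refset()
  cfg <- bhlh_config(seed = 5)
  motif <- gsub("-", "", rs$alignment[["Mitf"]])

  sim1 <- synthesize_contig(motif, 805L, "basic", strand = "+", seed = 31,
                            contig_id = "c1")
  hits1 <- deduplicate_hits(scan_genome(rs, sim1$contig, cfg))
  hits1 <- hits1[hits1$query == "Mitf" & hits1$strand == "+", , drop = FALSE]
  hits1 <- utils::head(hits1[order(-hits1$score), ], 2)
  cand1 <- join_split_motif(hits1, sim1$contig,
                            stats::setNames(motif, "Mitf"), cfg)
  expect_identical(cand1$gene_model$introns$length_bp, 805L)
  expect_identical(cand1$motif_aa, motif)

  sim2 <- synthesize_contig(motif, c(700L, 1500L), c("basic", "loop"),
                            strand = "+", seed = 33, contig_id = "c1")
  hits2 <- deduplicate_hits(scan_genome(rs, sim2$contig, cfg))
  hits2 <- hits2[hits2$query == "Mitf" & hits2$strand == "+", , drop = FALSE]
  hits2 <- utils::head(hits2[order(-hits2$score), ], 3)
  cand2 <- join_split_motif(hits2, sim2$contig,
                            stats::setNames(motif, "Mitf"), cfg)
  expect_identical(sort(cand2$gene_model$introns$length_bp), c(700L, 1500L))
  expect_identical(cand2$gene_model$segments[, c("start", "end")],
                   sim2$truth$segments[, c("start", "end")])
})

test_that("hits on two contigs join into a split-flagged candidate", {
  rs <- test_refset()
  cfg <- bhlh_config(seed = 6)
  motif <- gsub("-", "", rs$alignment[["crp"]])
  sim <- synthesize_contig(motif, 2000L, "loop", strand = "+", seed = 41,
                           contig_id = "cA")
  # cut the contig inside the intron: the two coding regions now sit on
  # separate contigs, as for the two split genes of the repertoire
  cut <- sim$truth$segments$end[1] + 900L
  ctgs <- c(cA = substring(sim$contig[[1]], 1, cut),
            cB = substring(sim$contig[[1]], cut + 1))
  hits <- deduplicate_hits(scan_genome(rs, ctgs, cfg))
  hits <- hits[hits$query == "crp" & hits$strand == "+", , drop = FALSE]
  # best hit per contig
  hits <- do.call(rbind, lapply(split(hits, hits$contig),
                                function(h) h[which.max(h$score), ]))
  expect_identical(sort(unique(hits$contig)), c("cA", "cB"))
  cand <- join_split_motif(hits, ctgs, stats::setNames(motif, "crp"), cfg)
  expect_true(cand$gene_model$split_across_contigs)
  expect_identical(cand$motif_aa, motif)
  expect_true(any(is.na(cand$gene_model$introns$length_bp)))
})

test_that("pseudogene-like stop interruption is flagged, not dropped", {
  rs <- test_refset()
  cfg <- bhlh_config(seed = 8)
  motif <- gsub("-", "", rs$alignment[["crp"]])
  sim <- synthesize_contig(motif, strand = "+", flank_len = 200, seed = 13,
                           contig_id = "c1")
  ct <- sim$contig[[1]]
  # overwrite the codons of motif positions 6-7 with stop codons
  s0 <- sim$truth$segments$start[1]
  substring(ct, s0 + 15L, s0 + 20L) <- "TAATGA"
  hits <- deduplicate_hits(scan_genome(rs, stats::setNames(ct, "c1"), cfg))
  cands <- bhlhscan:::assemble_candidates(hits, stats::setNames(ct, "c1"),
                                          rs, cfg)
  expect_gt(length(cands), 0)
  expect_true(any(vapply(cands, `[[`, logical(1), "stop_blocked")))
})
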
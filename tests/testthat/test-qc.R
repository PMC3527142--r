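test_that("site spec derivation finds the 19 invariant columns", {
  rs <- test_refset()
  spec <- derive_site_spec(rs)
  expect_length(spec$positions, 19)
  expect_true(all(diff(spec$positions) > 0))
  expect_identical(spec$minima[["default"]], 10L)
  # positions 23 and 64 are among the conserved sites
  expect_true(all(c(23L, 64L) %in% spec$positions))
  # YAML round-trip
  p <- withr::local_tempfile(fileext = ".yaml")
  write_site_spec(spec, p)
  back <- read_site_spec(p)
  expect_identical(back$positions, spec$positions)
  expect_identical(back$accepted, spec$accepted)
})

test_that("conserved-site scoring counts matches and applies thresholds", {
  rs <- test_refset()
  spec <- derive_site_spec(rs)
  cons <- strsplit(bhlhscan:::BHLH_CONSENSUS, "")[[1]]

  full <- score_conserved_sites(cons, spec)
  expect_identical(full$matches, 19L)
  expect_true(full$accepted)

  allW <- score_conserved_sites(rep("W", 75), spec)
  expect_identical(allW$matches, 0L)
  expect_false(allW$accepted)

  # exactly-threshold cases: engineer rows with a given number of matches
  k_matches <- function(k) {
    row <- rep("-", 75)
    for (p in spec$positions[seq_len(k)])
      row[p] <- spec$accepted[[as.character(p)]][1]
    row
  }
  expect_true(score_conserved_sites(k_matches(10), spec, 10L)$accepted)
  expect_false(score_conserved_sites(k_matches(9), spec, 10L)$accepted)

  expect_error(score_conserved_sites(c("A", "R"), spec), "profile-aligned")

  # monotonicity: adding a matching residue never decreases matches
  for (k in 0:18)
    expect_lte(score_conserved_sites(k_matches(k), spec)$matches,
               score_conserved_sites(k_matches(k + 1), spec)$matches)
})

test_that("qc_filter chooses class thresholds and partitions input", {
  rs <- test_refset()
  spec <- derive_site_spec(rs)
  mk <- function(k, cls = "default") {
    row <- rep("-", 75)
    for (p in spec$positions[seq_len(k)])
      row[p] <- spec$accepted[[as.character(p)]][1]
    list(row75 = row, family_class = cls)
  }
  cands <- list(ten = mk(10), nine = mk(9), emc6 = mk(6, "Emc"),
                emc4 = mk(4, "Emc"), coe8 = mk(8, "COE"),
                coe7 = mk(7, "COE"))
  out <- qc_filter(cands, spec)
  expect_setequal(names(out$accepted), c("ten", "emc6", "coe8"))
  expect_setequal(names(out$rejected), c("nine", "emc4", "coe7"))
  expect_match(out$rejected$nine$reason, "9 < 10")
  # partition: nothing lost, nothing duplicated
  expect_setequal(c(names(out$accepted), names(out$rejected)), names(cands))

  empty <- qc_filter(list(), spec)
  expect_length(empty$accepted, 0)
  expect_length(empty$rejected, 0)
})

test_that("protected mutation keeps acceptance at 100% at any rate", {
  rs <- test_refset()
  spec <- derive_site_spec(rs)
  prof <- build_profile(rs)
  dm_ids <- rs$entries$id[rs$entries$species == "Dm"]
  set.seed(33)
  for (i in 1:10) {
    id <- sample(dm_ids, 1)
    mut <- mutate_motif(rs$alignment[[id]], 0.30, protect_conserved = TRUE,
                        site_positions = spec$positions, seed = i)
    row <- align_to_profile(gsub("-", "", mut), prof)$row75
    thr <- switch(rs$entries$family[match(id, rs$entries$id)],
                  Emc = 5L, COE = 8L, 10L)
    expect_true(score_conserved_sites(row, spec, thr)$accepted, label = id)
  }
})

test_that("region assignment partitions the motif and labels endpoints", {
  expect_identical(assign_regions(1L), "basic")
  expect_identical(assign_regions(75L), "helix2")
  expect_identical(assign_regions(c(13L, 14L, 28L, 29L, 59L, 60L)),
                   c("basic", "helix1", "helix1", "loop", "loop", "helix2"))
  expect_error(assign_regions(76L), "outside")
})
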
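# Helpers to fabricate per-method in-group results for tier-rule tests.
res_entry <- function(partner, support, mono = TRUE)
  list(partner = partner, support = support, monophyletic = mono,
       tie = FALSE)
mk_results <- function(..., species = "Dm") {
  r <- list(...)
  attr(r, "species") <- species
  r
}

test_that("tier rules follow the published decision procedure", {
  rs <- test_refset()
  # all methods >= 50, same partner -> tier 1 (PaCrp1-style 100/100/94)
  r1 <- mk_results(nj = res_entry("crp", 100), mp = res_entry("crp", 100),
                   ml = res_entry("crp", 94))
  c1 <- assign_orthology(r1, rs, candidate_id = "x")
  expect_identical(c1$tier, 1L)
  expect_identical(c1$family, "AP4")
  expect_identical(c1$group, "B")

  # one method below 50 but monophyletic -> tier 2 (PaTwi2-style 63/43/73)
  r2 <- mk_results(nj = res_entry("twi", 63), mp = res_entry("twi", 43),
                   ml = res_entry("twi", 73))
  expect_identical(assign_orthology(r2, rs, candidate_id = "x")$tier, 2L)

  # monophyly in some methods, n/m in others -> tier 3 (PaHey-style 98/45/n/m)
  r3 <- mk_results(nj = res_entry("Hey", 98), mp = res_entry("Hey", 45),
                   ml = res_entry(NA_character_, NA_real_, mono = FALSE))
  c3 <- assign_orthology(r3, rs, candidate_id = "x")
  expect_identical(c3$tier, 3L)
  expect_identical(c3$family, "Hey")

  # no monophyly anywhere, fallback resolves -> tier 4 with sub-tier
  rnm <- mk_results(nj = res_entry(NA_character_, NA_real_, FALSE),
                    mp = res_entry(NA_character_, NA_real_, FALSE))
  fb <- function() mk_results(nj = res_entry("Am_AP4_1", 90),
                              mp = res_entry("Am_AP4_1", 80),
                              species = "Am")
  c4 <- assign_orthology(rnm, rs, fallback = fb, candidate_id = "x")
  expect_identical(c4$tier, 4L)
  expect_identical(c4$sub_tier, 1L)
  expect_identical(c4$reference_species, "Am")
  expect_identical(c4$family, "AP4")

  # nothing resolves -> tier 5, no family
  c5 <- assign_orthology(rnm, rs, candidate_id = "x")
  expect_identical(c5$tier, 5L)
  expect_true(is.na(c5$family))

  # partner disagreement between methods forces the fallback
  rdis <- mk_results(nj = res_entry("twi", 90), mp = res_entry("sc", 88))
  cdis <- assign_orthology(rdis, rs, fallback = fb, candidate_id = "x")
  expect_identical(cdis$tier, 4L)
})

test_that("tier is monotone: raising a support never increases the tier", {
  rs <- test_refset()
  sup_grid <- expand.grid(nj = c(20, 45, 55, 95), mp = c(20, 45, 55, 95))
  for (k in seq_len(nrow(sup_grid))) {
    base <- mk_results(nj = res_entry("twi", sup_grid$nj[k]),
                       mp = res_entry("twi", sup_grid$mp[k]))
    t_base <- assign_orthology(base, rs, candidate_id = "x")$tier
    for (m in c("nj", "mp")) {
      up <- base
      up[[m]]$support <- up[[m]]$support + 30
      t_up <- assign_orthology(up, rs, candidate_id = "x")$tier
      expect_lte(t_up, t_base)
    }
  }
})

test_that("a candidate identical to a reference gets full support, tier 1", {
  rs <- test_refset()
  cfg <- bhlh_config(methods = c("nj", "mp"), nj_bootstrap_reps = 50,
                     mp_bootstrap_reps = 25, seed = 14)
  row75 <- strsplit(rs$alignment[["crp"]], "")[[1]]
  res <- in_group_analysis("cand", row75, rs, group = "B", config = cfg)
  for (m in c("nj", "mp")) {
    expect_identical(res[[m]]$partner, "crp")
    expect_equal(res[[m]]$support, 100)
  }
  call <- assign_orthology(res, rs, candidate_id = "cand")
  expect_identical(call$tier, 1L)
  expect_identical(call$family, "AP4")
})

test_that("an unrelated motif finds no well-supported partner", {
  rs <- test_refset()
  cfg <- bhlh_config(methods = "nj", nj_bootstrap_reps = 100, seed = 15)
  # random motif: carries no family signal, so no candidate+reference pair
  # should be both monophyletic and significantly supported
  set.seed(2)
  row75 <- sample(bhlhscan:::AA20, 75, replace = TRUE)
  res <- in_group_analysis("cand", row75, rs, group = "B", config = cfg)
  expect_false(isTRUE(res$nj$monophyletic) &&
                 isTRUE(res$nj$support >= cfg$support_threshold))
})

test_that("group lookup, duplications, naming and WRPW flags", {
  expect_identical(assign_group("AP4"), "B")
  expect_identical(assign_group("COE"), "F")
  expect_identical(assign_group("Emc"), "D")
  expect_error(assign_group("NoSuchFamily"), "unknown family")

  rs <- test_refset()
  mkcall <- function(cand, fam, ortho, grp = "A") {
    structure(list(candidate = cand, family = fam, ortholog = ortho,
                   supports = c(nj = 99), monophyletic = c(nj = TRUE),
                   tier = 1L, sub_tier = NA_integer_,
                   reference_species = "Dm", group = grp, tie = FALSE),
              class = "orthology_call")
  }
  calls <- list(mkcall("c1", "Twist", "twi"), mkcall("c2", "Twist", "twi"),
                mkcall("c3", "Mist", "Mistr"), mkcall("c4", "Mist", "Mistr"),
                mkcall("c5", "E12/E47", "da"))
  dup <- detect_duplications(calls)
  expect_length(dup, 2)
  expect_setequal(dup[["Twist/twi"]], c("c1", "c2"))

  nm <- name_candidates(calls, "Pa")
  expect_identical(nm$name[nm$candidate == "c5"], "PaDa")
  expect_setequal(nm$name[nm$candidate %in% c("c3", "c4")],
                  c("PaMistr1", "PaMistr2"))
  # suffixes follow candidate-id order
  expect_identical(nm$name[nm$candidate == "c3"], "PaMistr1")

  # tier-5 candidates get provisional names
  calls5 <- c(calls[1], list(structure(list(candidate = "c9",
                                            family = NA_character_,
                                            ortholog = NA_character_,
                                            supports = c(nj = NA_real_),
                                            monophyletic = c(nj = FALSE),
                                            tier = 5L,
                                            sub_tier = NA_integer_,
                                            reference_species = "Dm",
                                            group = NA_character_,
                                            tie = FALSE),
                                       class = "orthology_call")))
  nm5 <- name_candidates(calls5)
  expect_identical(nm5$name[nm5$candidate == "c9"], "PaUnk1")

  # WRPW peptide flags
  ecalls <- list(mkcall("e1", "Hey", "Hey", grp = "E"),
                 mkcall("e2", "H/E(spl)", "h", grp = "E"),
                 mkcall("e3", "Hey", "Stich1", grp = "E"),
                 mkcall("a1", "Twist", "twi", grp = "A"))
  prot <- c(e1 = "MSEQENCEWRPW", e2 = "MSEQENCEWRPA")
  gf <- group_e_features(prot, ecalls)
  expect_identical(nrow(gf), 3L)
  expect_identical(gf$wrpw[gf$candidate == "e1"], "yes")
  expect_identical(gf$wrpw[gf$candidate == "e2"], "no")
  expect_identical(gf$wrpw[gf$candidate == "e3"], "unknown")
})
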
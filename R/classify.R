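# Tiered orthology assignment. Each accepted candidate is analysed inside
# its higher-order group: a tree is built per configured method from the
# candidate, the reference members of the group for one reference species,
# and the outgroup; the best-supported candidate+reference pair decides the
# family. Confidence tiers follow the published decision procedure:
#   1 - every method finds the same partner with support >= threshold;
#   2 - every method finds the same partner, at least one with support
#       >= threshold;
#   3 - tentative: monophyly (any support) in at least one method, the
#       others finding no monophyletic partner;
#   4 - resolved only against the fallback reference species (sub-tier
#       records which of 1-3 applied there);
#   5 - unclassified.

#' In-group phylogenetic analysis of one candidate
#'
#' Builds, for each configured method, a bootstrap-supported tree over the
#' candidate, all reference motifs of its higher-order group from one
#' reference species, and the outgroup; roots it on the outgroup; and finds
#' the reference maximizing the support of the candidate+reference clade.
#'
#' @param candidate_id Label for the candidate leaf.
#' @param row75 Candidate residues on motif positions 1..75 (character
#'   vector of length 75, `-` where absent).
#' @param refset A `reference_set`.
#' @param group Higher-order group letter (A-F).
#' @param species Reference species to draw the in-group from.
#' @param config A [bhlh_config()]; `methods`, replicate counts and the
#'   seed are taken from it.
#' @return List keyed by method: `partner`, `support`, `monophyletic`,
#'   `tie`, plus attributes `trees` (rooted supported trees) and `group`.
#' @export
in_group_analysis <- function(candidate_id, row75, refset, group,
                              species = "Dm", config = bhlh_config()) {
  stopifnot(inherits(refset, "reference_set"))
  sel <- refset$entries$species == species & refset$entries$group == group
  ref_ids <- refset$entries$id[sel]
  if (!length(ref_ids))
    stop("no ", species, " references in group ", group)
  rows <- c(refset$alignment[c(ref_ids, refset$outgroup)],
            stats::setNames(paste(row75, collapse = ""), candidate_id))
  out <- list()
  trees <- list()
  for (method in config$methods) {
    reps <- if (method == "nj") config$nj_bootstrap_reps
    else config$mp_bootstrap_reps
    tr <- bootstrap_support(rows, tree_builder = method, reps = reps,
                            seed = derive_seed(config$seed,
                                               paste0("ingroup:", candidate_id,
                                                      ":", method)),
                            outgroup = refset$outgroup)
    trees[[method]] <- tr
    best <- list(partner = NA_character_, support = NA_real_,
                 monophyletic = FALSE, tie = FALSE)
    sups <- vapply(ref_ids, function(r) {
      cs <- clade_support(tr, c(candidate_id, r))
      if (cs$monophyletic) cs$support %||% NA_real_ else NA_real_
    }, numeric(1))
    mono <- vapply(ref_ids, function(r)
      clade_support(tr, c(candidate_id, r))$monophyletic, logical(1))
    if (any(mono)) {
      cand_sup <- ifelse(mono, ifelse(is.na(sups), 0, sups), -Inf)
      mx <- max(cand_sup)
      hit <- ref_ids[cand_sup == mx]
      best <- list(partner = sort(hit)[1], support = mx,
                   monophyletic = TRUE, tie = length(hit) > 1L)
    }
    out[[method]] <- best
  }
  attr(out, "trees") <- trees
  attr(out, "group") <- group
  attr(out, "species") <- species
  out
}

#' Assign an orthology call from per-method in-group results
#'
#' Applies the tier rules to the primary (fly) in-group results; when they
#' do not resolve the candidate, `fallback()` is invoked to produce results
#' against the fallback reference species and tiers 1-3 are applied there
#' (recorded as tier 4 with a sub-tier).
#'
#' @param results Output of [in_group_analysis()] for the primary species.
#' @param refset A `reference_set` (for family lookup).
#' @param support_threshold Support percentage counting as significant.
#' @param fallback A function() returning in-group results for the fallback
#'   species, or `NULL`.
#' @param candidate_id Candidate label for the call record.
#' @return An `orthology_call`: list with `candidate`, `family`, `ortholog`,
#'   `supports` (named numeric, `NA` = no monophyly), `monophyletic`,
#'   `tier`, `sub_tier`, `reference_species`, `group`, `tie`.
#' @export
assign_orthology <- function(results, refset, support_threshold = 50,
                             fallback = NULL, candidate_id = "candidate") {
  tier_of <- function(res) {
    mono <- vapply(res, `[[`, logical(1), "monophyletic")
    partners <- vapply(res, function(x)
      x$partner %||% NA_character_, character(1))
    sups <- vapply(res, function(x) x$support %||% NA_real_, numeric(1))
    ok <- mono & !is.na(partners)
    if (!any(ok)) return(0L)
    agree <- length(unique(partners[ok])) == 1L
    if (!agree) return(0L)
    if (all(ok)) {
      if (all(sups[ok] >= support_threshold)) return(1L)
      if (any(sups[ok] >= support_threshold)) return(2L)
      return(0L) # monophyly everywhere but no significant support
    }
    3L
  }
  make_call <- function(res, tier, sub_tier, species) {
    mono <- vapply(res, `[[`, logical(1), "monophyletic")
    partners <- vapply(res, function(x) x$partner %||% NA_character_,
                       character(1))
    ortho <- if (any(mono)) unique(partners[mono])[1] else NA_character_
    fam <- if (!is.na(ortho))
      refset$entries$family[match(ortho, refset$entries$id)] else NA_character_
    grp <- if (!is.na(fam))
      refset$entries$group[match(fam, refset$entries$family)] else NA_character_
    structure(list(candidate = candidate_id, family = fam, ortholog = ortho,
                   supports = vapply(res, function(x)
                     x$support %||% NA_real_, numeric(1)),
                   monophyletic = mono, tier = tier, sub_tier = sub_tier,
                   reference_species = species,
                   group = grp,
                   tie = any(vapply(res, `[[`, logical(1), "tie"))),
              class = "orthology_call")
  }
  t1 <- tier_of(results)
  if (t1 > 0L)
    return(make_call(results, t1, NA_integer_, attr(results, "species")))
  if (!is.null(fallback)) {
    res2 <- fallback()
    t2 <- tier_of(res2)
    if (t2 > 0L)
      return(make_call(res2, 4L, t2, attr(res2, "species")))
  }
  call <- make_call(results, 5L, NA_integer_, attr(results, "species"))
  call$family <- NA_character_
  call$ortholog <- NA_character_
  call
}

#' @export
print.orthology_call <- function(x, ...) {
  sup <- paste(names(x$supports),
               ifelse(x$monophyletic, sprintf("%.0f", x$supports), "n/m"),
               collapse = " ", sep = "=")
  cat(sprintf("%s -> %s (ortholog %s, tier %d%s, %s, supports %s)\n",
              x$candidate, x$family %||% "?", x$ortholog %||% "?",
              x$tier,
              if (!is.na(x$sub_tier)) paste0(".", x$sub_tier) else "",
              x$reference_species, sup))
  invisible(x)
}

#' Higher-order group of a family
#'
#' @param family Family name.
#' @param refset A `reference_set` (defaults to the packaged family table).
#' @return Group letter A-F.
#' @export
assign_group <- function(family, refset = NULL) {
  tab <- if (!is.null(refset)) unique(refset$entries[, c("family", "group")])
  else bhlh_family_table()[, c("family", "group")]
  hit <- match(family, tab$family)
  if (anyNA(hit)) stop("unknown family: ",
                       paste(family[is.na(hit)], collapse = ", "))
  tab$group[hit]
}

#' Detect candidate sets sharing one ortholog
#'
#' Groups calls by (family, ortholog) and reports sets of two or more
#' candidates, which indicate lineage-specific duplications.
#'
#' @param calls List of `orthology_call`s.
#' @return Named list of candidate-id vectors (name = `family/ortholog`).
#' @export
detect_duplications <- function(calls) {
  calls <- Filter(function(x) !is.na(x$family), calls)
  if (!length(calls)) return(list())
  key <- vapply(calls, function(x) paste0(x$family, "/", x$ortholog),
                character(1))
  ids <- vapply(calls, `[[`, character(1), "candidate")
  sets <- split(ids, key)
  Filter(function(s) length(s) >= 2L, sets)
}

#' Name candidates after their orthologs
#'
#' Species prefix + ortholog name (first letter capitalized); when several
#' candidates share one ortholog they are numbered 1..k in candidate-id
#' order. Unclassified candidates get provisional `Unk` names.
#'
#' @param calls List of `orthology_call`s.
#' @param species_prefix Prefix (default `"Pa"`).
#' @return data.frame with `candidate`, `name`.
#' @export
name_candidates <- function(calls, species_prefix = "Pa") {
  ids <- vapply(calls, `[[`, character(1), "candidate")
  ortho <- vapply(calls, function(x) x$ortholog %||% NA_character_,
                  character(1))
  name <- character(length(calls))
  unk <- 0L
  base <- ifelse(is.na(ortho), NA_character_,
                 paste0(species_prefix, toupper(substring(ortho, 1, 1)),
                        substring(ortho, 2)))
  for (b in unique(base[!is.na(base)])) {
    ix <- which(!is.na(base) & base == b)
    ix <- ix[order(ids[ix])]
    if (length(ix) == 1L) name[ix] <- b
    else name[ix] <- paste0(b, seq_along(ix))
  }
  for (i in which(is.na(base))) {
    unk <- unk + 1L
    name[i] <- paste0(species_prefix, "Unk", unk)
  }
  data.frame(candidate = ids, name = name, stringsAsFactors = FALSE)
}

#' Terminal WRPW peptide check for group-E candidates
#'
#' Hairy/Enhancer-of-split (group E) proteins end with the WRPW tetrapeptide;
#' this flags whether each group-E call's full-length protein does.
#'
#' @param proteins Named character vector of full-length protein sequences
#'   (candidate id -> sequence); candidates without an entry are `"unknown"`.
#' @param calls List of `orthology_call`s.
#' @return data.frame with `candidate`, `group`, `wrpw` ("yes"/"no"/
#'   "unknown"); only group-E calls are reported.
#' @export
group_e_features <- function(proteins, calls) {
  e_calls <- Filter(function(x) identical(x$group, "E"), calls)
  if (!length(e_calls))
    return(data.frame(candidate = character(), group = character(),
                      wrpw = character()))
  ids <- vapply(e_calls, `[[`, character(1), "candidate")
  wrpw <- vapply(ids, function(id) {
    p <- if (id %in% names(proteins)) proteins[[id]] else NA_character_
    if (is.na(p)) "unknown"
    else if (endsWith(p, "WRPW")) "yes" else "no"
  }, character(1))
  data.frame(candidate = ids, group = "E", wrpw = unname(wrpw),
             stringsAsFactors = FALSE)
}

# Classify every accepted candidate: primary in-group analysis against the
# fly references, fallback against the bee references.
classify_candidates <- function(candidates, refset, config = bhlh_config()) {
  lapply(candidates, function(cand) {
    grp <- refset$entries$group[match(cand$query, refset$entries$id)]
    if (is.na(grp)) grp <- assign_group(
      refset$entries$family[match(cand$query, refset$entries$id)], refset)
    res <- in_group_analysis(cand$id, cand$row75, refset, grp,
                             species = "Dm", config = config)
    fb <- function() in_group_analysis(cand$id, cand$row75, refset, grp,
                                       species = "Am", config = config)
    assign_orthology(res, refset,
                     support_threshold = config$support_threshold,
                     fallback = fb, candidate_id = cand$id)
  })
}
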
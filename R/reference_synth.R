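# Synthetic reference motif sets.
#
# The pipeline needs three reference collections (a representative motif per
# family, the D. melanogaster motif set, and the A. mellifera fallback set)
# plus a distant outgroup. Family names, higher-order groups and per-species
# member counts are real (shipped in extdata/bhlh_families.tsv); the motif
# sequences themselves are SYNTHETIC, generated by hierarchical mutation from
# a single bHLH-like consensus so that family membership is recoverable by
# phylogenetic analysis: group ancestors diverge from the consensus, family
# ancestors from their group ancestor, and species members from their family
# ancestor, while 19 designated conserved sites are never mutated.

# 75-position bHLH-like consensus (basic 1-13, helix1 14-28, loop 29-59,
# helix2 60-75 under the default region bounds).
BHLH_CONSENSUS <- "MRERRMANNARERVRVRDINEAFRELGRMCQMHLKSDKAQTKLLILQQAVQVILGLEQQVRERNLNPKAACLKRR"

# Alignment positions held invariant across all synthetic references; these
# become the 19 conserved sites that the QC statistic rediscovers from the
# reference alignment.
BHLH_CONSERVED_POSITIONS <- c(5L, 9L, 13L, 16L, 19L, 21L, 23L, 26L, 35L,
                              42L, 49L, 55L, 60L, 62L, 64L, 66L, 69L, 71L, 74L)

# Hierarchical divergence rates (per non-conserved site substitution
# probabilities) and the short-motif windows for the Emc and COE classes.
.SYNTH_RATES <- c(group = 0.25, family = 0.18, member = 0.08, outgroup = 0.45)
.SHORT_MOTIF_WINDOW <- list(Emc = c(46L, 75L), COE = c(26L, 75L))

# Deterministic per-operation RNG stream: every stochastic operation draws
# from a stream derived from (seed, tag) so modules are independently
# reproducible.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Load the packaged family metadata table
#'
#' Families, higher-order groups and per-species member counts of the animal
#' bHLH classification used throughout the package.
#'
#' @return data.frame with columns `family`, `group`, `n_dm`, `n_am`,
#'   `dm_members`.
#' @export
bhlh_family_table <- function() {
  path <- system.file("extdata", "bhlh_families.tsv", package = "bhlhscan")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

#' Generate the synthetic reference motif set
#'
#' Builds a `reference_set` containing one representative motif per family,
#' the fly motif set (with real gene names where the orthology table records
#' them), the honey-bee fallback set, and the rice outgroup `OsRa`. Sequences
#' are synthetic (see the package vignette); the Emc and COE families are
#' truncated to their characteristic short motifs by gapping the alignment
#' rows outside their windows.
#'
#' @param seed Integer seed; the default yields the packaged reference set
#'   used by all examples and tests.
#' @return A `reference_set`.
#' @export
synthetic_reference_set <- function(seed = 101L) {
  fams <- bhlh_family_table()
  cons <- BHLH_CONSENSUS
  sites <- BHLH_CONSERVED_POSITIONS
  groups <- sort(unique(fams$group))
  ganc <- vapply(groups, function(g)
    mutate_motif(cons, .SYNTH_RATES[["group"]], protect_conserved = TRUE,
                 site_positions = sites,
                 seed = derive_seed(seed, paste0("group:", g))),
    character(1))
  names(ganc) <- groups

  ids <- character(0); seqs <- character(0)
  family <- character(0); group <- character(0); species <- character(0)
  add <- function(id, sq, fam, grp, sp) {
    ids <<- c(ids, id); seqs <<- c(seqs, sq)
    family <<- c(family, fam); group <<- c(group, grp); species <<- c(species, sp)
  }
  for (i in seq_len(nrow(fams))) {
    fam <- fams$family[i]; grp <- fams$group[i]
    fanc <- mutate_motif(ganc[[grp]], .SYNTH_RATES[["family"]],
                         protect_conserved = TRUE, site_positions = sites,
                         seed = derive_seed(seed, paste0("family:", fam)))
    add(paste0("Rep_", sanitize_id(fam)),
        mutate_motif(fanc, .SYNTH_RATES[["member"]], protect_conserved = TRUE,
                     site_positions = sites,
                     seed = derive_seed(seed, paste0("rep:", fam))),
        fam, grp, "representative")
    if (fams$n_dm[i] > 0) {
      nm <- strsplit(fams$dm_members[i], ",", fixed = TRUE)[[1]]
      for (j in seq_len(fams$n_dm[i]))
        add(nm[j],
            mutate_motif(fanc, .SYNTH_RATES[["member"]],
                         protect_conserved = TRUE, site_positions = sites,
                         seed = derive_seed(seed, paste0("dm:", fam, ":", j))),
            fam, grp, "Dm")
    }
    if (fams$n_am[i] > 0) {
      for (j in seq_len(fams$n_am[i]))
        add(paste0("Am_", sanitize_id(fam), "_", j),
            mutate_motif(fanc, .SYNTH_RATES[["member"]],
                         protect_conserved = TRUE, site_positions = sites,
                         seed = derive_seed(seed, paste0("am:", fam, ":", j))),
            fam, grp, "Am")
    }
  }
  names(seqs) <- ids
  # short-motif classes: blank the alignment outside the class window
  for (cls in names(.SHORT_MOTIF_WINDOW)) {
    win <- .SHORT_MOTIF_WINDOW[[cls]]
    for (id in ids[family == cls]) {
      ch <- split_chars(seqs[[id]])
      mask <- seq_along(ch) < win[1] | seq_along(ch) > win[2]
      ch[mask] <- "-"
      seqs[[id]] <- paste(ch, collapse = "")
    }
  }
  outgroup_seq <- mutate_motif(cons, .SYNTH_RATES[["outgroup"]],
                               protect_conserved = FALSE,
                               seed = derive_seed(seed, "outgroup:OsRa"))
  aln <- c(seqs, OsRa = outgroup_seq)
  entries <- data.frame(id = ids, family = family, group = group,
                        species = species, stringsAsFactors = FALSE)
  new_reference_set(alignment = aln, entries = entries, outgroup = "OsRa")
}

#' Write a reference set to FASTA + metadata TSV
#'
#' Inverse of [load_reference_set()]; the FASTA keeps alignment gaps.
#'
#' @param refset A `reference_set`.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference_set <- function(refset, fasta_path, metadata_path) {
  stopifnot(inherits(refset, "reference_set"))
  write_fasta(refset$alignment, fasta_path)
  meta <- rbind(refset$entries,
                data.frame(id = refset$outgroup, family = "outgroup",
                           group = "", species = "outgroup"))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, metadata_path))
}
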
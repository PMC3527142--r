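# Orchestration: scan -> QC -> alignment -> classification -> intron report,
# plus the repertoire tallies computed from gene-model sets or calls.

#' Run the full identification pipeline
#'
#' Scans contigs with the reference motifs, collapses redundant hits,
#' reconstructs spliced gene models, filters candidates by the
#' conserved-site statistic, places accepted motifs into the reference
#' alignment, assigns orthologous families by tiered in-group analysis, and
#' summarizes intron architecture. Deterministic for a fixed `config$seed`.
#'
#' @param contigs Named character vector of DNA contigs.
#' @param refset A `reference_set` (default: the packaged synthetic set).
#' @param config A [bhlh_config()].
#' @param out_dir Optional directory; when given, stage outputs are written
#'   there as TSV/FASTA.
#' @return A `bhlh_run_report`: list with `candidates` (accepted, with QC,
#'   alignment and gene models), `rejected`, `calls`, `names`, `gene_models`
#'   (named by assigned gene name), `intron_summary`, `tally`,
#'   `duplications`, `config`.
#' @export
run_pipeline <- function(contigs, refset = synthetic_reference_set(),
                         config = bhlh_config(), out_dir = NULL) {
  site_spec <- derive_site_spec(refset)
  profile <- build_profile(refset)
  hits <- scan_genome(refset, contigs, config)
  hits <- deduplicate_hits(hits)
  candidates <- assemble_candidates(hits, contigs, refset, config)
  # profile placement feeds both QC and classification
  for (nm in names(candidates)) {
    pl <- align_to_profile(candidates[[nm]]$motif_aa, profile,
                           config$gap_open, config$gap_extend)
    candidates[[nm]]$row75 <- pl$row75
    candidates[[nm]]$positions <- pl$positions
  }
  qc <- qc_filter(candidates, site_spec, config)
  accepted <- qc$accepted
  rejected <- qc$rejected
  # candidates whose extension hit a premature stop are flagged (possible
  # pseudogene / nonsense mutation), never silently dropped
  calls <- classify_candidates(accepted, refset, config)
  nm_tab <- if (length(calls)) name_candidates(calls, config$species_prefix)
  else data.frame(candidate = character(), name = character())
  gene_models <- list()
  for (k in seq_along(calls)) {
    cand <- accepted[[calls[[k]]$candidate]]
    gm <- cand$gene_model
    gm <- annotate_introns(gm, cand$positions, config$region_bounds)
    gm$gene <- nm_tab$name[k]
    gm$family <- calls[[k]]$family
    gm$group <- calls[[k]]$group
    gm$motif_aa <- cand$motif_aa
    gene_models[[gm$gene]] <- gm
  }
  report <- structure(
    list(candidates = accepted, rejected = rejected, calls = calls,
         names = nm_tab, gene_models = gene_models,
         intron_summary = summarize_introns(gene_models),
         tally = tally_report(gene_models),
         duplications = detect_duplications(calls),
         config = config),
    class = "bhlh_run_report")
  if (!is.null(out_dir)) render_tables(report, out_dir)
  report
}

#' @export
print.bhlh_run_report <- function(x, ...) {
  t <- x$tally
  cat("bhlh run report:", t$total_members, "members in", t$total_families,
      "families\n")
  cat("  groups:", paste(names(t$group_counts), t$group_counts,
                         collapse = ", "), "\n")
  cat("  rejected candidates:", length(x$rejected), "\n")
  invisible(x)
}

#' Repertoire tallies
#'
#' Counts members per higher-order group, distinct families, and families
#' with two or more members, from a list of gene models or orthology calls.
#'
#' @param x Named list of `gene_model`s, or list of `orthology_call`s.
#' @return List with `total_members`, `total_families`, `group_counts`
#'   (named A-F), `families_ge2`, `family_counts`.
#' @export
tally_report <- function(x) {
  if (length(x) && inherits(x[[1]], "orthology_call")) {
    fam <- vapply(x, function(c) c$family %||% NA_character_, character(1))
    grp <- vapply(x, function(c) c$group %||% NA_character_, character(1))
  } else {
    fam <- vapply(x, `[[`, character(1), "family")
    grp <- vapply(x, `[[`, character(1), "group")
  }
  keep <- !is.na(fam)
  fam <- fam[keep]; grp <- grp[keep]
  fam_counts <- table(fam)
  list(total_members = length(fam),
       total_families = length(fam_counts),
       group_counts = stats::setNames(
         as.integer(table(factor(grp, levels = LETTERS[1:6]))),
         LETTERS[1:6]),
       families_ge2 = sum(fam_counts >= 2),
       family_counts = stats::setNames(as.integer(fam_counts),
                                       names(fam_counts)))
}

#' Write report tables
#'
#' Renders the run report as TSV files: the orthology-call table (gene,
#' family, ortholog, per-method supports with `n/m` preserved, tier), the
#' gene-model table (same layout as the packaged repertoire transcription),
#' and the family tally.
#'
#' @param report A `bhlh_run_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  # Table-1-style calls
  calls <- report$calls
  call_rows <- lapply(seq_along(calls), function(k) {
    cl <- calls[[k]]
    sup <- vapply(seq_along(cl$supports), function(i)
      if (cl$monophyletic[i]) sprintf("%.0f", cl$supports[i]) else "n/m",
      character(1))
    names(sup) <- toupper(names(cl$supports))
    cbind(data.frame(gene = report$names$name[k],
                     family = cl$family %||% "",
                     ortholog = cl$ortholog %||% "",
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(sup), stringsAsFactors = FALSE),
          data.frame(tier = cl$tier,
                     reference_species = cl$reference_species))
  })
  p <- file.path(dir, "orthology_calls.tsv")
  tab <- if (length(call_rows)) do.call(rbind, call_rows)
  else data.frame(gene = character(), family = character(),
                  ortholog = character(), tier = integer(),
                  reference_species = character())
  utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  # Table-2-style gene models
  p <- file.path(dir, "gene_models.tsv")
  utils::write.table(gene_models_to_table(report$gene_models), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  # Table-3-style tally
  p <- file.path(dir, "family_tally.tsv")
  fc <- report$tally$family_counts
  utils::write.table(data.frame(family = names(fc), members = as.integer(fc)),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (length(report$candidates)) {
    p <- file.path(dir, "candidate_motifs.fasta")
    write_fasta(vapply(report$candidates, `[[`, character(1), "motif_aa"), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Serialize gene models to the segment-per-row table layout
#'
#' @param gene_models Named list of `gene_model`s.
#' @return data.frame in the same layout as the packaged repertoire TSV.
#' @export
gene_models_to_table <- function(gene_models) {
  rows <- list()
  for (gm in gene_models) {
    for (i in seq_len(nrow(gm$segments))) {
      has_intron <- i <= nrow(gm$introns)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gm$gene, family = gm$family, group = gm$group,
        contig = gm$segments$contig[i], frame = gm$segments$frame[i],
        start = gm$segments$start[i], end = gm$segments$end[i],
        intron_region = if (has_intron) gm$introns$region[i] else "",
        intron_length = if (has_intron && !is.na(gm$introns$length_bp[i]))
          gm$introns$length_bp[i] else NA_integer_,
        note = if (gm$split_across_contigs) "split" else "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), family = character(),
                      group = character(), contig = character(),
                      frame = character(), start = integer(),
                      end = integer(), intron_region = character(),
                      intron_length = integer(), note = character()))
  do.call(rbind, rows)
}
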
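# Intron architecture relative to the motif sub-regions, and the
# repertoire-level summaries.

#' Annotate a gene model's introns with motif sub-regions
#'
#' Each inter-segment gap inherits the sub-region of the motif position
#' whose codon it precedes (the first position of the downstream segment).
#' Gene models produced by the scan carry the interrupted candidate residue
#' index (`boundary_aa`); `positions` maps candidate residue indices to
#' motif positions 1..75 (from [align_to_profile()]). Cross-contig gaps
#' keep their region only if already recorded.
#'
#' @param gm A `gene_model`.
#' @param positions Integer vector: motif position of each candidate
#'   residue (`NA` for insert residues).
#' @param region_bounds Region intervals, as in [bhlh_config()].
#' @return The gene model with `introns$region` filled.
#' @export
annotate_introns <- function(gm, positions,
                             region_bounds = bhlh_config()$region_bounds) {
  if (!nrow(gm$introns)) return(gm)
  if (is.null(gm$introns$boundary_aa))
    stop("gene model lacks intron boundary indices")
  for (i in seq_len(nrow(gm$introns))) {
    b <- gm$introns$boundary_aa[i]
    pos <- positions[b]
    if (is.na(pos)) pos <- positions[which(!is.na(positions))[1]]
    gm$introns$region[i] <- assign_regions(pos, region_bounds)
  }
  gm
}

#' Summarize intron architecture over a gene-model set
#'
#' Tallies intron-bearing genes, intron counts per gene, per-region counts
#' and length statistics. Cross-contig gaps (split genes) carry no length:
#' the genes are listed separately and excluded from the length statistics
#' and intron counts. The mean length is reported to the nearest bp.
#'
#' @param gene_models List of `gene_model`s.
#' @return An `intron_summary`: list with `genes_total`,
#'   `genes_with_introns`, `total_introns`, `histogram` (named count of
#'   1-intron, 2-intron, ... genes), `per_region`, `min_bp`, `max_bp`,
#'   `mean_bp`, `split_contig_genes`.
#' @export
summarize_introns <- function(gene_models) {
  lens <- list(); regions <- list(); per_gene <- integer(0)
  split_genes <- character(0)
  for (gm in gene_models) {
    if (gm$split_across_contigs) split_genes <- c(split_genes, gm$gene)
    keep <- !is.na(gm$introns$length_bp)
    n <- sum(keep)
    per_gene[gm$gene] <- n
    if (n) {
      lens[[gm$gene]] <- gm$introns$length_bp[keep]
      regions[[gm$gene]] <- gm$introns$region[keep]
    }
  }
  all_len <- unlist(lens, use.names = FALSE)
  all_reg <- unlist(regions, use.names = FALSE)
  hist <- table(factor(per_gene[per_gene > 0]))
  per_region <- table(factor(all_reg,
                             levels = c("basic", "helix1", "loop", "helix2")))
  out <- list(genes_total = length(gene_models),
              genes_with_introns = sum(per_gene > 0),
              total_introns = length(all_len),
              histogram = stats::setNames(as.integer(hist), names(hist)),
              per_region = stats::setNames(as.integer(per_region),
                                           names(per_region)),
              min_bp = if (length(all_len)) min(all_len) else 0L,
              max_bp = if (length(all_len)) max(all_len) else 0L,
              mean_bp = if (length(all_len)) round(mean(all_len)) else 0L,
              split_contig_genes = split_genes)
  class(out) <- "intron_summary"
  out
}

#' @export
print.intron_summary <- function(x, ...) {
  cat(sprintf(paste0("%d of %d genes carry introns in their motif coding",
                     " regions (%d introns in total).\n"),
              x$genes_with_introns, x$genes_total, x$total_introns))
  if (length(x$histogram))
    cat("  introns per gene:",
        paste(sprintf("%s intron(s): %d genes", names(x$histogram),
                      x$histogram), collapse = "; "), "\n")
  cat("  by region:",
      paste(names(x$per_region), x$per_region, collapse = ", "), "\n")
  cat(sprintf("  lengths: min %d bp, max %d bp, mean %d bp\n",
              x$min_bp, x$max_bp, x$mean_bp))
  if (length(x$split_contig_genes))
    cat("  split across two contigs:",
        paste(x$split_contig_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Cross-species intron comparison table
#'
#' Renders the package's computed summaries side by side with fixed
#' literature rows for other insect species (packaged in
#' `extdata/insect_intron_stats.tsv`).
#'
#' @param summaries Named list of `intron_summary` objects (name = species).
#' @param literature Include the packaged literature rows.
#' @return data.frame with one row per species.
#' @export
compare_species <- function(summaries, literature = TRUE) {
  rows <- lapply(names(summaries), function(sp) {
    s <- summaries[[sp]]
    if (!inherits(s, "intron_summary"))
      stop("summaries must be intron_summary objects")
    data.frame(species = sp, genes_with_introns = s$genes_with_introns,
               total_introns = s$total_introns, min_bp = s$min_bp,
               max_bp = s$max_bp, mean_bp = s$mean_bp)
  })
  out <- do.call(rbind, rows)
  if (literature) {
    lit <- utils::read.delim(system.file("extdata", "insect_intron_stats.tsv",
                                         package = "bhlhscan"),
                             stringsAsFactors = FALSE)
    out <- rbind(out, lit)
  }
  out
}
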
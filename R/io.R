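#' Read a FASTA file
#'
#' Reads a multi-record FASTA file into a named character vector. Sequences
#' are uppercased; the molecule type is inferred from the alphabet unless
#' supplied.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"dna"`, `"protein"`, or `NULL` to infer.
#' @return Named character vector of sequences with attribute `moltype`.
#' @export
read_fasta <- function(path, moltype = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA parse error: empty header in ", path)
  if (anyDuplicated(ids))
    stop("FASTA parse error: duplicate id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- nchar(seqs) == 0L
  if (any(empty))
    stop("FASTA parse error: empty sequence for record(s) ",
         paste(ids[empty], collapse = ", "), " in ", path)
  names(seqs) <- ids
  if (is.null(moltype))
    moltype <- if (all(is_dna_string(seqs))) "dna" else "protein"
  moltype <- match.arg(moltype, c("dna", "protein"))
  if (moltype == "dna" && !all(is_dna_string(seqs)))
    stop("sequence alphabet inconsistent with moltype 'dna'")
  if (moltype == "protein" && !all(is_protein_string(gsub("-", "", seqs))))
    stop("sequence alphabet inconsistent with moltype 'protein'")
  attr(seqs, "moltype") <- moltype
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and write Newick trees
#'
#' Thin wrappers over the ape Newick reader/writer that preserve internal
#' node labels, which this package uses to carry bootstrap support
#' percentages.
#'
#' @param tree An object of class `phylo`.
#' @param path File path.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns
#'   `path` invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' Load a reference motif set
#'
#' Joins reference motif sequences to their family / higher-order-group /
#' species metadata and flags the outgroup entry. Every FASTA id must have a
#' metadata row; each family must map to exactly one group.
#'
#' @param fasta_path FASTA of (optionally gapped) reference motifs, including
#'   the outgroup record.
#' @param metadata_path TSV with columns `id`, `family`, `group`, `species`;
#'   the outgroup row carries family `"outgroup"`.
#' @return A `reference_set` object.
#' @export
load_reference_set <- function(fasta_path, metadata_path) {
  aln <- read_fasta(fasta_path, moltype = "protein")
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("id", "family", "group", "species")
  if (!all(need %in% names(meta)) || nrow(meta) == 0L)
    stop("reference metadata must be a non-empty TSV with columns ",
         paste(need, collapse = ", "))
  missing <- setdiff(names(aln), meta$id)
  if (length(missing))
    stop("FASTA id(s) absent from metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(names(aln), meta$id), ]
  out_idx <- which(meta$family == "outgroup")
  if (length(out_idx) != 1L)
    stop("metadata must flag exactly one outgroup row (family = 'outgroup')")
  new_reference_set(alignment = aln,
                    entries = meta[-out_idx, , drop = FALSE],
                    outgroup = meta$id[out_idx])
}

new_reference_set <- function(alignment, entries, outgroup) {
  alignment <- stats::setNames(as.character(alignment), names(alignment))
  if (length(unique(nchar(alignment))) != 1L)
    stop("reference alignment rows must have equal length")
  fam_grp <- unique(entries[, c("family", "group")])
  if (anyDuplicated(fam_grp$family))
    stop("each family must map to exactly one higher-order group")
  if (outgroup %in% entries$id)
    stop("outgroup id must be distinct from entry ids")
  rs <- list(entries = entries[, c("id", "family", "group", "species")],
             alignment = alignment,
             seqs = gsub("-", "", alignment),
             outgroup = outgroup)
  class(rs) <- "reference_set"
  rs
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", nrow(x$entries), "entries,",
      length(unique(x$entries$family)), "families,",
      "outgroup", x$outgroup, "\n")
  print(table(x$entries$species, x$entries$group))
  invisible(x)
}

#' Restrict a reference set to given species and/or group
#'
#' @param refset A `reference_set`.
#' @param species,group Optional filters; `NULL` keeps everything.
#' @param keep_outgroup Keep the outgroup row in the alignment.
#' @return A `reference_set` restricted to the matching entries.
#' @export
subset_reference_set <- function(refset, species = NULL, group = NULL,
                                 keep_outgroup = TRUE) {
  stopifnot(inherits(refset, "reference_set"))
  keep <- rep(TRUE, nrow(refset$entries))
  if (!is.null(species)) keep <- keep & refset$entries$species %in% species
  if (!is.null(group)) keep <- keep & refset$entries$group %in% group
  ids <- refset$entries$id[keep]
  rows <- c(ids, if (keep_outgroup) refset$outgroup)
  new_reference_set(alignment = refset$alignment[rows],
                    entries = refset$entries[keep, , drop = FALSE],
                    outgroup = refset$outgroup)
}

# ---- gene models -----------------------------------------------------------

#' Construct a gene model
#'
#' A gene model is an ordered set of genomic coding segments (transcript
#' orientation) for one bHLH motif, with derived intron records. Coordinates
#' are 1-based inclusive; minus-strand segments are stored in genome
#' coordinates with `start > end` and transcript order runs by descending
#' coordinate.
#'
#' @param gene Gene name.
#' @param family,group Family and higher-order group labels (may be `NA`
#'   before classification).
#' @param segments data.frame with columns `contig`, `frame` (e.g. `"+3"`),
#'   `start`, `end`, in transcript order.
#' @param introns data.frame with columns `region`, `length_bp` (one row per
#'   inter-segment gap; `length_bp` `NA` for a cross-contig gap), or `NULL`
#'   to derive lengths from the coordinates.
#' @param motif_aa Optional motif amino-acid sequence.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, family = NA_character_, group = NA_character_,
                       segments, introns = NULL, motif_aa = NULL) {
  stopifnot(is.data.frame(segments),
            all(c("contig", "frame", "start", "end") %in% names(segments)))
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  contigs <- unique(segments$contig)
  if (length(contigs) > 2L) stop("gene model spans more than two contigs")
  split <- length(contigs) == 2L
  strand <- if (startsWith(segments$frame[1], "-")) "-" else "+"
  check_segments(segments, strand)
  if (is.null(introns)) {
    introns <- derive_introns(segments)
  } else {
    stopifnot(all(c("region", "length_bp") %in% names(introns)))
  }
  n_gaps <- nrow(segments) - 1L
  if (nrow(introns) != n_gaps)
    stop("gene ", gene, ": expected ", n_gaps, " intron record(s), got ",
         nrow(introns))
  bad <- !is.na(introns$length_bp) & introns$length_bp < 1L
  if (any(bad)) stop("intron lengths must be >= 1 bp")
  gm <- list(gene = gene, family = family, group = group,
             contigs = contigs, strand = strand,
             frames = segments$frame, segments = segments,
             introns = introns, split_across_contigs = split,
             motif_aa = motif_aa)
  class(gm) <- "gene_model"
  gm
}

check_segments <- function(segments, strand) {
  for (ct in unique(segments$contig)) {
    seg <- segments[segments$contig == ct, , drop = FALSE]
    lo <- pmin(seg$start, seg$end); hi <- pmax(seg$start, seg$end)
    ord <- order(lo)
    if (any(lo[ord][-1] <= hi[ord][-nrow(seg)]))
      stop("overlapping coding segments on contig ", ct)
  }
  invisible(TRUE)
}

# Intron length = gap between consecutive transcript segments, 1-based
# inclusive coordinates (validated against the printed repertoire table).
derive_introns <- function(segments) {
  n <- nrow(segments)
  if (n <= 1L)
    return(data.frame(region = character(), length_bp = integer()))
  len <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    if (segments$contig[i] != segments$contig[i + 1L]) {
      len[i] <- NA_integer_
      next
    }
    a <- range(c(segments$start[i], segments$end[i]))
    b <- range(c(segments$start[i + 1L], segments$end[i + 1L]))
    len[i] <- if (b[1] > a[2]) b[1] - a[2] - 1L else a[1] - b[2] - 1L
  }
  data.frame(region = rep(NA_character_, n - 1L), length_bp = len)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(x$gene, " [", x$family, "/", x$group, "] ",
      paste(x$contigs, collapse = "+"), " strand ", x$strand, "\n", sep = "")
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  segment %d: %s %s %d-%d\n", i, x$segments$contig[i],
                x$segments$frame[i], x$segments$start[i], x$segments$end[i]))
  if (nrow(x$introns))
    for (i in seq_len(nrow(x$introns)))
      cat(sprintf("  intron %d: %s, %s bp\n", i, x$introns$region[i],
                  ifelse(is.na(x$introns$length_bp[i]), "cross-contig",
                         x$introns$length_bp[i])))
  invisible(x)
}

#' Load a gene-model table
#'
#' Reads a TSV with one row per coding segment (columns `gene`, `family`,
#' `group`, `contig`, `frame`, `start`, `end`, and optional `intron_region`,
#' `intron_length`, `note`) into a list of [gene_model()] objects. Intron
#' lengths are recomputed from the segment coordinates; the printed lengths,
#' when present, are kept alongside for cross-checking.
#'
#' @param path TSV path. Defaults to the packaged transcription of the
#'   ponerine ant bHLH repertoire (57 genes).
#' @return Named list of `gene_model` objects, in file order.
#' @export
load_gene_table <- function(path = system.file("extdata",
                                               "pabhlh_gene_models.tsv",
                                               package = "bhlhscan")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = c(frame = "character"))
  need <- c("gene", "family", "group", "contig", "frame", "start", "end")
  if (!all(need %in% names(tab))) stop("gene table missing columns")
  if (!"intron_region" %in% names(tab)) tab$intron_region <- NA_character_
  if (!"intron_length" %in% names(tab)) tab$intron_length <- NA_integer_
  tab$intron_region[tab$intron_region %in% c("", NA)] <- NA_character_
  tab$intron_length <- suppressWarnings(as.integer(tab$intron_length))
  genes <- unique(tab$gene)
  models <- lapply(genes, function(g) {
    rows <- tab[tab$gene == g, , drop = FALSE]
    segs <- rows[, c("contig", "frame", "start", "end")]
    gm <- gene_model(gene = g, family = rows$family[1], group = rows$group[1],
                     segments = segs)
    if (nrow(gm$introns)) {
      gm$introns$region <- rows$intron_region[seq_len(nrow(gm$introns))]
      gm$introns$printed_length <- rows$intron_length[seq_len(nrow(gm$introns))]
    }
    gm
  })
  names(models) <- genes
  models
}
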
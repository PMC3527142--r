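#' Mutate a motif under a per-site substitution model
#'
#' Each non-gap position is independently substituted with probability
#' `subst_rate`, uniformly over the 19 other residues. When
#' `protect_conserved` is `TRUE` the listed conserved alignment positions are
#' never mutated. Deterministic for a fixed seed.
#'
#' @param ref_motif Amino-acid string (may carry alignment gaps `-`).
#' @param subst_rate Substitution probability in `[0, 1)`.
#' @param protect_conserved Protect the conserved sites?
#' @param site_positions Integer alignment positions to protect; defaults to
#'   the package's 19 conserved sites. A `site_spec` object is also accepted.
#' @param seed Optional integer seed (local RNG stream; the caller's RNG
#'   state is untouched).
#' @return The mutated motif string.
#' @export
mutate_motif <- function(ref_motif, subst_rate, protect_conserved = TRUE,
                         site_positions = BHLH_CONSERVED_POSITIONS,
                         seed = NULL) {
  if (subst_rate < 0 || subst_rate >= 1)
    stop("subst_rate must lie in [0, 1)")
  if (inherits(site_positions, "site_spec"))
    site_positions <- site_positions$positions
  run <- function() {
    ch <- split_chars(ref_motif)
    eligible <- ch != "-"
    if (protect_conserved)
      eligible[intersect(site_positions, seq_along(ch))] <- FALSE
    hit <- eligible & stats::runif(length(ch)) < subst_rate
    for (i in which(hit)) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Reverse-translate a protein with uniform codon choice.
reverse_translate <- function(aa) {
  tab <- codons_for_aa()
  ch <- split_chars(aa)
  paste(vapply(ch, function(a) {
    cands <- tab[[a]]
    if (is.null(cands)) stop("cannot reverse-translate residue ", a)
    if (length(cands) == 1L) cands else sample(cands, 1L)
  }, character(1)), collapse = "")
}

#' Synthesize a contig containing one intron-interrupted bHLH coding region
#'
#' Reverse-translates a motif with uniform codon choice, inserts canonical
#' `GT..AG` introns at codon boundaries inside the requested motif
#' sub-regions, embeds the result in random flanking DNA on the requested
#' strand, and returns the contig together with the true gene model.
#'
#' @param motif Protein motif to plant (no gaps).
#' @param intron_lengths Integer vector of intron lengths (bp, each >= 4);
#'   length 0 plants an intron-less gene.
#' @param intron_regions Character vector (same length) of target sub-regions
#'   among `basic`, `helix1`, `loop`, `helix2`.
#' @param strand `"+"` or `"-"`.
#' @param flank_len Random flank length on each side (bp).
#' @param seed Integer seed (local RNG stream).
#' @param contig_id Contig name for the output records.
#' @param gene Gene name recorded in the truth model.
#' @param aln_positions Alignment position (1..75) of each motif residue;
#'   defaults to `1:nchar(motif)`. Used to honour region requests for
#'   short-motif classes.
#' @param min_exon_aa Minimum coding-segment length in codons on both sides
#'   of every intron (default 4). With a substitution-only divergence model
#'   and canonical `GT..AG` ends as the only splice signal, exons shorter
#'   than a few codons carry too little sequence information to be
#'   localized, so the generator keeps planted structures inside the
#'   identifiable regime.
#' @param region_bounds Region intervals, as in [bhlh_config()].
#' @return List with elements `contig` (named DNA string) and `truth`
#'   (a [gene_model()] whose spliced translation equals `motif`).
#' @export
synthesize_contig <- function(motif, intron_lengths = integer(0),
                              intron_regions = character(0),
                              strand = "+", flank_len = 500L, seed = 1L,
                              contig_id = "ctg1", gene = "gene1",
                              aln_positions = NULL, min_exon_aa = 4L,
                              region_bounds = bhlh_config()$region_bounds) {
  stopifnot(length(intron_lengths) == length(intron_regions),
            strand %in% c("+", "-"))
  if (any(intron_lengths < 4L))
    stop("intron length must be >= 4 bp to hold GT..AG")
  n_aa <- nchar(motif)
  if (is.null(aln_positions)) aln_positions <- seq_len(n_aa)
  with_seed(seed, {
    cds <- reverse_translate(motif)
    # pick codon-boundary insertion points whose following codon lies in the
    # requested region; boundaries must be distinct and ordered
    region_of <- function(pos) {
      for (r in names(region_bounds))
        if (pos >= region_bounds[[r]][1] && pos <= region_bounds[[r]][2])
          return(r)
      NA_character_
    }
    usable <- vapply(2:n_aa, function(j) region_of(aln_positions[j]), character(1))
    boundaries <- integer(0)
    for (k in seq_along(intron_regions)) {
      ok <- which(usable == intron_regions[k])
      # boundary j: intron follows codon j; keep >= min_exon_aa codons on
      # both sides of every intron
      ok <- ok[ok >= min_exon_aa & (n_aa - ok) >= min_exon_aa]
      ok <- ok[vapply(ok, function(j)
        all(abs(j - boundaries) >= min_exon_aa), logical(1))]
      if (!length(ok))
        stop("no usable codon boundary in region ", intron_regions[k])
      boundaries <- c(boundaries, sample(ok, 1L))
    }
    ord <- order(boundaries)
    boundaries <- boundaries[ord]
    intron_lengths <- intron_lengths[ord]
    intron_regions <- intron_regions[ord]
    introns <- vapply(intron_lengths, function(L)
      paste0("GT", random_dna(L - 4L), "AG"), character(1))
    # assemble gene in plus-strand ("working") orientation
    pieces <- character(0)
    seg_aa_start <- c(1L, boundaries + 1L)
    seg_aa_end <- c(boundaries, n_aa)
    w_segs <- data.frame(start = integer(0), end = integer(0))
    pos <- flank_len + 1L
    for (s in seq_along(seg_aa_start)) {
      seg_nt <- substring(cds, (seg_aa_start[s] - 1L) * 3L + 1L,
                          seg_aa_end[s] * 3L)
      w_segs <- rbind(w_segs, data.frame(start = pos,
                                         end = pos + nchar(seg_nt) - 1L))
      pieces <- c(pieces, seg_nt)
      pos <- pos + nchar(seg_nt)
      if (s <= length(introns)) {
        pieces <- c(pieces, introns[s])
        pos <- pos + nchar(introns[s])
      }
    }
    body <- paste(pieces, collapse = "")
    contig <- paste0(random_dna(flank_len), body, random_dna(flank_len))
    L <- nchar(contig)
    if (strand == "-") contig <- revcomp(contig)
    segs <- working_to_genomic(w_segs, strand, L)
    segs$contig <- contig_id
    introns_df <- data.frame(region = intron_regions,
                             length_bp = as.integer(intron_lengths))
    truth <- gene_model(gene = gene, segments = segs[, c("contig", "frame",
                                                         "start", "end")],
                        introns = introns_df, motif_aa = motif)
    contig_vec <- stats::setNames(contig, contig_id)
    list(contig = contig_vec, truth = truth)
  })
}

# Map working-strand (always ascending, plus orientation) segments to genome
# coordinates with frame labels. For minus-strand genes the contig was
# reverse-complemented, so working position w corresponds to genome position
# L - w + 1 and transcript order runs by descending genome coordinate.
working_to_genomic <- function(w_segs, strand, L) {
  if (strand == "+") {
    frame <- paste0("+", ((w_segs$start - 1L) %% 3L) + 1L)
    data.frame(start = w_segs$start, end = w_segs$end, frame = frame)
  } else {
    start <- L - w_segs$start + 1L
    end <- L - w_segs$end + 1L
    frame <- paste0("-", ((w_segs$start - 1L) %% 3L) + 1L)
    data.frame(start = start, end = end, frame = frame)
  }
}

# Extract and splice the coding segments of a gene model from its contigs
# (named DNA strings) and translate; transcript orientation respected.
splice_translate <- function(gm, contigs) {
  nt <- character(0)
  for (i in seq_len(nrow(gm$segments))) {
    ct <- contigs[[gm$segments$contig[i]]]
    a <- gm$segments$start[i]; b <- gm$segments$end[i]
    piece <- if (a <= b) substring(ct, a, b)
    else revcomp(substring(ct, b, a))
    nt <- c(nt, piece)
  }
  translate_dna(paste(nt, collapse = ""))
}

#' Generate a benchmark genome with known truth
#'
#' Plants `n_genes` mutated copies of fly reference motifs, each on its own
#' contig with 0-2 canonical introns (lengths drawn from the packaged
#' repertoire table), plus one decoy region engineered to fail the
#' 19-conserved-site statistic. Families are first drawn without replacement,
#' then with replacement, so recent in-paralog pairs occur.
#'
#' @param refset A `reference_set` (defaults to the packaged synthetic set).
#' @param n_genes Number of genes to plant.
#' @param subst_rate Per-site substitution rate applied to each planted
#'   motif.
#' @param protect_conserved Protect the 19 conserved sites when mutating.
#' @param intron_prob Probability that a planted gene carries at least one
#'   intron (a second intron is added with the repertoire's conditional
#'   frequency 4/22).
#' @param seed Integer seed; the whole benchmark is reproducible from it.
#' @param site_spec Site specification used both for protection and for the
#'   decoy construction; defaults to the spec derived from `refset`.
#' @return List with `contigs` (named DNA vector), `truth` (list of
#'   `gene_model`s), `truth_table` (data.frame), `decoy_contig` (id).
#' @export
make_benchmark <- function(refset = synthetic_reference_set(),
                           n_genes = 20L, subst_rate = 0.10,
                           protect_conserved = TRUE, intron_prob = 0.4,
                           seed = 1L, site_spec = NULL) {
  stopifnot(inherits(refset, "reference_set"), n_genes >= 1L)
  if (is.null(site_spec)) site_spec <- derive_site_spec(refset)
  dm <- refset$entries[refset$entries$species == "Dm", , drop = FALSE]
  fams <- unique(dm$family)
  intron_pool <- benchmark_intron_pool()
  with_seed(derive_seed(seed, "benchmark"), {
    n_unique <- min(length(fams), ceiling(0.9 * n_genes))
    chosen <- sample(fams, n_unique)
    if (n_genes > n_unique)
      chosen <- c(chosen, sample(chosen, n_genes - n_unique, replace = TRUE))
    contigs <- character(0)
    truth <- list()
    rows <- list()
    for (i in seq_len(n_genes)) {
      fam <- chosen[i]
      ref_ids <- dm$id[dm$family == fam]
      ref_id <- if (length(ref_ids) == 1L) ref_ids else sample(ref_ids, 1L)
      ref_row <- refset$alignment[[ref_id]]
      mot_aln <- mutate_motif(ref_row, subst_rate,
                              protect_conserved = protect_conserved,
                              site_positions = site_spec$positions,
                              seed = derive_seed(seed, paste0("mut:", i)))
      keep <- split_chars(mot_aln) != "-"
      motif <- paste(split_chars(mot_aln)[keep], collapse = "")
      aln_pos <- which(keep)
      n_int <- 0L
      if (stats::runif(1) < intron_prob)
        n_int <- if (stats::runif(1) < 4 / 22) 2L else 1L
      regions <- if (n_int == 2L) c("basic", "loop")
      else if (n_int == 1L) sample(c("basic", "helix1", "loop", "helix2"), 1L)
      else character(0)
      # short-motif classes have no basic region to interrupt
      if (n_int > 0L && any(!regions %in% available_regions(aln_pos)))
        regions <- rep("loop", n_int)[seq_len(n_int)]
      if (n_int == 2L && length(unique(regions)) == 1L)
        n_int <- 1L
      regions <- regions[seq_len(n_int)]
      lengths <- if (n_int) sample(intron_pool, n_int) else integer(0)
      strand <- sample(c("+", "-"), 1L)
      ctg_id <- sprintf("ctg%02d", i)
      gene_id <- sprintf("G%02d", i)
      sim <- synthesize_contig(motif, lengths, regions, strand = strand,
                               flank_len = sample(300:800, 1L),
                               seed = derive_seed(seed, paste0("ctg:", i)),
                               contig_id = ctg_id, gene = gene_id,
                               aln_positions = aln_pos)
      sim$truth$family <- fam
      sim$truth$group <- dm$group[dm$family == fam][1]
      attr(sim$truth, "ref_id") <- ref_id
      contigs <- c(contigs, sim$contig)
      truth[[gene_id]] <- sim$truth
      rows[[i]] <- data.frame(gene = gene_id, family = fam,
                              group = sim$truth$group, contig = ctg_id,
                              strand = strand, ref_id = ref_id,
                              n_introns = n_int,
                              intron_lengths = paste(lengths, collapse = ","),
                              intron_regions = paste(regions, collapse = ","),
                              motif = motif)
    }
    decoy <- make_decoy(refset, site_spec,
                        seed = derive_seed(seed, "decoy"))
    contigs <- c(contigs, decoy$contig)
    list(contigs = contigs, truth = truth,
         truth_table = do.call(rbind, rows),
         decoy_contig = names(decoy$contig), decoy_motif = decoy$motif)
  })
}

available_regions <- function(aln_pos, region_bounds = bhlh_config()$region_bounds) {
  names(Filter(function(b) sum(aln_pos[-1] >= b[1] & aln_pos[-1] <= b[2]) > 0,
               region_bounds))
}

# Intron lengths observed in the packaged repertoire table.
benchmark_intron_pool <- function() {
  models <- load_gene_table()
  lens <- unlist(lapply(models, function(m) m$introns$length_bp))
  lens <- lens[!is.na(lens)]
  as.integer(lens)
}

# A decoy that aligns well enough to be picked up by the scan but mismatches
# at >= 12 of the 19 conserved sites, so the QC statistic must reject it.
make_decoy <- function(refset, site_spec, seed) {
  with_seed(seed, {
    base <- refset$alignment[[sample(refset$entries$id[
      refset$entries$species == "Dm" & !refset$entries$family %in%
        names(.SHORT_MOTIF_WINDOW)], 1L)]]
    ch <- split_chars(base)
    broken <- sample(site_spec$positions, 12L)
    for (p in broken) {
      allowed <- site_spec$accepted[[as.character(p)]]
      ch[p] <- sample(setdiff(AA20, allowed), 1L)
    }
    motif <- paste(ch[ch != "-"], collapse = "")
    sim <- synthesize_contig(motif, strand = "+", flank_len = 400L,
                             seed = seed + 1L, contig_id = "ctg_decoy",
                             gene = "decoy")
    list(contig = sim$contig, motif = motif)
  })
}
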
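# Candidate discovery: six-frame translation of contigs, Smith-Waterman
# local alignment of reference motifs against every frame (the stand-in for
# a translated-BLAST search), redundancy collapse, in-frame motif extension
# and splice-aware joining of intron-separated coding regions.

#' Six-frame translation
#'
#' Frames `+1..+3` translate the forward strand at offsets 0..2; `-1..-3`
#' translate the reverse complement likewise. Trailing partial codons are
#' dropped; stop codons are rendered `*`, fuzzy codons `X`.
#'
#' @param dna A DNA string.
#' @return Named character vector of six protein strings
#'   (`"+1"`,`"+2"`,`"+3"`,`"-1"`,`"-2"`,`"-3"`).
#' @export
six_frame_translate <- function(dna) {
  rc <- revcomp(dna)
  out <- c(`+1` = translate_dna(dna),
           `+2` = translate_dna(substring(dna, 2)),
           `+3` = translate_dna(substring(dna, 3)),
           `-1` = translate_dna(rc),
           `-2` = translate_dna(substring(rc, 2)),
           `-3` = translate_dna(substring(rc, 3)))
  out
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps under PAM250 (extended with neutral `X`
#' and penalized `*`).
#'
#' @param query_aa,target_aa Protein strings.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return List: `score`, `q_start`, `q_end`, `t_start`, `t_end` (1-based
#'   inclusive spans; zero-length spans when no positive-scoring pair
#'   exists), `q_aln`, `t_aln` (aligned strings with gaps).
#' @export
local_align <- function(query_aa, target_aa, gap_open = 10, gap_extend = 1) {
  stopifnot(nchar(query_aa) > 0L, nchar(target_aa) > 0L)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_aa), Biostrings::AAString(target_aa),
    type = "local", substitutionMatrix = pam250_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0)
    return(list(score = 0, q_start = 0L, q_end = -1L, t_start = 0L,
                t_end = -1L, q_aln = "", t_aln = ""))
  list(score = sc,
       q_start = pa@pattern@range@start,
       q_end = pa@pattern@range@start + pa@pattern@range@width - 1L,
       t_start = pa@subject@range@start,
       t_end = pa@subject@range@start + pa@subject@range@width - 1L,
       q_aln = as.character(Biostrings::alignedPattern(pa)),
       t_aln = as.character(Biostrings::alignedSubject(pa)))
}

# Longest gapless block of a local alignment, as query/target offsets.
gapless_core <- function(al) {
  qa <- split_chars(al$q_aln); ta <- split_chars(al$t_aln)
  gap <- qa == "-" | ta == "-"
  if (!length(gap)) return(NULL)
  r <- rle(!gap)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  if (!length(ok)) return(NULL)
  best <- ok[which.max(r$lengths[ok])]
  cols <- starts[best]:ends[best]
  qpos <- cumsum(qa != "-"); tpos <- cumsum(ta != "-")
  list(q_start = al$q_start + qpos[cols[1]] - 1L,
       q_end = al$q_start + qpos[cols[length(cols)]] - 1L,
       t_start = al$t_start + tpos[cols[1]] - 1L,
       t_end = al$t_start + tpos[cols[length(cols)]] - 1L)
}

# Genomic coordinates of an amino-acid span in a translated frame.
# Frame "+k": aa p starts at k + 3(p-1). Frame "-k": positions count on the
# reverse complement; genome position = L - rc_position + 1.
frame_aa_to_genomic <- function(frame, aa_start, aa_end, L) {
  k <- abs(as.integer(frame))
  w_start <- k + 3L * (aa_start - 1L)
  w_end <- k + 3L * (aa_end - 1L) + 2L
  if (startsWith(frame, "-")) {
    c(g_start = L - w_start + 1L, g_end = L - w_end + 1L)
  } else c(g_start = w_start, g_end = w_end)
}

#' Scan contigs for candidate bHLH-coding regions
#'
#' Aligns every reference motif against all six reading frames of every
#' contig (score-only pass), then, for the contig's promising queries (best
#' frame score at least `anchor_min_frac` of the query's self-score, capped
#' at the `scan_top_queries` best), records full local alignments in every
#' frame; each recorded hit is masked and the frame re-scanned so that
#' intron-separated coding regions of the same query surface as secondary
#' hits. Hits scoring below `config$secondary_min_score` are dropped; the
#' fraction-of-self-score acceptance threshold is applied later, to
#' assembled candidates.
#'
#' @param queries A `reference_set` or named character vector of protein
#'   motifs (gaps are removed).
#' @param contigs Named character vector of DNA contigs.
#' @param config A [bhlh_config()].
#' @return data.frame of hits: `contig`, `frame`, `query`, `score`,
#'   `q_start`, `q_end`, `t_start`, `t_end` (aa in frame), `g_start`,
#'   `g_end` (genomic, orientation-aware), `strand`.
#' @export
scan_genome <- function(queries, contigs, config = bhlh_config()) {
  qseqs <- if (inherits(queries, "reference_set"))
    gsub("-", "", queries$alignment[queries$entries$id]) else gsub("-", "", queries)
  stopifnot(!is.null(names(qseqs)))
  if (!length(contigs)) return(empty_hits())
  qset <- Biostrings::AAStringSet(qseqs)
  self <- vapply(qseqs, pam_self_score, numeric(1))
  rows <- list()
  for (ct in names(contigs)) {
    L <- nchar(contigs[[ct]])
    frames <- six_frame_translate(contigs[[ct]])
    frames <- frames[nchar(frames) >= 3L]
    if (!length(frames)) next
    smat <- vapply(frames, function(tprot)
      Biostrings::pairwiseAlignment(
        qset, Biostrings::AAString(tprot), type = "local",
        substitutionMatrix = pam250_matrix(),
        gapOpening = config$gap_open, gapExtension = config$gap_extend,
        scoreOnly = TRUE), numeric(length(qseqs)))
    qmax <- apply(smat, 1L, max)
    promising <- which(qmax >= pmax(config$secondary_min_score,
                                    config$anchor_min_frac * self))
    promising <- promising[order(-qmax[promising])]
    promising <- utils::head(promising, config$scan_top_queries)
    for (qi in promising) {
      q <- names(qseqs)[qi]
      for (fr in names(frames)) {
        if (smat[qi, fr] < config$secondary_min_score) next
        masked <- frames[[fr]]
        for (pass in 1:4) {
          al <- local_align(qseqs[[q]], masked, config$gap_open,
                            config$gap_extend)
          if (al$score < config$secondary_min_score) break
          g <- frame_aa_to_genomic(fr, al$t_start, al$t_end, L)
          rows[[length(rows) + 1L]] <- data.frame(
            contig = ct, frame = fr, query = q, score = al$score,
            q_start = al$q_start, q_end = al$q_end,
            t_start = al$t_start, t_end = al$t_end,
            g_start = unname(g["g_start"]), g_end = unname(g["g_end"]),
            strand = if (startsWith(fr, "-")) "-" else "+")
          mask <- strrep("*", al$t_end - al$t_start + 1L)
          substring(masked, al$t_start, al$t_end) <- mask
        }
      }
    }
  }
  if (!length(rows)) return(empty_hits())
  do.call(rbind, rows)
}

empty_hits <- function() {
  data.frame(contig = character(), frame = character(), query = character(),
             score = numeric(), q_start = integer(), q_end = integer(),
             t_start = integer(), t_end = integer(), g_start = integer(),
             g_end = integer(), strand = character())
}

#' Collapse redundant hits
#'
#' Hits with the same contig, frame and genomic span are collapsed to one
#' representative (highest score, then first query id alphabetically).
#' Overlapping-but-unequal spans on the same contig and frame are merged
#' into their union span when the overlap covers at least half of the
#' shorter span. Idempotent.
#'
#' @param hits data.frame as returned by [scan_genome()].
#' @return Deduplicated hits data.frame.
#' @export
deduplicate_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  lo <- pmin(hits$g_start, hits$g_end); hi <- pmax(hits$g_start, hits$g_end)
  key <- paste(hits$contig, hits$frame, lo, hi, sep = "|")
  ord <- order(key, -hits$score, hits$query)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(key[ord]), , drop = FALSE]
  # union-merge overlapping spans within (contig, frame)
  out <- list()
  for (grp in split(hits, paste(hits$contig, hits$frame))) {
    lo <- pmin(grp$g_start, grp$g_end); hi <- pmax(grp$g_start, grp$g_end)
    o <- order(lo, hi)
    grp <- grp[o, , drop = FALSE]; lo <- lo[o]; hi <- hi[o]
    cur <- grp[1, , drop = FALSE]; cur_lo <- lo[1]; cur_hi <- hi[1]
    flush <- function(cur, cur_lo, cur_hi) {
      if (cur$strand == "+") { cur$g_start <- cur_lo; cur$g_end <- cur_hi }
      else { cur$g_start <- cur_hi; cur$g_end <- cur_lo }
      cur
    }
    for (r in seq_len(nrow(grp))[-1]) {
      ov <- min(cur_hi, hi[r]) - max(cur_lo, lo[r]) + 1L
      shorter <- min(cur_hi - cur_lo, hi[r] - lo[r]) + 1L
      if (ov >= 0.5 * shorter) {
        cur_lo <- min(cur_lo, lo[r]); cur_hi <- max(cur_hi, hi[r])
        if (grp$score[r] > cur$score) {
          sc <- max(cur$score, grp$score[r])
          cur <- grp[r, , drop = FALSE]; cur$score <- sc
        }
      } else {
        out[[length(out) + 1L]] <- flush(cur, cur_lo, cur_hi)
        cur <- grp[r, , drop = FALSE]; cur_lo <- lo[r]; cur_hi <- hi[r]
      }
    }
    out[[length(out) + 1L]] <- flush(cur, cur_lo, cur_hi)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$contig, res$frame, pmin(res$g_start, res$g_end)), ,
      drop = FALSE]
}

# ---- working-strand machinery ---------------------------------------------

# All reconstruction happens on the "working strand": the contig itself for
# plus-strand loci, its reverse complement for minus-strand loci, so exons
# always run left to right.

working_seq <- function(contig_seq, strand) {
  if (strand == "+") contig_seq else revcomp(contig_seq)
}

w_frames <- function(W) {
  list(translate_dna(W), translate_dna(substring(W, 2)),
       translate_dna(substring(W, 3)))
}

# Amino acids for codons starting at W positions xs (all same frame).
codons_at <- function(frames, xs) {
  if (!length(xs)) return(character(0))
  f <- ((xs[1] - 1L) %% 3L) + 1L
  idx <- (xs - f) %/% 3L + 1L
  tr <- frames[[f]]
  aa <- rep("X", length(xs))
  ok <- !is.na(idx) & idx >= 1L & idx <= nchar(tr)
  if (any(ok)) aa[ok] <- substring(tr, idx[ok], idx[ok])
  aa
}

gt_positions <- function(W) {
  if (is.null(attr(W, "gt"))) {
    m <- gregexpr("(?=GT)", W, perl = TRUE)[[1]]
    attr(W, "gt") <- if (m[1] == -1L) integer(0) else as.integer(m)
  }
  attr(W, "gt")
}

ag_positions <- function(W) {
  m <- gregexpr("(?=AG)", W, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# Drop weakly-scoring edges: returns c(from, to) such that every prefix sum
# from either end of the kept run is positive, or NULL if nothing remains.
trim_positive_core <- function(s) {
  from <- 1L; cum <- 0
  for (i in seq_along(s)) {
    cum <- cum + s[i]
    if (cum <= 0) { from <- i + 1L; cum <- 0 }
  }
  to <- length(s); cum <- 0
  for (i in rev(seq_along(s))) {
    cum <- cum + s[i]
    if (cum <= 0) { to <- i - 1L; cum <- 0 }
  }
  if (from > to) return(NULL)
  c(from, to)
}

# Best-scoring suffix of a per-position score vector (positions ordered
# qpos descending is handled by caller); stop codons (-Inf entries) act as
# barriers. Returns list(score, take) where take = number of positions kept.
best_run <- function(scores) {
  best <- 0; cum <- 0; take <- 0L
  for (k in seq_along(scores)) {
    if (!is.finite(scores[k])) break
    cum <- cum + scores[k]
    if (cum > best) { best <- cum; take <- k }
  }
  list(score = best, take = take)
}

STOP_SCORE <- -Inf

# Scores for extending a segment's coverage one direction along contiguous
# codons. positions: query positions outward from the segment edge.
contiguous_scores <- function(frames, query_chars, qpos, xs) {
  aa <- codons_at(frames, xs)
  s <- pam_score_vec(aa, query_chars[qpos])
  s[aa == "*"] <- STOP_SCORE
  s[xs < 1L] <- STOP_SCORE
  s
}

# ---- splice-aware reconstruction ------------------------------------------

# Reconstruct the full coding structure of one locus on the working strand.
# anchor: list(qs, qe, ws) - query span and W position of the codon of qs.
# Returns list(segments = data.frame(w_start, w_end, q_start, q_end),
#              introns = data.frame(w_start, w_end, length_bp, boundary_aa),
#              stop_blocked = logical)
reconstruct_locus <- function(W, frames, query, anchor, config,
                              edge_slack = 30L) {
  qc <- split_chars(query)
  Q <- length(qc)
  segs <- data.frame(w_start = anchor$ws,
                     w_end = anchor$ws + 3L * (anchor$qe - anchor$qs + 1L) - 1L,
                     q_start = anchor$qs, q_end = anchor$qe)
  introns <- data.frame(w_start = integer(), w_end = integer(),
                        length_bp = integer(), boundary_aa = integer())
  stop_blocked <- FALSE
  gt <- gt_positions(W)
  ag <- ag_positions(W)
  Lw <- nchar(W)

  # ---------- prefix (towards query position 1) ----------
  repeat {
    cur <- segs[1, ]
    if (cur$q_start <= 1L) break
    res <- find_splice_prefix(W, frames, qc, cur, config, edge_slack, gt,
                              introns_left = config$max_introns - nrow(introns))
    if (res$type == "intron") {
      segs[1, c("w_start", "q_start")] <- c(res$anchor_w, res$anchor_q)
      segs <- rbind(data.frame(w_start = res$exon_w[1], w_end = res$exon_w[2],
                               q_start = res$exon_q[1], q_end = res$exon_q[2]),
                    segs)
      introns <- rbind(data.frame(w_start = res$intron_w[1],
                                  w_end = res$intron_w[2],
                                  length_bp = res$intron_w[2] - res$intron_w[1] + 1L,
                                  boundary_aa = res$boundary), introns)
    } else {
      if (res$take > 0L)
        segs[1, c("w_start", "q_start")] <-
          c(cur$w_start - 3L * res$take, cur$q_start - res$take)
      if (res$stop_blocked) stop_blocked <- TRUE
      break
    }
  }
  # ---------- suffix (towards query position Q) ----------
  repeat {
    n <- nrow(segs)
    cur <- segs[n, ]
    if (cur$q_end >= Q) break
    res <- find_splice_suffix(W, frames, qc, cur, config, edge_slack, ag,
                              introns_left = config$max_introns - nrow(introns))
    if (res$type == "intron") {
      segs[n, c("w_end", "q_end")] <- c(res$anchor_w, res$anchor_q)
      segs <- rbind(segs,
                    data.frame(w_start = res$exon_w[1], w_end = res$exon_w[2],
                               q_start = res$exon_q[1], q_end = res$exon_q[2]))
      introns <- rbind(introns,
                       data.frame(w_start = res$intron_w[1],
                                  w_end = res$intron_w[2],
                                  length_bp = res$intron_w[2] - res$intron_w[1] + 1L,
                                  boundary_aa = res$boundary))
    } else {
      if (res$take > 0L)
        segs[n, c("w_end", "q_end")] <-
          c(cur$w_end + 3L * res$take, cur$q_end + res$take)
      if (res$stop_blocked) stop_blocked <- TRUE
      break
    }
  }
  list(segments = segs, introns = introns, stop_blocked = stop_blocked)
}

find_splice_prefix <- function(W, frames, qc, cur, config, edge_slack, gt,
                               introns_left) {
  qs <- cur$q_start; ws <- cur$w_start
  miss <- qs - 1L
  qpos <- seq(qs - 1L, 1L)                      # outward order
  xs <- ws - 3L * seq_len(miss)
  cscore <- contiguous_scores(frames, qc, qpos, xs)
  cont <- best_run(cscore)
  n_free <- length(cscore)
  if (any(!is.finite(cscore))) n_free <- which(!is.finite(cscore))[1] - 1L
  # scores of the anchor's own leading codons (for boundary retraction)
  n_in <- max(0L, min(edge_slack, cur$q_end - qs - 2L))
  in_scores <- if (n_in > 0L)
    pam_score_vec(codons_at(frames, ws + 3L * (seq_len(n_in) - 1L)),
                  qc[seq(qs, qs + n_in - 1L)]) else numeric(0)
  best <- list(total = -Inf)
  if (introns_left > 0L) {
    for (b in seq(max(2L, qs - edge_slack), qs + n_in)) {
      n_onexon <- qs - b                        # >0: extend; <0: retract
      if (n_onexon > n_free) next
      s_anchor <- if (n_onexon > 0L) sum(cscore[seq_len(n_onexon)])
      else if (n_onexon < 0L) -sum(in_scores[seq_len(-n_onexon)])
      else 0
      xb <- ws - 3L * n_onexon                  # W start of codon b
      if (xb < 7L) next
      if (substring(W, xb - 2L, xb - 1L) != "AG") next
      dmin <- max(1L, xb - config$max_intron_len)
      dmax <- xb - config$min_intron_len
      dd <- gt[gt >= dmin & gt <= dmax]
      for (d in dd) {
        n_up <- min(b - 1L, (d - 1L) %/% 3L)
        if (n_up < 1L) next
        ys <- d - 3L * seq_len(n_up)
        escore <- contiguous_scores(frames, qc, seq(b - 1L, b - n_up), ys)
        er <- best_run(escore)
        if (er$take < 1L) next
        total <- s_anchor + er$score
        if (total > best$total) {
          best <- list(total = total, b = b, d = d, take = er$take,
                       xb = xb)
        }
      }
    }
  }
  if (is.finite(best$total) &&
      best$total > cont$score + config$intron_margin) {
    b <- best$b; d <- best$d; take <- best$take
    return(list(type = "intron",
                anchor_w = best$xb, anchor_q = b,
                exon_w = c(d - 3L * take, d - 1L),
                exon_q = c(b - take, b - 1L),
                intron_w = c(d, best$xb - 1L),
                boundary = b))
  }
  # contiguous: cover the full missing span when it is stop-free (extension
  # is coordinate-driven once no splice is supported), else the best run
  take <- if (n_free >= miss) miss else cont$take
  list(type = "final", take = take, stop_blocked = n_free < miss)
}

find_splice_suffix <- function(W, frames, qc, cur, config, edge_slack, ag,
                               introns_left) {
  Q <- length(qc); Lw <- nchar(W)
  qe <- cur$q_end; we <- cur$w_end
  miss <- Q - qe
  qpos <- seq(qe + 1L, Q)
  xs <- we + 1L + 3L * (seq_len(miss) - 1L)
  xs_valid <- xs + 2L <= Lw
  cscore <- contiguous_scores(frames, qc, qpos, xs)
  cscore[!xs_valid] <- STOP_SCORE
  cont <- best_run(cscore)
  n_free <- length(cscore)
  if (any(!is.finite(cscore))) n_free <- which(!is.finite(cscore))[1] - 1L
  # scores of the anchor's own trailing codons (for boundary retraction)
  n_in <- max(0L, min(edge_slack, qe - cur$q_start - 2L))
  in_scores <- if (n_in > 0L)
    pam_score_vec(codons_at(frames, we - 2L - 3L * (seq_len(n_in) - 1L)),
                  qc[seq(qe, qe - n_in + 1L)]) else numeric(0)
  best <- list(total = -Inf)
  if (introns_left > 0L) {
    for (b in seq(max(cur$q_start + 2L, qe - n_in), min(Q - 1L, qe + edge_slack))) {
      n_onexon <- b - qe                        # >0: extend; <0: retract
      if (n_onexon > n_free) next
      s_anchor <- if (n_onexon > 0L) sum(cscore[seq_len(n_onexon)])
      else if (n_onexon < 0L) -sum(in_scores[seq_len(-n_onexon)])
      else 0
      xe <- we + 3L * n_onexon                  # W end of codon b
      if (xe + 2L > Lw) next
      if (substring(W, xe + 1L, xe + 2L) != "GT") next
      amin <- xe + config$min_intron_len
      amax <- min(Lw - 2L, xe + config$max_intron_len)
      aa_pos <- ag[ag + 1L >= amin & ag + 1L <= amax] # ag = start of "AG"
      for (a in aa_pos + 1L) {                  # a = intron end
        n_dn <- min(Q - b, (Lw - a) %/% 3L)
        if (n_dn < 1L) next
        ys <- a + 1L + 3L * (seq_len(n_dn) - 1L)
        escore <- contiguous_scores(frames, qc, seq(b + 1L, b + n_dn), ys)
        er <- best_run(escore)
        if (er$take < 1L) next
        total <- s_anchor + er$score
        if (total > best$total)
          best <- list(total = total, b = b, a = a, take = er$take, xe = xe)
      }
    }
  }
  if (is.finite(best$total) &&
      best$total > cont$score + config$intron_margin) {
    b <- best$b; a <- best$a; take <- best$take
    return(list(type = "intron",
                anchor_w = best$xe, anchor_q = b,
                exon_w = c(a + 1L, a + 3L * take),
                exon_q = c(b + 1L, b + take),
                intron_w = c(best$xe + 1L, a),
                boundary = b + 1L))
  }
  take <- if (n_free >= miss) miss else cont$take
  list(type = "final", take = take, stop_blocked = n_free < miss)
}

# ---- candidate assembly ----------------------------------------------------

new_candidate <- function(id, motif_aa, gm, complete, query, query_score,
                          family_class, stop_blocked, q_cov) {
  structure(list(id = id, motif_aa = motif_aa, gene_model = gm,
                 complete = complete, query = query,
                 query_score = query_score, family_class = family_class,
                 stop_blocked = stop_blocked, q_cov = q_cov),
            class = "motif_candidate")
}

#' @export
print.motif_candidate <- function(x, ...) {
  cat("motif_candidate", x$id, ifelse(x$complete, "(complete)", "(partial)"),
      "query", x$query, "score", x$query_score, "\n  ", x$motif_aa, "\n")
  invisible(x)
}

# Build a candidate from a locus' hits on one contig and strand. The
# reconstruction is confined to a window around the locus so that other
# copies of the same query elsewhere on the contig cannot capture the
# anchor alignment.
build_locus_candidate <- function(hits_locus, contig_seq, contig_id, strand,
                                  queries, qmeta, config, id = "cand") {
  best <- hits_locus[which.max(hits_locus$score), , drop = FALSE]
  q <- best$query
  qseq <- gsub("-", "", queries[[q]])
  W <- working_seq(contig_seq, strand)
  L <- nchar(contig_seq)
  g_lo <- min(pmin(hits_locus$g_start, hits_locus$g_end))
  g_hi <- max(pmax(hits_locus$g_start, hits_locus$g_end))
  wr <- if (strand == "+") c(g_lo, g_hi) else c(L - g_hi + 1L, L - g_lo + 1L)
  pad <- config$max_intron_len + 400L
  wa <- max(1L, wr[1] - pad); wb <- min(L, wr[2] + pad)
  Wsub <- substring(W, wa, wb)
  frames <- w_frames(Wsub)
  als <- lapply(frames, function(fp)
    if (nchar(fp) >= 3L)
      local_align(qseq, fp, config$gap_open, config$gap_extend)
    else list(score = 0))
  k <- which.max(vapply(als, `[[`, numeric(1), "score"))
  if (als[[k]]$score <= 0) return(NULL)
  core <- gapless_core(als[[k]])
  if (is.null(core)) return(NULL)
  ws <- k + 3L * (core$t_start - 1L)
  # trim the anchor to its positively-scoring core: weakly matching edge
  # codons (incidental flank matches) would otherwise hide a splice site;
  # genuinely contiguous codons are re-added by the reconstruction.
  n_core <- core$q_end - core$q_start + 1L
  aa <- codons_at(frames, ws + 3L * (seq_len(n_core) - 1L))
  s <- pam_score_vec(aa, split_chars(qseq)[core$q_start:core$q_end])
  tr <- trim_positive_core(s)
  if (is.null(tr)) return(NULL)
  core$q_end <- core$q_start + tr[2] - 1L
  core$q_start <- core$q_start + tr[1] - 1L
  ws <- ws + 3L * (tr[1] - 1L)
  rec <- reconstruct_locus(Wsub, frames, qseq,
                           list(qs = core$q_start, qe = core$q_end, ws = ws),
                           config)
  w_segs <- rec$segments
  w_segs$w_start <- w_segs$w_start + wa - 1L
  w_segs$w_end <- w_segs$w_end + wa - 1L
  nt <- paste(substring(W, w_segs$w_start, w_segs$w_end), collapse = "")
  motif <- translate_dna(nt)
  segs <- working_to_genomic(data.frame(start = w_segs$w_start,
                                        end = w_segs$w_end), strand, L)
  segs$contig <- contig_id
  introns_df <- data.frame(
    region = rep(NA_character_, nrow(rec$introns)),
    length_bp = rec$introns$length_bp,
    boundary_aa = rec$introns$boundary_aa - w_segs$q_start[1] + 1L)
  gm <- gene_model(gene = id,
                   segments = segs[, c("contig", "frame", "start", "end")],
                   introns = if (nrow(introns_df)) introns_df else NULL,
                   motif_aa = motif)
  stopifnot(identical(splice_translate(gm, stats::setNames(contig_seq,
                                                           contig_id)), motif))
  q_cov <- c(w_segs$q_start[1], w_segs$q_end[nrow(w_segs)])
  score <- pam_score(motif, substring(qseq, q_cov[1], q_cov[2]))
  fam <- qmeta$family[match(q, qmeta$id)]
  new_candidate(id, motif, gm, complete = q_cov[1] == 1L &&
                  q_cov[2] == nchar(qseq),
                query = q, query_score = score,
                family_class = if (!is.na(fam) &&
                                   fam %in% c("Emc", "COE")) fam else "default",
                stop_blocked = rec$stop_blocked, q_cov = q_cov)
}

#' Extend a hit in frame to cover the full motif
#'
#' Contiguous (intron-free) extension of one hit towards both motif ends,
#' stopping at stop codons or the contig edge; the completeness flag records
#' whether the query motif span was fully covered.
#'
#' @param hit One-row hits data.frame (see [scan_genome()]).
#' @param contig_seq DNA string of the hit's contig.
#' @param query_seq The query motif (ungapped).
#' @param config A [bhlh_config()].
#' @return A `motif_candidate` (single-segment gene model).
#' @export
extend_motif <- function(hit, contig_seq, query_seq, config = bhlh_config()) {
  cfg <- config
  cfg$max_introns <- 0L
  qmeta <- data.frame(id = hit$query, family = NA_character_)
  build_locus_candidate(hit, contig_seq, hit$contig, hit$strand,
                        stats::setNames(query_seq, hit$query), qmeta, cfg,
                        id = paste0(hit$contig, ":", hit$g_start))
}

#' Join partial hits of one query into a spliced or split candidate
#'
#' For 2-3 collinear hits of the same query on one contig and strand, the
#' intervening gaps are scanned for canonical `GT..AG` introns whose removal
#' yields the in-frame join maximizing the PAM250 score against the query.
#' For hits on two contigs, the partial candidates are concatenated in query
#' order and flagged `split_across_contigs`; the cross-contig gap carries no
#' intron length.
#'
#' @param hits data.frame of 2-3 hits sharing one query.
#' @param contigs Named DNA vector.
#' @param queries Named vector of query motifs (or a `reference_set`).
#' @param config A [bhlh_config()].
#' @return A `motif_candidate`, or `NULL` when no consistent join exists.
#' @export
join_split_motif <- function(hits, contigs, queries, config = bhlh_config()) {
  if (inherits(queries, "reference_set"))
    queries <- gsub("-", "", queries$alignment[queries$entries$id])
  stopifnot(length(unique(hits$query)) == 1L, nrow(hits) >= 2L,
            nrow(hits) <= 3L)
  qmeta <- data.frame(id = names(queries), family = NA_character_)
  cts <- unique(hits$contig)
  if (length(cts) == 1L) {
    return(build_locus_candidate(hits, contigs[[cts]], cts,
                                 hits$strand[1], queries, qmeta, config,
                                 id = paste0(cts, ":join")))
  }
  if (length(cts) > 2L) stop("join across more than two contigs")
  # each split gene contributes one coding region per contig, so part
  # reconstruction is intron-free; junk tails are resolved by the split
  # point optimization below
  cfg_part <- config
  cfg_part$max_introns <- 0L
  parts <- lapply(cts, function(ct) {
    hh <- hits[hits$contig == ct, , drop = FALSE]
    build_locus_candidate(hh, contigs[[ct]], ct, hh$strand[1], queries,
                          qmeta, cfg_part, id = paste0(ct, ":part"))
  })
  if (any(vapply(parts, is.null, logical(1)))) return(NULL)
  q <- hits$query[1]
  qraw <- queries[[q]]
  ord <- order(vapply(parts, function(p) {
    # order parts by where their best-matching region lies on the query
    sc <- part_scores(p, qraw)
    sum(seq_along(sc) * pmax(sc, 0)) / max(1, sum(pmax(sc, 0)))
  }, numeric(1)))
  a <- parts[[ord[1]]]; b <- parts[[ord[2]]]
  # resolve query overlap: pick the split point maximizing the summed
  # per-position PAM250 score of the left part before it and the right
  # part after it, then trim both parts to their side
  if (b$q_cov[1] <= a$q_cov[2]) {
    sa <- part_scores(a, qraw); sb <- part_scores(b, qraw)
    lo <- max(a$q_cov[1], b$q_cov[1] - 1L)
    hi <- min(a$q_cov[2], b$q_cov[2] - 1L)
    if (lo > hi) return(NULL)
    tot <- vapply(lo:hi, function(s)
      sum(sa[a$q_cov[1]:s]) + sum(sb[(s + 1L):b$q_cov[2]]), numeric(1))
    s_opt <- (lo:hi)[which.max(tot)]
    a <- trim_candidate_suffix(a, a$q_cov[2] - s_opt)
    b <- trim_candidate_prefix(b, s_opt + 1L - b$q_cov[1])
    if (is.null(a) || is.null(b)) return(NULL)
  }
  segs <- rbind(a$gene_model$segments, b$gene_model$segments)
  introns <- rbind(
    if (nrow(a$gene_model$introns)) a$gene_model$introns else NULL,
    data.frame(region = NA_character_, length_bp = NA_integer_,
               boundary_aa = b$q_cov[1] - a$q_cov[1] + 1L),
    if (nrow(b$gene_model$introns)) b$gene_model$introns else NULL)
  gm <- gene_model(gene = paste0(a$id, "+", b$id), segments = segs,
                   introns = introns,
                   motif_aa = paste0(a$motif_aa, b$motif_aa))
  q <- hits$query[1]
  qseq <- queries[[q]]
  motif <- paste0(a$motif_aa, b$motif_aa)
  q_cov <- c(a$q_cov[1], b$q_cov[2])
  score <- pam_score(motif, substring(qseq, q_cov[1], q_cov[2]))
  new_candidate(paste0(a$id, "+", b$id), motif, gm,
                complete = q_cov[1] == 1L && q_cov[2] == nchar(qseq),
                query = q, query_score = score, family_class = "default",
                stop_blocked = a$stop_blocked || b$stop_blocked,
                q_cov = q_cov)
}

# Per-position PAM250 scores of a part candidate against the query motif,
# indexed by query position (zero outside the part's coverage).
part_scores <- function(cand, qraw) {
  sc <- numeric(nchar(qraw))
  idx <- cand$q_cov[1]:cand$q_cov[2]
  sc[idx] <- pam_score_vec(split_chars(cand$motif_aa),
                           split_chars(qraw)[idx])
  sc
}

# Trim `drop_n` residues from one end of a simple (single-terminal-segment)
# partial candidate. Trims crossing an intron are refused.
trim_candidate_prefix <- function(cand, drop_n) {
  if (drop_n <= 0L) return(cand)
  gm <- cand$gene_model
  seg <- gm$segments[1, ]
  seg_aa <- (abs(seg$end - seg$start) + 1L) %/% 3L
  if (drop_n >= seg_aa) return(NULL)
  if (gm$strand == "+") seg$start <- seg$start + 3L * drop_n
  else seg$start <- seg$start - 3L * drop_n
  gm$segments[1, ] <- seg
  introns <- if (nrow(gm$introns)) {
    df <- gm$introns
    df$boundary_aa <- df$boundary_aa - drop_n
    if (any(df$boundary_aa <= 1L)) return(NULL)
    df
  } else NULL
  motif <- substring(cand$motif_aa, drop_n + 1L)
  gm2 <- gene_model(gene = gm$gene, segments = gm$segments,
                    introns = introns, motif_aa = motif)
  cand$gene_model <- gm2
  cand$motif_aa <- motif
  cand$q_cov[1] <- cand$q_cov[1] + drop_n
  cand
}

trim_candidate_suffix <- function(cand, drop_n) {
  if (drop_n <= 0L) return(cand)
  gm <- cand$gene_model
  n <- nrow(gm$segments)
  seg <- gm$segments[n, ]
  seg_aa <- (abs(seg$end - seg$start) + 1L) %/% 3L
  if (drop_n >= seg_aa) return(NULL)
  if (gm$strand == "+") seg$end <- seg$end - 3L * drop_n
  else seg$end <- seg$end + 3L * drop_n
  gm$segments[n, ] <- seg
  n_aa <- nchar(cand$motif_aa)
  introns <- if (nrow(gm$introns)) {
    df <- gm$introns
    if (any(df$boundary_aa > n_aa - drop_n)) return(NULL)
    df
  } else NULL
  motif <- substring(cand$motif_aa, 1L, n_aa - drop_n)
  gm2 <- gene_model(gene = gm$gene, segments = gm$segments,
                    introns = introns, motif_aa = motif)
  cand$gene_model <- gm2
  cand$motif_aa <- motif
  cand$q_cov[2] <- cand$q_cov[2] - drop_n
  cand
}

# Cluster deduplicated hits into loci (per contig and strand; hits separated
# by more than max_intron_len belong to different loci), then build one
# candidate per locus using the locus' best query.
assemble_candidates <- function(hits, contigs, refset,
                                config = bhlh_config()) {
  if (!nrow(hits)) return(list())
  queries <- gsub("-", "", refset$alignment[refset$entries$id])
  qmeta <- refset$entries
  out <- list()
  for (grp in split(hits, paste(hits$contig, hits$strand))) {
    ct <- grp$contig[1]; strand <- grp$strand[1]
    lo <- pmin(grp$g_start, grp$g_end); hi <- pmax(grp$g_start, grp$g_end)
    o <- order(lo); grp <- grp[o, , drop = FALSE]
    lo <- lo[o]; hi <- hi[o]
    locus_id <- cumsum(c(1L, as.integer(lo[-1] - cummax(hi)[-length(hi)] >
                                          config$max_intron_len)))
    for (lid in unique(locus_id)) {
      hl <- grp[locus_id == lid, , drop = FALSE]
      cand_id <- sprintf("%s%s:%d", ct, strand, min(pmin(hl$g_start, hl$g_end)))
      cand <- tryCatch(
        build_locus_candidate(hl, contigs[[ct]], ct, strand, queries, qmeta,
                              config, id = cand_id),
        error = function(e) NULL)
      if (is.null(cand)) next
      self <- pam_self_score(substring(gsub("-", "", queries[[cand$query]]),
                                       cand$q_cov[1], cand$q_cov[2]))
      if (cand$query_score >= config$scan_min_frac * self)
        out[[cand_id]] <- cand
    }
  }
  dedupe_candidates(out)
}

# Two candidates with overlapping genomic footprints on the same contig and
# strand describe the same locus: keep the higher-scoring one.
dedupe_candidates <- function(cands) {
  if (length(cands) <= 1L) return(cands)
  keep <- rep(TRUE, length(cands))
  info <- lapply(cands, function(cc) {
    s <- cc$gene_model$segments
    list(ct = s$contig[1], strand = cc$gene_model$strand,
         lo = min(pmin(s$start, s$end)), hi = max(pmax(s$start, s$end)),
         score = cc$query_score)
  })
  for (i in seq_along(cands)) for (j in seq_along(cands)) {
    if (i >= j) next
    a <- info[[i]]; b <- info[[j]]
    if (a$ct != b$ct || a$strand != b$strand) next
    ov <- min(a$hi, b$hi) - max(a$lo, b$lo) + 1L
    if (ov >= 0.5 * min(a$hi - a$lo, b$hi - b$lo)) {
      if (a$score >= b$score) keep[j] <- FALSE else keep[i] <- FALSE
    }
  }
  cands[keep]
}
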
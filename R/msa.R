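# Profile alignment of candidate motifs into the fixed reference alignment
# coordinate system (positions 1..75 plus any candidate-induced insert
# columns). Deterministic profile alignment replaces de-novo progressive MSA:
# the reference alignment is fixed and candidates are placed one at a time.

#' Build a position-specific score profile from a reference alignment
#'
#' Per-column residue frequencies with pseudocount 0.5, converted to log-odds
#' scores against the background residue frequencies of the whole reference
#' set. Gap characters do not contribute to column counts.
#'
#' @param refset A `reference_set`, or a named character vector of equal
#'   length gapped rows.
#' @param include_outgroup Include the outgroup row (default `FALSE`).
#' @return A `bhlh_profile`: list with `scores` (20 x L matrix, bits),
#'   `ncol`, `background`.
#' @export
build_profile <- function(refset, include_outgroup = FALSE) {
  rows <- if (inherits(refset, "reference_set")) {
    if (include_outgroup) refset$alignment
    else refset$alignment[setdiff(names(refset$alignment), refset$outgroup)]
  } else refset
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("alignment rows must have equal length")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  all_res <- mat[mat != "-"]
  bg <- (table(factor(all_res, levels = AA20)) + 0.5) /
    (length(all_res) + 0.5 * 20)
  scores <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA20, NULL))
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col != "-"]
    fr <- (table(factor(col, levels = AA20)) + 0.5) / (length(col) + 0.5 * 20)
    scores[, j] <- log2(as.numeric(fr) / as.numeric(bg))
  }
  structure(list(scores = scores, ncol = L, background = as.numeric(bg)),
            class = "bhlh_profile")
}

#' Align a candidate motif to a profile
#'
#' Global alignment of the candidate against the profile columns
#' (Needleman-Wunsch with affine gaps, free end gaps on the candidate so
#' short motifs are placed rather than stretched). Candidate residues that
#' align to no profile column become insert columns. Ties prefer a match
#' over a gap, then the leftmost gap.
#'
#' @param candidate Ungapped amino-acid string.
#' @param profile A `bhlh_profile`.
#' @param gap_open,gap_extend Affine gap penalties (bits).
#' @return List: `positions` (for each candidate residue, its profile column
#'   1..L or `NA` for an insert), `row75` (character vector of length L,
#'   candidate residue per profile column or `-`), `aligned` (gapped
#'   candidate string over L + n_insert columns), `column_map` (profile
#'   column per output column, `NA` at inserts), `score`.
#' @export
align_to_profile <- function(candidate, profile, gap_open = 10, gap_extend = 1) {
  stopifnot(inherits(profile, "bhlh_profile"), nchar(candidate) > 0L)
  ch <- split_chars(candidate)
  n <- length(ch); L <- profile$ncol
  S <- profile$scores
  sub <- matrix(0, nrow = n, ncol = L)
  known <- ch %in% rownames(S)
  sub[known, ] <- S[ch[known], , drop = FALSE]
  NEG <- -1e9
  # three-state affine DP with explicit traceback pointers.
  # Ix = gap in profile (candidate insertion), Iy = gap in candidate
  # (profile column deleted). Leading/trailing Iy runs are free so short
  # motifs are placed, not stretched. Pointer codes: 1 = M, 2 = Iy, 3 = Ix
  # (order encodes the tie-break: match preferred, then profile deletion).
  M <- matrix(NEG, n + 1L, L + 1L); Iy <- M; Ix <- M
  PM <- matrix(0L, n + 1L, L + 1L); PIy <- PM; PIx <- PM
  M[1, 1] <- 0
  Iy[1, ] <- 0; PIy[1, ] <- 2L; PIy[1, 2] <- 1L # free leading deletions
  Ix[, 1] <- c(NEG, -gap_open - gap_extend * (seq_len(n) - 1L))
  PIx[2, 1] <- 1L; if (n > 1L) PIx[3:(n + 1L), 1] <- 3L
  pick <- function(vals) { k <- which.max(vals); c(vals[k], k) }
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      d <- pick(c(M[i, j], Iy[i, j], Ix[i, j]))
      M[i + 1L, j + 1L] <- d[1] + sub[i, j]
      PM[i + 1L, j + 1L] <- d[2]
      free <- (i == n) # trailing profile deletions are free
      oy <- M[i + 1L, j] - if (free) 0 else gap_open
      ey <- Iy[i + 1L, j] - if (free) 0 else gap_extend
      gy <- pick(c(oy, ey))
      Iy[i + 1L, j + 1L] <- gy[1]
      PIy[i + 1L, j + 1L] <- c(1L, 2L)[gy[2]]
      gx <- pick(c(M[i, j + 1L] - gap_open, Ix[i, j + 1L] - gap_extend))
      Ix[i + 1L, j + 1L] <- gx[1]
      PIx[i + 1L, j + 1L] <- c(1L, 3L)[gx[2]]
    }
  }
  fin <- pick(c(M[n + 1L, L + 1L], Iy[n + 1L, L + 1L], Ix[n + 1L, L + 1L]))
  score <- fin[1]
  state <- fin[2]
  i <- n; j <- L
  ops <- character(n + L) # at most n+L operations
  k <- length(ops) + 1L
  while (i > 0L || j > 0L) {
    k <- k - 1L
    if (state == 1L) {
      ops[k] <- "M"
      state <- PM[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ops[k] <- "Iy"
      state <- PIy[i + 1L, j + 1L]
      j <- j - 1L
    } else {
      ops[k] <- "Ix"
      state <- PIx[i + 1L, j + 1L]
      i <- i - 1L
    }
  }
  build_profile_alignment(ch, ops[k:length(ops)], L, score)
}

build_profile_alignment <- function(ch, ops, L, score) {
  positions <- rep(NA_integer_, length(ch))
  row75 <- rep("-", L)
  aligned <- character(0)
  column_map <- integer(0)
  i <- 0L; j <- 0L
  for (op in ops) {
    if (op == "M") {
      i <- i + 1L; j <- j + 1L
      positions[i] <- j
      row75[j] <- ch[i]
      aligned <- c(aligned, ch[i]); column_map <- c(column_map, j)
    } else if (op == "Ix") {
      i <- i + 1L
      aligned <- c(aligned, ch[i]); column_map <- c(column_map, NA_integer_)
    } else {
      j <- j + 1L
      aligned <- c(aligned, "-"); column_map <- c(column_map, j)
    }
  }
  list(positions = positions, row75 = row75,
       aligned = paste(aligned, collapse = ""),
       column_map = column_map, score = score)
}

#' Merge aligned candidates into the reference alignment
#'
#' Builds a single alignment matrix containing the reference rows and the
#' candidate rows; candidate insert columns pad all reference rows with
#' gaps. Ungapping any row returns its original sequence.
#'
#' @param refset A `reference_set` (or named gapped rows).
#' @param aligned_candidates Named list of [align_to_profile()] results.
#' @return List with `rows` (named gapped strings, equal width) and
#'   `column_map` (profile position per column, `NA` at insert columns).
#' @export
merge_alignment <- function(refset, aligned_candidates = list()) {
  ref_rows <- if (inherits(refset, "reference_set")) refset$alignment else refset
  L <- unique(nchar(ref_rows))
  stopifnot(length(L) == 1L)
  if (!length(aligned_candidates))
    return(list(rows = ref_rows, column_map = seq_len(L)))
  # collect insert columns: keyed by (after profile column), max multiplicity
  ins_count <- integer(L + 1L) # inserts before column j+1, index = j+1
  per_cand <- lapply(aligned_candidates, function(a) {
    cm <- a$column_map
    ins_after <- integer(0)
    last <- 0L
    for (k in seq_along(cm)) {
      if (is.na(cm[k])) ins_after <- c(ins_after, last) else last <- cm[k]
    }
    ins_after
  })
  for (ia in per_cand) {
    tab <- table(ia)
    for (nm in names(tab)) {
      idx <- as.integer(nm) + 1L
      ins_count[idx] <- max(ins_count[idx], tab[[nm]])
    }
  }
  # output column layout: for each profile column j: inserts-after slots of j-1
  # were already emitted; emit column j then inserts after j
  column_map <- integer(0)
  for (j in 0:L) {
    if (j > 0L) column_map <- c(column_map, j)
    column_map <- c(column_map, rep(NA_integer_, ins_count[j + 1L]))
  }
  width <- length(column_map)
  expand_ref <- function(row) {
    ch <- split_chars(row)
    out <- rep("-", width)
    out[!is.na(column_map)] <- ch
    paste(out, collapse = "")
  }
  rows <- vapply(ref_rows, expand_ref, character(1))
  for (nm in names(aligned_candidates)) {
    a <- aligned_candidates[[nm]]
    ch <- split_chars(gsub("-", "", a$aligned))
    out <- rep("-", width)
    # place matched residues at their profile columns
    out_pos <- match(a$positions, column_map)
    matched <- !is.na(a$positions)
    out[out_pos[matched]] <- ch[matched]
    # place inserts into the reserved slots after their anchor column
    ia <- per_cand[[match(nm, names(aligned_candidates))]]
    if (length(ia)) {
      ins_res <- ch[!matched]
      for (u in unique(ia)) {
        slots <- which(is.na(column_map))
        anchor_out <- if (u == 0L) 0L else match(u, column_map)
        slots <- slots[slots > anchor_out]
        if (u < L) {
          nxt <- match(u + 1L, column_map)
          slots <- slots[slots < nxt]
        }
        take <- sum(ia == u)
        out[slots[seq_len(take)]] <- ins_res[seq_len(take)]
        ins_res <- ins_res[-seq_len(take)]
      }
    }
    rows[[nm]] <- paste(out, collapse = "")
  }
  list(rows = rows, column_map = column_map)
}

# Candidate residues mapped onto profile positions 1..75, as a 75-length
# character vector with "-" where the candidate has no residue.
candidate_row75 <- function(candidate, profile, gap_open = 10, gap_extend = 1) {
  align_to_profile(candidate, profile, gap_open, gap_extend)$row75
}
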
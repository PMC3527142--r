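# Independent oracles used to validate the implementation. These share no
# code with the package internals they check.

# Fitch small-parsimony count by explicit set recursion over a rooted
# representation of the tree. Gaps/unknowns ("-", "?", "X", "*") are treated
# as the full state set.
oracle_fitch <- function(tree, rows) {
  mat <- do.call(rbind, strsplit(rows[tree$tip.label], "", fixed = TRUE))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  all_states <- unique(as.vector(mat[!mat %in% c("-", "?", "X", "*")]))
  total <- 0L
  for (j in seq_len(ncol(mat))) {
    changes <- 0L
    states <- function(node) {
      if (node <= ntip) {
        s <- mat[node, j]
        if (s %in% c("-", "?", "X", "*")) return(all_states)
        return(s)
      }
      sets <- lapply(kids[[as.character(node)]], states)
      acc <- sets[[1]]
      for (k in seq_along(sets)[-1]) {
        inter <- intersect(acc, sets[[k]])
        if (length(inter)) acc <- inter
        else { acc <- union(acc, sets[[k]]); changes <<- changes + 1L }
      }
      acc
    }
    states(root)
    total <- total + changes
  }
  total
}

# Brute-force optimal local alignment score over all gapless and
# single-internal-gap local alignments (sufficient at lengths <= 12 with
# steep gap penalties, where a second gap can never pay for itself).
oracle_local_score <- function(q, t, gap_open = 10, gap_extend = 1) {
  m <- bhlhscan:::pam250_matrix()
  qs <- strsplit(q, "")[[1]]; ts <- strsplit(t, "")[[1]]
  nq <- length(qs); nt <- length(ts)
  sc <- function(a, b) m[a, b]
  best <- 0
  # gapless: all diagonal windows
  for (qi in seq_len(nq)) for (ti in seq_len(nt)) {
    run <- 0
    k <- 0L
    while (qi + k <= nq && ti + k <= nt) {
      run <- run + sc(qs[qi + k], ts[ti + k])
      if (run > best) best <- run
      k <- k + 1L
    }
  }
  # one internal gap of length g in either sequence
  diag_sum <- function(qi, ti, len) {
    if (len <= 0) return(0)
    sum(vapply(seq_len(len) - 1L,
               function(k) sc(qs[qi + k], ts[ti + k]), numeric(1)))
  }
  for (qi in seq_len(nq)) for (ti in seq_len(nt)) {
    maxlen <- min(nq - qi + 1L, nt - ti + 1L)
    for (l1 in seq_len(maxlen)) {
      s1 <- diag_sum(qi, ti, l1)
      for (g in 1:4) {
        # gap in query (skip target residues)
        ti2 <- ti + l1 + g; qi2 <- qi + l1
        if (ti2 <= nt && qi2 <= nq) {
          maxl2 <- min(nq - qi2 + 1L, nt - ti2 + 1L)
          for (l2 in seq_len(maxl2)) {
            s <- s1 - gap_open - gap_extend * (g - 1L) +
              diag_sum(qi2, ti2, l2)
            if (s > best) best <- s
          }
        }
        # gap in target (skip query residues)
        qi3 <- qi + l1 + g; ti3 <- ti + l1
        if (qi3 <= nq && ti3 <= nt) {
          maxl3 <- min(nq - qi3 + 1L, nt - ti3 + 1L)
          for (l3 in seq_len(maxl3)) {
            s <- s1 - gap_open - gap_extend * (g - 1L) +
              diag_sum(qi3, ti3, l3)
            if (s > best) best <- s
          }
        }
      }
    }
  }
  best
}

# Clade support by explicit edge enumeration: walk every internal node via
# the edge matrix, collect its tip set, and read the node label.
oracle_clade_support <- function(tree, taxon_set) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  tipset <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tipset))
  }
  want <- sort(unique(taxon_set))
  if (length(want) >= ntip)
    return(list(monophyletic = FALSE, support = NA_real_))
  for (nd in nodes) {
    if (identical(sort(tipset(nd)), want)) {
      lab <- tree$node.label[nd - ntip]
      return(list(monophyletic = TRUE,
                  support = suppressWarnings(as.numeric(lab))))
    }
  }
  list(monophyletic = FALSE, support = NA_real_)
}

# Alignment rows evolved along a random tree by per-branch substitution:
# the phylogenetically structured instance class the search methods are
# designed for (uniformly random rows are structureless and pathologically
# rugged for hill-climbing).
evolved_rows <- function(n_taxa = 6, n_cols = 30, rate = 0.15) {
  tr <- ape::unroot(ape::rtree(n_taxa))
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G")
  seqs <- list()
  rec <- function(node, seq) {
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    if (!length(kids)) {
      seqs[[tr$tip.label[node]]] <<- seq
      return()
    }
    for (k in kids) {
      s2 <- seq
      mut <- stats::runif(n_cols) < rate
      s2[mut] <- sample(aa, sum(mut), TRUE)
      rec(k, s2)
    }
  }
  rec(n_taxa + 1L, sample(aa, n_cols, TRUE))
  vapply(seqs, paste, character(1), collapse = "")
}

# Random protein alignment rows (possibly with gaps) for parsimony tests.
random_rows <- function(n_taxa, n_cols, gap_frac = 0) {
  aa <- c("A", "R", "N", "D", "C")
  rows <- vapply(seq_len(n_taxa), function(i) {
    ch <- sample(aa, n_cols, replace = TRUE)
    if (gap_frac > 0)
      ch[stats::runif(n_cols) < gap_frac] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  stats::setNames(rows, paste0("t", seq_len(n_taxa)))
}

# Shared small reference set (built once per test run).
test_refset <- local({
  rs <- NULL
  function() {
    if (is.null(rs)) rs <<- synthetic_reference_set()
    rs
  }
})
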
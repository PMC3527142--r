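# Distance computation, neighbor-joining, Fitch parsimony with NNI search,
# bootstrap bipartition support, outgroup rooting and monophyly queries.
# Trees are ape "phylo" objects; bootstrap supports are carried as numeric
# internal node labels (NA on the root).

aln_char_matrix <- function(rows) {
  stopifnot(!is.null(names(rows)))
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("alignment rows must have equal length")
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

# Normalized PAM250 dissimilarity lookup: delta(a,b) =
# (max(s(a,a), s(b,b)) - s(a,b)) / (max(s(a,a), s(b,b)) - min(PAM250)),
# so identical residues score 0 and delta lies in [0, 1]. This is a
# documented stand-in for the unpublished PAUP step-matrix transformation.
pam250_delta_table <- function() {
  if (!is.null(.bhlh_env$delta)) return(.bhlh_env$delta)
  m <- pam250_matrix()
  lev <- rownames(m)
  smin <- min(m)
  self <- diag(m)
  mx <- outer(self, self, pmax)
  d <- (mx - m) / (mx - smin)
  dimnames(d) <- list(lev, lev)
  .bhlh_env$delta <- d
  d
}

#' Pairwise distances between aligned motif rows
#'
#' `pam250_step`: mean, over shared ungapped columns, of a normalized
#' PAM250 dissimilarity (0 for identical residues, 1 for the most dissimilar
#' pair). `p_distance`: proportion of differing shared columns. Columns with
#' a gap in either row are skipped (pairwise deletion); fewer than
#' `min_shared` shared columns is an error.
#'
#' @param rows Named character vector of equal-length gapped rows.
#' @param metric `"pam250_step"` or `"p_distance"`.
#' @param min_shared Minimum shared ungapped columns per pair.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(rows, metric = c("pam250_step", "p_distance"),
                              min_shared = 10L) {
  metric <- match.arg(metric)
  m <- aln_char_matrix(rows)
  dist_from_char(m, metric, min_shared)
}

dist_from_char <- function(m, metric = "pam250_step", min_shared = 10L) {
  n <- nrow(m)
  lab <- rownames(m)
  dt <- pam250_delta_table()
  lev <- rownames(dt)
  out <- matrix(0, n, n, dimnames = list(lab, lab))
  gap <- m == "-"
  mi <- matrix(match(m, lev), n, ncol(m)) # NA for gap/unknown
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(mi[i, ]) & !is.na(mi[j, ])
    if (sum(ok) < min_shared)
      stop("rows ", lab[i], " and ", lab[j], " share fewer than ",
           min_shared, " ungapped columns")
    d <- if (metric == "pam250_step")
      mean(dt[cbind(mi[i, ok], mi[j, ok])])
    else mean(m[i, ok] != m[j, ok])
    out[i, j] <- out[j, i] <- d
  }
  out
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix; negative branch lengths
#' are clamped to zero.
#'
#' @param dm Symmetric distance matrix with taxon dimnames.
#' @return Unrooted `phylo` tree (no supports yet).
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

aln_phyDat <- function(rows) {
  m <- aln_char_matrix(rows)
  m[m == "-"] <- "?" # missing: union-neutral in parsimony
  m[m == "*"] <- "?"
  phangorn::phyDat(m, type = "AA")
}

#' Fitch parsimony score of a tree
#'
#' Sum over alignment columns of the Fitch small-parsimony change counts;
#' gaps are treated as missing data.
#'
#' @param tree A `phylo` whose tip labels are row names of `rows`.
#' @param rows Named character vector of equal-length rows.
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, rows) {
  dat <- aln_phyDat(rows)
  as.integer(phangorn::fitch(tree, dat))
}

#' Maximum-parsimony heuristic search
#'
#' Hill-climb on the Fitch score with nearest-neighbor-interchange moves,
#' starting from the neighbor-joining tree (or a supplied start tree); ties
#' keep the current tree.
#'
#' @param rows Named character vector of equal-length rows.
#' @param start Optional start `phylo`; default is the NJ tree on the
#'   `pam250_step` distances.
#' @return A `phylo` tree with attribute `pscore` (final parsimony score).
#' @export
mp_search <- function(rows, start = NULL) {
  if (is.null(start)) start <- nj_tree(pairwise_distance(rows))
  dat <- aln_phyDat(rows)
  tr <- suppressMessages(
    phangorn::optim.parsimony(start, dat, method = "fitch",
                              rearrangements = "NNI", trace = 0))
  attr(tr, "pscore") <- as.integer(phangorn::fitch(tr, dat))
  tr
}

# ---- splits, clades, supports ---------------------------------------------

node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  lapply(desc, function(ix) sort(tree$tip.label[ix]))
}

split_key <- function(tips_in, all_tips) {
  anchor <- min(all_tips)
  side <- if (anchor %in% tips_in) sort(setdiff(all_tips, tips_in))
  else sort(tips_in)
  paste(side, collapse = "\r")
}

# Non-trivial bipartition keys of an (effectively unrooted) tree.
tree_split_keys <- function(tree) {
  tips <- sort(tree$tip.label)
  sets <- node_tip_sets(tree)
  keys <- vapply(sets, split_key, character(1), all_tips = tips)
  sizes <- vapply(sets, length, integer(1))
  keys[sizes >= 2L & sizes <= length(tips) - 2L]
}

# Clade keys (exact tip sets below each internal node) of a rooted tree.
tree_clade_keys <- function(tree) {
  sets <- node_tip_sets(tree)
  vapply(sets, paste, character(1), collapse = "\r")
}

#' Bootstrap support for a tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with the requested builder, and annotates each internal edge of
#' the tree built from the full alignment with the percentage of replicate
#' trees containing the same bipartition (or, when `outgroup` is given, the
#' same rooted clade). Deterministic for a fixed seed.
#'
#' @param rows Named character vector of equal-length rows.
#' @param tree_builder `"nj"` or `"mp"`.
#' @param reps Number of bootstrap replicates (> 0).
#' @param seed Integer seed.
#' @param outgroup Optional outgroup label; when given, both the base tree
#'   and every replicate are rooted on it and supports count rooted clades.
#' @param metric Distance metric for the NJ builder.
#' @return The base `phylo` tree with numeric `node.label` supports (NA on
#'   the root and on trivial edges).
#' @export
bootstrap_support <- function(rows, tree_builder = c("nj", "mp"), reps = 100L,
                              seed = 1L, outgroup = NULL,
                              metric = "pam250_step") {
  tree_builder <- match.arg(tree_builder)
  if (reps <= 0L) stop("bootstrap reps must be positive")
  m <- aln_char_matrix(rows)
  build <- function(cm) {
    rws <- apply(cm, 1L, paste, collapse = "")
    if (tree_builder == "nj") nj_tree(dist_from_char(cm, metric))
    else mp_search(stats::setNames(rws, rownames(cm)))
  }
  base <- build(m)
  if (!is.null(outgroup)) base <- root_with_outgroup(base, outgroup)
  rep_keys <- with_seed(derive_seed(seed, paste0("boot:", tree_builder)), {
    lapply(seq_len(reps), function(r) {
      cm <- m[, sample.int(ncol(m), replace = TRUE), drop = FALSE]
      tr <- build(cm)
      if (!is.null(outgroup)) {
        tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
        tree_clade_keys(tr)
      } else tree_split_keys(tr)
    })
  })
  count_of <- table(unlist(rep_keys))
  sets <- node_tip_sets(base)
  ntip <- length(base$tip.label)
  labels <- rep(NA_real_, base$Nnode)
  tips_all <- sort(base$tip.label)
  for (k in seq_along(sets)) {
    sz <- length(sets[[k]])
    if (!is.null(outgroup)) {
      if (sz >= length(tips_all)) next # root
      key <- paste(sets[[k]], collapse = "\r")
    } else {
      if (sz < 2L || sz > length(tips_all) - 2L) next
      key <- split_key(sets[[k]], tips_all)
    }
    labels[k] <- 100 * (count_of[key] %||% 0) / reps
    if (is.na(count_of[key])) labels[k] <- 0
  }
  base$node.label <- round(labels, 1)
  base
}

#' Root a tree on an outgroup
#'
#' Places the root on the outgroup's pendant edge. Bootstrap supports held
#' in the node labels are re-attached to the corresponding edges by matching
#' bipartitions, so rooting preserves them; re-rooting is idempotent.
#'
#' @param tree A `phylo`, optionally with numeric node-label supports.
#' @param outgroup Outgroup tip label.
#' @return Rooted `phylo` with supports transferred.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup label not in tree: ", outgroup)
  has_support <- !is.null(tree$node.label)
  sup_map <- NULL
  if (has_support) {
    tips_all <- sort(tree$tip.label)
    sets <- node_tip_sets(tree)
    keys <- vapply(sets, split_key, character(1), all_tips = tips_all)
    sup <- suppressWarnings(as.numeric(tree$node.label))
    sup_map <- stats::setNames(sup, keys)
  }
  rt <- ape::root(ape::unroot(tree), outgroup = outgroup, resolve.root = TRUE)
  if (has_support) {
    tips_all <- sort(rt$tip.label)
    sets <- node_tip_sets(rt)
    lab <- vapply(seq_along(sets), function(k) {
      key <- split_key(sets[[k]], tips_all)
      unname(sup_map[key] %||% NA_real_)
    }, numeric(1))
    lab[vapply(sets, length, integer(1)) >= length(tips_all)] <- NA_real_
    rt$node.label <- lab
  }
  rt
}

#' Support for a clade in a rooted tree
#'
#' If some internal node's descendant tip set equals `taxon_set` exactly,
#' returns that node's support; otherwise reports non-monophyly. The full
#' leaf set (the root) is treated as not monophyletic for pair queries.
#'
#' @param tree Rooted `phylo` with numeric node-label supports.
#' @param taxon_set Character vector of tip labels.
#' @return List with `monophyletic` (logical) and `support` (numeric,
#'   `NA` when not monophyletic or unsupported).
#' @export
clade_support <- function(tree, taxon_set) {
  taxon_set <- sort(unique(taxon_set))
  if (!all(taxon_set %in% tree$tip.label))
    stop("taxon set contains labels absent from the tree")
  if (length(taxon_set) >= length(tree$tip.label))
    return(list(monophyletic = FALSE, support = NA_real_))
  sets <- node_tip_sets(tree)
  key <- paste(taxon_set, collapse = "\r")
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  hit <- match(key, keys)
  if (is.na(hit)) return(list(monophyletic = FALSE, support = NA_real_))
  sup <- if (!is.null(tree$node.label))
    suppressWarnings(as.numeric(tree$node.label[hit])) else NA_real_
  list(monophyletic = TRUE, support = sup)
}
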
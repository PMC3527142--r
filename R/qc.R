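# Acceptance of candidate motifs by the 19-conserved-site statistic, and
# partition of motif positions into basic / helix1 / loop / helix2 regions.

#' Derive the conserved-site specification from a reference alignment
#'
#' The 19 most-conserved alignment columns (by modal-residue frequency among
#' non-gap residues; ties broken towards the lower position) define the site
#' positions; the accepted residue set at each site is every residue observed
#' in at least `min_freq` of the references at that column.
#'
#' @param refset A `reference_set`.
#' @param n_sites Number of sites (19 for the canonical statistic).
#' @param min_freq Frequency threshold for the accepted residue set.
#' @return A `site_spec`: list with `positions` (sorted), `accepted` (named
#'   list of residue vectors keyed by position) and `minima`
#'   (default/Emc/COE acceptance thresholds).
#' @export
derive_site_spec <- function(refset, n_sites = 19L, min_freq = 0.05) {
  stopifnot(inherits(refset, "reference_set"))
  rows <- refset$alignment[setdiff(names(refset$alignment), refset$outgroup)]
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(mat)
  cons <- numeric(L)
  accepted_all <- vector("list", L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col != "-"]
    tab <- table(col) / length(col)
    cons[j] <- max(tab)
    accepted_all[[j]] <- names(tab)[tab >= min_freq]
  }
  positions <- sort(order(-cons, seq_len(L))[seq_len(n_sites)])
  spec <- list(positions = positions,
               accepted = stats::setNames(accepted_all[positions],
                                          as.character(positions)),
               minima = c(default = 10L, Emc = 5L, COE = 8L))
  class(spec) <- "site_spec"
  spec
}

#' Read or write a site specification as YAML
#'
#' @param spec A `site_spec`.
#' @param path File path.
#' @return `read_site_spec()` returns a `site_spec`.
#' @export
write_site_spec <- function(spec, path) {
  stopifnot(inherits(spec, "site_spec"))
  yaml::write_yaml(list(positions = spec$positions,
                        accepted = lapply(spec$accepted, as.list),
                        minima = as.list(spec$minima)), path)
  invisible(path)
}

#' @rdname write_site_spec
#' @export
read_site_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  spec <- list(positions = as.integer(unlist(raw$positions)),
               accepted = lapply(raw$accepted, function(x) unlist(x)),
               minima = unlist(raw$minima))
  if (length(spec$positions) != length(spec$accepted))
    stop("site spec: positions and accepted sets disagree")
  class(spec) <- "site_spec"
  spec
}

#' Score a candidate at the conserved sites
#'
#' Counts matches over the conserved sites of a candidate that has been
#' placed into the 75-position reference coordinate system. A gap at a site
#' counts as a mismatch.
#'
#' @param row75 Character vector of length 75 (candidate residue per motif
#'   position, `-` where absent), as returned in `align_to_profile()$row75`;
#'   a 75-character string is also accepted.
#' @param site_spec A `site_spec`.
#' @param threshold Acceptance threshold (matches required).
#' @return A `conserved_site_score`: list with `matches`, `per_site`
#'   (logical named by position), `accepted`, `threshold_used`.
#' @export
score_conserved_sites <- function(row75, site_spec, threshold = 10L) {
  if (is.character(row75) && length(row75) == 1L)
    row75 <- split_chars(row75)
  if (length(row75) < max(site_spec$positions))
    stop("candidate must be profile-aligned to motif positions before scoring")
  hit <- vapply(seq_along(site_spec$positions), function(k) {
    p <- site_spec$positions[k]
    res <- row75[p]
    res != "-" && res %in% site_spec$accepted[[as.character(p)]]
  }, logical(1))
  names(hit) <- as.character(site_spec$positions)
  out <- list(matches = sum(hit), per_site = hit,
              accepted = sum(hit) >= threshold,
              threshold_used = as.integer(threshold))
  class(out) <- "conserved_site_score"
  out
}

#' Filter candidates by the conserved-site statistic
#'
#' Chooses the acceptance threshold from each candidate's putative family
#' class (`Emc` and `COE` motifs are much shorter than the canonical domain,
#' so their minima are lowered) and splits the input into accepted and
#' rejected lists, recording the rejection reason.
#'
#' @param candidates Named list; each element must carry `row75` (see
#'   [score_conserved_sites()]) and may carry `family_class`.
#' @param site_spec A `site_spec`.
#' @param config A [bhlh_config()] supplying the class minima.
#' @return List with `accepted`, `rejected` (both named lists; each element
#'   gains a `qc` score, rejected ones a `reason`).
#' @export
qc_filter <- function(candidates, site_spec, config = bhlh_config()) {
  accepted <- list(); rejected <- list()
  for (nm in names(candidates)) {
    cand <- candidates[[nm]]
    cls <- cand$family_class %||% "default"
    thr <- switch(cls,
                  Emc = config$conserved_site_min_emc,
                  COE = config$conserved_site_min_coe,
                  config$conserved_site_min)
    sc <- score_conserved_sites(cand$row75, site_spec, threshold = thr)
    cand$qc <- sc
    if (sc$accepted) {
      accepted[[nm]] <- cand
    } else {
      cand$reason <- sprintf("conserved-site matches %d < %d (%s class)",
                             sc$matches, thr, cls)
      rejected[[nm]] <- cand
    }
  }
  list(accepted = accepted, rejected = rejected)
}

#' Assign motif positions to sub-regions
#'
#' @param positions Integer vector of motif positions (1..75).
#' @param region_bounds Region intervals, as in [bhlh_config()].
#' @return Character vector of region names per position.
#' @export
assign_regions <- function(positions, region_bounds = bhlh_config()$region_bounds) {
  validate_region_bounds(region_bounds)
  out <- rep(NA_character_, length(positions))
  for (r in names(region_bounds)) {
    b <- region_bounds[[r]]
    out[positions >= b[1] & positions <= b[2]] <- r
  }
  if (anyNA(out)) stop("position(s) outside 1..75: ",
                       paste(positions[is.na(out)], collapse = ", "))
  out
}
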
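#' Pipeline configuration
#'
#' Builds the configuration object consumed by the scan, QC, alignment,
#' phylogenetics and classification stages. Defaults mirror the published
#' search protocol: a permissive scan threshold standing in for the E = 10
#' translated-BLAST cutoff, acceptance at >= 10 matches over the 19 conserved
#' motif sites (5 for Emc-class and 8 for COE-class candidates, whose motifs
#' are shorter), bipartition support counted as significant at >= 50, and
#' bootstrap defaults of 1000 neighbor-joining and 100 parsimony replicates.
#'
#' @param scan_min_frac Minimum score an assembled candidate must reach,
#'   expressed as a fraction of its query's self-score (default 0.4) - the
#'   stand-in for the permissive E = 10 translated-search cutoff.
#' @param anchor_min_frac Minimum best-frame score (fraction of self-score)
#'   for a query to be pursued with full alignments on a contig.
#' @param scan_top_queries At most this many queries are pursued per contig.
#' @param secondary_min_score Absolute floor for secondary (masked re-scan)
#'   hits that are only used to seed splice-aware joining.
#' @param conserved_site_min Minimum conserved-site matches for acceptance
#'   (default class).
#' @param conserved_site_min_emc,conserved_site_min_coe Adjusted minima for
#'   the Emc and COE family classes.
#' @param support_threshold Bootstrap percentage at or above which a
#'   monophyletic pairing counts as supported.
#' @param nj_bootstrap_reps,mp_bootstrap_reps Bootstrap replicate counts for
#'   the neighbor-joining and parsimony analyses.
#' @param methods Phylogenetic methods run per candidate; any subset of
#'   `c("nj", "mp")`.
#' @param gap_open,gap_extend Affine gap penalties for local and profile
#'   alignment.
#' @param region_bounds Named list of `c(start, end)` position intervals
#'   partitioning motif positions 1..75 into basic, helix1, loop and helix2.
#' @param min_intron_len,max_intron_len Bounds on intron lengths considered
#'   by the GT..AG splice search (bp).
#' @param max_introns Maximum introns reconstructed per gene model.
#' @param intron_margin Minimum score improvement an intron hypothesis must
#'   achieve over contiguous in-frame extension before it is accepted.
#' @param species_prefix Prefix for assigned candidate gene names.
#' @param seed Integer seed controlling all stochastic stages.
#' @return A list of class `bhlh_config`.
#' @export
bhlh_config <- function(scan_min_frac = 0.4,
                        anchor_min_frac = 0.25,
                        scan_top_queries = 10L,
                        secondary_min_score = 20L,
                        conserved_site_min = 10L,
                        conserved_site_min_emc = 5L,
                        conserved_site_min_coe = 8L,
                        support_threshold = 50,
                        nj_bootstrap_reps = 1000L,
                        mp_bootstrap_reps = 100L,
                        methods = c("nj", "mp"),
                        gap_open = 10,
                        gap_extend = 1,
                        region_bounds = list(basic = c(1L, 13L),
                                             helix1 = c(14L, 28L),
                                             loop = c(29L, 59L),
                                             helix2 = c(60L, 75L)),
                        min_intron_len = 4L,
                        max_intron_len = 9000L,
                        max_introns = 2L,
                        intron_margin = 5,
                        species_prefix = "Pa",
                        seed = 1L) {
  stopifnot(scan_min_frac > 0, scan_min_frac <= 1,
            conserved_site_min > 0, conserved_site_min_emc > 0,
            conserved_site_min_coe > 0,
            support_threshold > 0, support_threshold <= 100,
            nj_bootstrap_reps >= 0, mp_bootstrap_reps >= 0,
            gap_open >= 0, gap_extend >= 0,
            min_intron_len >= 4, max_intron_len > min_intron_len)
  methods <- match.arg(methods, c("nj", "mp"), several.ok = TRUE)
  validate_region_bounds(region_bounds)
  cfg <- list(scan_min_frac = scan_min_frac,
              anchor_min_frac = anchor_min_frac,
              scan_top_queries = as.integer(scan_top_queries),
              secondary_min_score = as.integer(secondary_min_score),
              conserved_site_min = as.integer(conserved_site_min),
              conserved_site_min_emc = as.integer(conserved_site_min_emc),
              conserved_site_min_coe = as.integer(conserved_site_min_coe),
              support_threshold = support_threshold,
              nj_bootstrap_reps = as.integer(nj_bootstrap_reps),
              mp_bootstrap_reps = as.integer(mp_bootstrap_reps),
              methods = methods,
              gap_open = gap_open,
              gap_extend = gap_extend,
              region_bounds = lapply(region_bounds, as.integer),
              min_intron_len = as.integer(min_intron_len),
              max_intron_len = as.integer(max_intron_len),
              max_introns = as.integer(max_introns),
              intron_margin = intron_margin,
              species_prefix = species_prefix,
              seed = as.integer(seed))
  class(cfg) <- "bhlh_config"
  cfg
}

# Region bounds must partition 1..75 without gap or overlap.
validate_region_bounds <- function(bounds) {
  need <- c("basic", "helix1", "loop", "helix2")
  if (!identical(sort(names(bounds)), sort(need)))
    stop("region_bounds must name exactly basic, helix1, loop, helix2")
  iv <- do.call(rbind, bounds[need])
  covered <- unlist(lapply(need, function(r) seq.int(bounds[[r]][1], bounds[[r]][2])))
  if (anyDuplicated(covered) || !identical(sort(covered), 1:75))
    stop("region_bounds must partition positions 1..75 without overlap")
  invisible(iv)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path File path.
#' @param config A `bhlh_config` object.
#' @return `read_config()` returns a `bhlh_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$region_bounds))
    raw$region_bounds <- lapply(raw$region_bounds, as.integer)
  do.call(bhlh_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "bhlh_config"))
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.bhlh_config <- function(x, ...) {
  cat("bhlh pipeline configuration\n")
  cat("  scan threshold:", x$scan_min_frac, "x query self-score\n")
  cat("  conserved-site minima: default", x$conserved_site_min,
      "| Emc", x$conserved_site_min_emc, "| COE", x$conserved_site_min_coe, "\n")
  cat("  methods:", paste(x$methods, collapse = "+"),
      sprintf("(NJ %d reps, MP %d reps, support >= %g)\n",
              x$nj_bootstrap_reps, x$mp_bootstrap_reps, x$support_threshold))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
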
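#' Detection configuration
#'
#' Bundles every tunable threshold of the eccDNA detection pipeline in one
#' validated list. Defaults are the published working values of the method:
#' a soft clip must be at least 50 bases to count as junction evidence, a
#' call needs at least two independent structural-read variants, only
#' circles up to 1 Mb are annotated, the confidence tiers cut at >95%
#' internal coverage and a >2-fold mean coverage relative to the summed
#' coverage of the two flanks, overlapping calls merge at >=50% reciprocal
#' overlap, recurrence across samples requires >=90% reciprocal overlap,
#' variant-database co-occurrence requires 99%, RNA junction transcripts
#' tolerate at most a 20-nucleotide start deviation, Monte Carlo nulls use
#' 1,000 randomizations, and saturation curves decimate reads in 10% steps.
#'
#' @param min_softclip_bases minimum clipped bases for soft-clip evidence.
#' @param min_structural_variants minimum distinct supporting reads per call.
#' @param max_circle_size largest circle annotated, in bp.
#' @param coverage_fraction_threshold fraction of covered positions above
#'   which a call leaves the lowq tier (strictly greater than).
#' @param coverage_fold_threshold fold change of internal mean coverage over
#'   the summed flank coverage required for hconf (strictly greater than).
#' @param merge_reciprocal_overlap reciprocal overlap at or above which two
#'   calls are merged.
#' @param recurrence_reciprocal_overlap reciprocal overlap required to count
#'   calls from different samples as the same recurrent circle.
#' @param variantdb_reciprocal_overlap reciprocal overlap for intersection
#'   with external variant intervals.
#' @param rna_max_start_deviation maximum deviation (nt) between a split
#'   transcript's implied start and the circle start.
#' @param mc_randomizations Monte Carlo replicates.
#' @param cluster_tolerance_bp tolerance for grouping inexact evidence
#'   coordinates (about one insert size).
#' @param exact_tolerance_bp tolerance for grouping exact (base-pair
#'   resolution) evidence coordinates.
#' @param realign_kmer seed k-mer length for clipped-fragment realignment.
#' @param realign_min_identity minimum ungapped identity to accept a
#'   realignment locus.
#' @param decimation_step fraction step of the saturation curve.
#' @param min_mapq minimum mapping quality for evidence and coverage reads.
#' @param flank_mode `"sum"` compares the internal mean against the sum of
#'   the two flank means (literal reading of the published rule);
#'   `"mean"` compares against the mean depth over the union of the flanks.
#' @param use_duplicates include duplicate-marked reads (default drops them).
#' @param seed integer seed funnelled to all randomized operations.
#'
#' @return A named list of class `ecc_config`.
#' @export
#' @examples
#' cfg <- detection_config()
#' cfg$min_softclip_bases
detection_config <- function(min_softclip_bases = 50L,
                             min_structural_variants = 2L,
                             max_circle_size = 1000000L,
                             coverage_fraction_threshold = 0.95,
                             coverage_fold_threshold = 2.0,
                             merge_reciprocal_overlap = 0.50,
                             recurrence_reciprocal_overlap = 0.90,
                             variantdb_reciprocal_overlap = 0.99,
                             rna_max_start_deviation = 20L,
                             mc_randomizations = 1000L,
                             cluster_tolerance_bp = 500L,
                             exact_tolerance_bp = 5L,
                             realign_kmer = 15L,
                             realign_min_identity = 0.95,
                             decimation_step = 0.10,
                             min_mapq = 1L,
                             flank_mode = c("sum", "mean"),
                             use_duplicates = FALSE,
                             seed = 1L) {
  flank_mode <- match.arg(flank_mode)
  cfg <- list(
    min_softclip_bases = as.integer(min_softclip_bases),
    min_structural_variants = as.integer(min_structural_variants),
    max_circle_size = as.integer(max_circle_size),
    coverage_fraction_threshold = coverage_fraction_threshold,
    coverage_fold_threshold = coverage_fold_threshold,
    merge_reciprocal_overlap = merge_reciprocal_overlap,
    recurrence_reciprocal_overlap = recurrence_reciprocal_overlap,
    variantdb_reciprocal_overlap = variantdb_reciprocal_overlap,
    rna_max_start_deviation = as.integer(rna_max_start_deviation),
    mc_randomizations = as.integer(mc_randomizations),
    cluster_tolerance_bp = as.integer(cluster_tolerance_bp),
    exact_tolerance_bp = as.integer(exact_tolerance_bp),
    realign_kmer = as.integer(realign_kmer),
    realign_min_identity = realign_min_identity,
    decimation_step = decimation_step,
    min_mapq = as.integer(min_mapq),
    flank_mode = flank_mode,
    use_duplicates = isTRUE(use_duplicates),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "ecc_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$min_softclip_bases > 0L,
    cfg$min_structural_variants > 0L,
    cfg$max_circle_size > 0L,
    cfg$coverage_fraction_threshold > 0, cfg$coverage_fraction_threshold <= 1,
    cfg$coverage_fold_threshold > 0,
    cfg$merge_reciprocal_overlap > 0, cfg$merge_reciprocal_overlap <= 1,
    cfg$recurrence_reciprocal_overlap > 0, cfg$recurrence_reciprocal_overlap <= 1,
    cfg$variantdb_reciprocal_overlap > 0, cfg$variantdb_reciprocal_overlap <= 1,
    cfg$rna_max_start_deviation >= 0L,
    cfg$mc_randomizations >= 1L,
    cfg$cluster_tolerance_bp >= 0L,
    cfg$exact_tolerance_bp >= 0L,
    cfg$realign_kmer > 0L,
    cfg$realign_min_identity > 0, cfg$realign_min_identity <= 1,
    cfg$decimation_step > 0, cfg$decimation_step <= 1,
    cfg$min_mapq >= 0L
  )
  invisible(cfg)
}

#' @export
print.ecc_config <- function(x, ...) {
  cat("eccDNA detection configuration\n")
  for (k in names(x)) cat(sprintf("  %-28s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Spike-in plasmid inventory
#'
#' The control mixture of plasmids added to each sample before circular DNA
#' purification, with lengths and copy numbers: 100 copies pSH63 (6,998 bp),
#' 100 copies pUC19_yEGFP3 (3,397 bp), 10,000 copies YGPM3k20 (26,305 bp),
#' 20,000 copies pBR322 (4,361 bp) and 50,000 copies pUG72 (3,988 bp).
#'
#' @param nuclei_in_sample nuclei the mixture was added to (default 1e6,
#'   the muscle-sample scale).
#' @return data.frame with columns `name`, `length_bp`, `copies_added`,
#'   `nuclei_in_sample`.
#' @export
#' @examples
#' spike_in_controls()
spike_in_controls <- function(nuclei_in_sample = 1e6) {
  stopifnot(nuclei_in_sample > 0)
  data.frame(
    name = c("pSH63", "pUC19_yEGFP3", "YGPM3k20", "pBR322", "pUG72"),
    length_bp = c(6998L, 3397L, 26305L, 4361L, 3988L),
    copies_added = c(100L, 100L, 10000L, 20000L, 50000L),
    nuclei_in_sample = nuclei_in_sample,
    stringsAsFactors = FALSE
  )
}
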
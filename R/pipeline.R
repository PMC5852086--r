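# Pipeline composition: alignments in, confidence-ranked circle table and
# run report out. Deterministic given input and configuration.

#' Detect circles from an alignment set
#'
#' The full detection pass on an already-loaded alignment data.frame:
#' evidence extraction, clustering, coverage-ranked calling, merging and
#' optional gene annotation.
#'
#' @param aln an `ecc_alignments` data.frame ([read_alignments()]).
#' @param cfg a [detection_config()].
#' @param reference optional named `DNAStringSet` enabling
#'   clipped-fragment realignment for reads without a
#'   supplementary-locus annotation.
#' @param genes optional annotation intervals ([read_intervals()]).
#' @param genome an `ecc_genome_index`; defaults to the one attached to
#'   `aln`.
#' @return an `ecc_calls` data.frame with a `run_report` attribute (see
#'   [run_report()]).
#' @export
detect_circles <- function(aln, cfg = detection_config(), reference = NULL,
                           genes = NULL, genome = attr(aln, "genome_index")) {
  validate_config(cfg)
  stopifnot(!is.null(genome))
  t0 <- proc.time()[["elapsed"]]
  ev <- extract_evidence(aln, cfg, reference)
  clusters <- cluster_evidence(ev, cfg)
  cov <- coverage_depth(aln, genome)
  calls <- call_circles(clusters, cov, genome, cfg)
  n_premerge <- nrow(calls)
  drops <- list(few = attr(calls, "n_dropped_few_reads"),
                size = attr(calls, "n_dropped_size"),
                unresolved = attr(calls, "n_dropped_unresolved"))
  calls <- merge_calls(calls, cfg)
  if (!is.null(genes)) calls <- annotate_genes(calls, genes)
  report <- list(
    n_records = nrow(aln),
    n_evidence = nrow(ev),
    n_evidence_split = sum(ev$kind == "split"),
    n_evidence_softclip = sum(ev$kind == "softclip"),
    n_evidence_discordant = sum(ev$kind == "discordant"),
    n_discordant_dropped_span = attr(ev, "n_dropped_span"),
    n_clusters = nrow(clusters),
    n_dropped_few_reads = drops$few,
    n_dropped_size = drops$size,
    n_dropped_unresolved = drops$unresolved,
    n_calls_premerge = n_premerge,
    n_calls = nrow(calls),
    n_hconf = sum(calls$confidence == "hconf"),
    n_conf = sum(calls$confidence == "conf"),
    n_lowq = sum(calls$confidence == "lowq"),
    config = unclass(cfg),
    wall_time_s = proc.time()[["elapsed"]] - t0
  )
  attr(calls, "run_report") <- report
  calls
}

#' Detect circles from a SAM/BAM file
#'
#' Convenience wrapper: reads the alignments (and optionally reference
#' FASTA and gene BED) from disk and runs [detect_circles()].
#'
#' @param alignment_path SAM or BAM file.
#' @param cfg a [detection_config()].
#' @param reference_path optional FASTA.
#' @param genes_path optional BED of gene intervals.
#' @return an `ecc_calls` data.frame with a `run_report` attribute.
#' @export
detect_eccdna <- function(alignment_path, cfg = detection_config(),
                          reference_path = NULL, genes_path = NULL) {
  aln <- read_alignments(alignment_path)
  reference <- if (!is.null(reference_path)) {
    Biostrings::readDNAStringSet(reference_path)
  }
  if (!is.null(reference)) names(reference) <- sub("\\s.*$", "", names(reference))
  genes <- if (!is.null(genes_path)) {
    read_intervals(genes_path, attr(aln, "genome_index"))
  }
  detect_circles(aln, cfg, reference, genes)
}

#' Extract the run report of a detection pass
#'
#' Per-stage counters (records in, evidence by kind, clusters, calls by
#' tier, dropped-by-filter counts), the configuration snapshot, and wall
#' time. The counters reconcile: every cluster is either called or
#' counted in one of the dropped categories.
#'
#' @param calls an `ecc_calls` from [detect_circles()].
#' @return named list.
#' @export
run_report <- function(calls) {
  rep <- attr(calls, "run_report")
  if (is.null(rep)) stop("no run report attached; was this produced by detect_circles()?")
  rep
}
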
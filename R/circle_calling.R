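# Circle calling: junction clusters become confidence-ranked calls by
# comparing internal read coverage against the two flanking regions of the
# same length, then merging near-duplicate calls by reciprocal overlap.

#' Per-base coverage from an alignment set
#'
#' Depth is computed from primary, non-duplicate, mapped records
#' (supplementary and secondary records are excluded to avoid counting a
#' read twice).
#'
#' @param aln an `ecc_alignments` data.frame.
#' @param genome an `ecc_genome_index`; defaults to the one attached to
#'   `aln`.
#' @return an `RleList` of per-base depths, one element per chromosome.
#' @export
coverage_depth <- function(aln, genome = attr(aln, "genome_index")) {
  stopifnot(!is.null(genome))
  keep <- !aln$is_unmapped & !aln$is_secondary & !aln$is_supplementary &
    !aln$is_duplicate
  a <- aln[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(a$chrom, levels = names(genome)),
    ranges = IRanges::IRanges(start = a$start + 1L, end = a$end),
    seqlengths = stats::setNames(as.integer(unclass(genome)), names(genome)))
  GenomicRanges::coverage(gr)
}

#' Coverage statistics for a candidate circle
#'
#' Computes the mean depth and covered fraction over `[start, end)` and
#' the mean depths of the upstream and downstream flanks of the same
#' length. Flanks are truncated at chromosome boundaries (the mean then
#' uses only the available bases); a fully unavailable flank contributes
#' the other flank's mean, doubling it.
#'
#' @param chrom,start,end circle interval (0-based half-open).
#' @param cov an `RleList` from [coverage_depth()].
#' @param genome an `ecc_genome_index`.
#' @return list: `mean_cov`, `fraction_covered`, `flank_up_mean`,
#'   `flank_down_mean`, `flank_sum`, `flank_union_mean`,
#'   `flank_truncated`.
#' @export
coverage_stats <- function(chrom, start, end, cov, genome) {
  chr_len <- unclass(genome)[[chrom]]
  if (is.na(chr_len) || start < 0 || end > chr_len || start >= end) {
    stop("interval outside the genome: ", chrom, ":", start, "-", end)
  }
  v <- cov[[chrom]]
  inside <- S4Vectors::window(v, start + 1L, end)
  L <- end - start
  mean_cov <- sum(as.numeric(S4Vectors::runValue(inside)) *
                    S4Vectors::runLength(inside)) / L
  frac <- sum(S4Vectors::runLength(inside)[S4Vectors::runValue(inside) > 0]) / L

  flank_mean <- function(lo, hi) {  # 0-based half-open, clamped
    lo <- max(0L, lo); hi <- min(chr_len, hi)
    if (hi <= lo) return(list(mean = NA_real_, n = 0L))
    w <- S4Vectors::window(v, lo + 1L, hi)
    list(mean = sum(as.numeric(S4Vectors::runValue(w)) *
                      S4Vectors::runLength(w)) / (hi - lo), n = hi - lo)
  }
  up <- flank_mean(start - L, start)
  down <- flank_mean(end, end + L)
  truncated <- (up$n < L) || (down$n < L)
  um <- up$mean; dm <- down$mean
  if (is.na(um) && is.na(dm)) { um <- 0; dm <- 0 }
  else if (is.na(um)) um <- dm
  else if (is.na(dm)) dm <- um
  union_n <- up$n + down$n
  union_mean <- if (union_n > 0) {
    (ifelse(up$n > 0, up$mean * up$n, 0) + ifelse(down$n > 0, down$mean * down$n, 0)) / union_n
  } else 0
  list(mean_cov = mean_cov, fraction_covered = frac,
       flank_up_mean = um, flank_down_mean = dm,
       flank_sum = um + dm, flank_union_mean = union_mean,
       flank_truncated = truncated)
}

#' Assign a confidence tier to a candidate circle
#'
#' Tiers follow the published three-level ranking: calls whose covered
#' fraction does not exceed `coverage_fraction_threshold` (default 0.95)
#' rest solely on their structural-read variants (`lowq`); above it they
#' are `conf`; and additionally `hconf` when the internal mean coverage is
#' more than `coverage_fold_threshold` (default 2) times the summed
#' coverage of the two adjacent regions of equivalent length.
#'
#' @param stats a list from [coverage_stats()].
#' @param cfg a [detection_config()]; `cfg$flank_mode` selects whether the
#'   fold test compares against the sum of the flank means (`"sum"`, the
#'   default, literal reading) or the mean over the flank union
#'   (`"mean"`).
#' @return `"hconf"`, `"conf"` or `"lowq"`.
#' @export
assign_confidence <- function(stats, cfg = detection_config()) {
  if (stats$fraction_covered <= cfg$coverage_fraction_threshold) return("lowq")
  comparator <- if (cfg$flank_mode == "sum") stats$flank_sum else stats$flank_union_mean
  if (stats$mean_cov > cfg$coverage_fold_threshold * comparator) "hconf" else "conf"
}

#' Call circles from evidence clusters
#'
#' Clusters with at least `min_structural_variants` distinct supporting
#' reads, both consensus coordinates resolved, and a size within
#' `max_circle_size` become calls; each gets coverage statistics and a
#' confidence tier. Everything else is discarded with counters.
#'
#' @param clusters data.frame from [cluster_evidence()].
#' @param cov `RleList` from [coverage_depth()].
#' @param genome an `ecc_genome_index`.
#' @param cfg a [detection_config()].
#' @return `ecc_calls` data.frame with attributes `n_dropped_few_reads`,
#'   `n_dropped_size`, `n_dropped_unresolved`.
#' @export
call_circles <- function(clusters, cov, genome, cfg = detection_config()) {
  empty <- empty_calls()
  if (nrow(clusters) == 0L) return(empty)
  resolved <- !is.na(clusters$consensus_start) & !is.na(clusters$consensus_end) &
    clusters$consensus_start < clusters$consensus_end
  size <- clusters$consensus_end - clusters$consensus_start
  size_ok <- resolved & size <= cfg$max_circle_size & size > 0
  reads_ok <- clusters$n_distinct_reads >= cfg$min_structural_variants
  keep <- resolved & size_ok & reads_ok
  cl <- clusters[keep, , drop = FALSE]
  if (nrow(cl) == 0L) {
    return(structure(empty,
                     n_dropped_few_reads = sum(resolved & size_ok & !reads_ok),
                     n_dropped_size = sum(resolved & !size_ok),
                     n_dropped_unresolved = sum(!resolved)))
  }
  stats <- lapply(seq_len(nrow(cl)), function(i)
    coverage_stats(cl$chrom[i], cl$consensus_start[i], cl$consensus_end[i],
                   cov, genome))
  calls <- data.frame(
    chrom = cl$chrom,
    start = cl$consensus_start,
    end = cl$consensus_end,
    size_bp = cl$consensus_end - cl$consensus_start,
    confidence = vapply(stats, assign_confidence, "", cfg = cfg),
    n_reads = cl$n_distinct_reads,
    n_split = cl$n_split,
    n_softclip = cl$n_softclip,
    n_discordant = cl$n_discordant,
    mean_coverage = vapply(stats, `[[`, 0, "mean_cov"),
    coverage_fraction = vapply(stats, `[[`, 0, "fraction_covered"),
    flank_coverage_sum = vapply(stats, `[[`, 0, "flank_sum"),
    gene_names = "",
    n_merged = 1L,
    stringsAsFactors = FALSE
  )
  o <- order(calls$chrom, calls$start, calls$end, calls$confidence)
  calls <- calls[o, , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls,
            class = c("ecc_calls", "data.frame"),
            n_dropped_few_reads = sum(resolved & size_ok & !reads_ok),
            n_dropped_size = sum(resolved & !size_ok),
            n_dropped_unresolved = sum(!resolved))
}

empty_calls <- function() {
  structure(data.frame(chrom = character(), start = integer(), end = integer(),
                       size_bp = integer(), confidence = character(),
                       n_reads = integer(), n_split = integer(),
                       n_softclip = integer(), n_discordant = integer(),
                       mean_coverage = numeric(), coverage_fraction = numeric(),
                       flank_coverage_sum = numeric(), gene_names = character(),
                       n_merged = integer(), stringsAsFactors = FALSE),
            class = c("ecc_calls", "data.frame"))
}

#' Reciprocal overlap of two genomic intervals
#'
#' `min(overlap/|a|, overlap/|b|)`; 0 for different chromosomes or
#' disjoint intervals. Symmetric.
#'
#' @param a,b lists or one-row data.frames with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' reciprocal_overlap(list(chrom = "c", start = 0, end = 100),
#'                    list(chrom = "c", start = 50, end = 150))
reciprocal_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ro_vec(a$start, a$end, b$start, b$end)
}

ro_vec <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  ifelse(ov == 0, 0, pmin(ov / (e1 - s1), ov / (e2 - s2)))
}

#' Merge near-duplicate circle calls
#'
#' Calls with reciprocal overlap at or above `merge_reciprocal_overlap`
#' (default 0.50) are collapsed by transitive closure; below the threshold
#' both calls are kept, since circles may derive repeatedly from the same
#' locus in close proximity. The representative of a merged group is the
#' member with the most distinct evidence reads (ties: larger covered
#' fraction, then leftmost); its `n_merged` records the group size and
#' `merged_members` the constituents. Idempotent and order-independent.
#'
#' @param calls an `ecc_calls` data.frame.
#' @param cfg a [detection_config()].
#' @return merged `ecc_calls` data.frame with a `merged_members` list
#'   attribute (one data.frame of constituents per output row).
#' @export
merge_calls <- function(calls, cfg = detection_config()) {
  if (nrow(calls) <= 1L) {
    attr(calls, "merged_members") <- lapply(seq_len(nrow(calls)),
                                            function(i) as.data.frame(calls)[i, ])
    return(calls)
  }
  df <- as.data.frame(calls)
  o <- order(df$chrom, df$start, df$end, df$confidence, -df$n_reads)
  df <- df[o, , drop = FALSE]
  n <- nrow(df)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ro <- ro_vec(df$start[qi], df$end[qi], df$start[si], df$end[si])
  link <- ro >= cfg$merge_reciprocal_overlap
  parent <- seq_len(n)
  for (k in which(link)) {
    ri <- uf_find(parent, qi[k]); rj <- uf_find(parent, si[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  groups <- split(seq_len(n), root)
  reps <- vapply(groups, function(g) {
    m <- df[g, , drop = FALSE]
    g[order(-m$n_reads, -m$coverage_fraction, m$start, m$end)[1]]
  }, integer(1))
  out <- df[reps, , drop = FALSE]
  out$n_merged <- vapply(groups, function(g) sum(df$n_merged[g]), integer(1))
  members <- lapply(groups, function(g) df[g, , drop = FALSE])
  o2 <- order(out$chrom, out$start, out$end)
  out <- out[o2, , drop = FALSE]
  members <- members[o2]
  rownames(out) <- NULL
  structure(out, class = c("ecc_calls", "data.frame"),
            merged_members = members)
}

#' Annotate calls with overlapping gene names
#'
#' Any positive overlap (1 bp suffices) adds the gene; names are sorted
#' and deduplicated into the comma-separated `gene_names` column.
#'
#' @param calls an `ecc_calls` data.frame.
#' @param genes data.frame from [read_intervals()] (`chrom`, `start`,
#'   `end`, `name`).
#' @return `calls` with `gene_names` filled in.
#' @export
annotate_genes <- function(calls, genes) {
  if (nrow(calls) == 0L || nrow(genes) == 0L) return(calls)
  gr_c <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$start + 1L, calls$end))
  gr_g <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_c, gr_g)
  lst <- split(genes$name[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits))
  calls$gene_names <- ""
  for (k in names(lst)) {
    calls$gene_names[as.integer(k)] <- paste(sort(unique(lst[[k]])), collapse = ",")
  }
  calls
}

#' Per-sample summary of circle calls
#'
#' Counts by confidence tier, the frequency of distinct circles per 100
#' nuclei, and a size histogram in 0.1 log10-kb bins.
#'
#' @param calls an `ecc_calls` data.frame.
#' @param nuclei_count number of nuclei the sample derives from.
#' @return list: `n_hconf`, `n_conf`, `n_lowq`, `n_total`,
#'   `per_100_nuclei`, `size_hist` (data.frame `log10_kb_bin`, `count`).
#' @export
#' @examples
#' summarize_sample(empty_calls_public(), nuclei_count = 1e6)$n_total
summarize_sample <- function(calls, nuclei_count) {
  stopifnot(nuclei_count > 0)
  n_total <- nrow(calls)
  conf <- calls$confidence
  hist <- if (n_total > 0) {
    bin <- floor(log10(calls$size_bp / 1000) / 0.1) * 0.1
    tab <- table(bin)
    data.frame(log10_kb_bin = as.numeric(names(tab)),
               count = as.integer(tab))
  } else data.frame(log10_kb_bin = numeric(), count = integer())
  list(n_hconf = sum(conf == "hconf"),
       n_conf = sum(conf == "conf"),
       n_lowq = sum(conf == "lowq"),
       n_total = n_total,
       per_100_nuclei = n_total / nuclei_count * 100,
       size_hist = hist)
}

#' An empty call table
#'
#' Convenience constructor of an `ecc_calls` data.frame with zero rows,
#' useful as a degenerate input.
#' @return empty `ecc_calls` data.frame.
#' @export
empty_calls_public <- function() empty_calls()
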
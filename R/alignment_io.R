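# Alignment and interval I/O. One coordinate convention everywhere:
# internal coordinates are 0-based half-open ([start, end)), SAM input is
# converted on read, BED output needs no conversion.

#' Build a genome index
#'
#' @param lengths named numeric vector of chromosome lengths (bp).
#' @return object of class `ecc_genome_index`: the named vector with a
#'   `total_length` attribute.
#' @export
#' @examples
#' genome_index(c(chr1 = 1e6, chr2 = 5e5))
genome_index <- function(lengths) {
  stopifnot(length(lengths) > 0, !is.null(names(lengths)),
            !anyDuplicated(names(lengths)), all(lengths > 0))
  structure(stats::setNames(as.numeric(lengths), names(lengths)),
            total_length = sum(as.numeric(lengths)),
            class = "ecc_genome_index")
}

#' Read aligned reads from a SAM or BAM file
#'
#' Parses coordinate-sorted paired-end alignments into one record per
#' alignment line with the geometry the junction-evidence extractor needs:
#' 0-based half-open reference coordinates, leading/trailing clip lengths,
#' the soft-clipped sequence itself, mate position and strand, and the
#' locus of any supplementary alignment (`SA` tag). Secondary,
#' supplementary, duplicate and unmapped records are flagged, not dropped.
#'
#' @param path SAM (text) or BAM file. SAM files are converted through
#'   `Rsamtools::asBam()`, so a header with `@SQ` lines is required.
#' @return data.frame of class `ecc_alignments`, one row per record, with
#'   a `genome_index` attribute built from the header.
#' @export
read_alignments <- function(path) {
  stopifnot(file.exists(path))
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE),
      error = function(e) stop("failed to parse SAM (missing/invalid header?): ",
                               conditionMessage(e), call. = FALSE))
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (length(hdr) == 0L) stop("alignment header carries no sequence lines")
  gi <- genome_index(hdr)

  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "mrnm", "mpos", "seq"),
    tag = "SA")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  flag <- b$flag
  seqs <- as.character(b$seq)
  cig <- b$cigar

  unmapped <- bitwAnd(flag, 4L) > 0L
  refw <- rep(NA_integer_, n)
  refw[!unmapped] <- cigar_ref_width(cig[!unmapped])
  clips <- cigar_clips(ifelse(unmapped, "*", cig))

  # record-level sanity: query width must match SEQ where SEQ is stored
  qw <- rep(NA_integer_, n)
  qw[!unmapped] <- cigar_query_width(cig[!unmapped])
  has_seq <- !is.na(seqs) & seqs != "" & seqs != "*"
  bad <- which(!unmapped & has_seq & qw != nchar(seqs))
  if (length(bad)) {
    stop("CIGAR/sequence length mismatch for read(s): ",
         paste(utils::head(b$qname[bad], 3), collapse = ", "))
  }

  start <- ifelse(unmapped, NA_integer_, b$pos - 1L)
  clip_left_seq <- ifelse(has_seq & clips$left_soft > 0L,
                          substring(seqs, 1L, clips$left_soft), NA_character_)
  clip_right_seq <- ifelse(has_seq & clips$right_soft > 0L,
                           substring(seqs, nchar(seqs) - clips$right_soft + 1L,
                                     nchar(seqs)), NA_character_)

  sa <- b$tag$SA
  if (is.null(sa)) sa <- rep(NA_character_, n)
  sa_first <- sub(";.*$", "", sa)
  sa_first[is.na(sa_first)] <- ""
  sa_parts <- strsplit(as.character(sa_first), ",", fixed = TRUE)
  sa_ok <- vapply(sa_parts, length, integer(1)) >= 4L
  sa_chrom <- ifelse(sa_ok, vapply(sa_parts, function(x) x[1], ""), NA_character_)
  sa_start <- ifelse(sa_ok,
                     suppressWarnings(as.integer(vapply(sa_parts, function(x) x[2], ""))) - 1L,
                     NA_integer_)
  sa_strand <- ifelse(sa_ok, vapply(sa_parts, function(x) x[3], ""), NA_character_)
  sa_cigar <- ifelse(sa_ok, vapply(sa_parts, function(x) x[4], ""), NA_character_)
  sa_refw <- rep(NA_integer_, n)
  sa_refw[sa_ok] <- cigar_ref_width(sa_cigar[sa_ok])

  mate_mapped <- bitwAnd(flag, 8L) == 0L & bitwAnd(flag, 1L) > 0L

  df <- data.frame(
    read_name = b$qname,
    chrom = as.character(b$rname),
    start = start,
    end = start + refw,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = b$mapq,
    cigar = cig,
    is_read1 = bitwAnd(flag, 64L) > 0L,
    is_paired = bitwAnd(flag, 1L) > 0L,
    is_secondary = bitwAnd(flag, 256L) > 0L,
    is_supplementary = bitwAnd(flag, 2048L) > 0L,
    is_duplicate = bitwAnd(flag, 1024L) > 0L,
    is_unmapped = unmapped,
    mate_chrom = ifelse(mate_mapped, as.character(b$mrnm), NA_character_),
    mate_start = ifelse(mate_mapped, b$mpos - 1L, NA_integer_),
    mate_strand = ifelse(mate_mapped,
                         ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
                         NA_character_),
    left_clip_len = clips$left_len,
    right_clip_len = clips$right_len,
    clipped_seq_left = clip_left_seq,
    clipped_seq_right = clip_right_seq,
    sa_chrom = sa_chrom,
    sa_start = sa_start,
    sa_strand = sa_strand,
    sa_ref_width = sa_refw,
    stringsAsFactors = FALSE
  )
  structure(df, genome_index = gi, class = c("ecc_alignments", "data.frame"))
}

#' Read genomic intervals from a BED(-like) file
#'
#' @param path BED file (0-based half-open; 3+ columns).
#' @param genome optional `ecc_genome_index`; intervals on unknown
#'   chromosomes are skipped with a warning and counted.
#' @return data.frame with columns `chrom`, `start`, `end`, `name` and an
#'   attribute `n_skipped`.
#' @export
read_intervals <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(df$start >= df$end)) {
    stop("interval with start >= end at line(s) ",
         paste(utils::head(which(df$start >= df$end), 3), collapse = ", "))
  }
  n_skipped <- 0L
  if (!is.null(genome)) {
    known <- df$chrom %in% names(genome)
    n_skipped <- sum(!known)
    if (n_skipped > 0L) {
      warning(n_skipped, " interval(s) on unknown chromosomes skipped")
      df <- df[known, , drop = FALSE]
    }
    bad <- df$end > unclass(genome)[df$chrom]
    if (any(bad)) stop("interval extends past chromosome end")
  }
  rownames(df) <- NULL
  structure(df, n_skipped = n_skipped)
}

#' Write (and read back) a circle call table
#'
#' Writes one row per call, ordered by (chrom, start, end), with BED-style
#' 0-based half-open coordinates, plus a companion BED file of the call
#' intervals. Coverage statistics are reported to two decimals
#' (`coverage_fraction` to four, as the 0.95 tier boundary needs them).
#'
#' @param calls an `ecc_calls` data.frame (see [call_circles()]).
#' @param path output path of the tab-separated table.
#' @param bed_path companion BED path; default replaces the extension of
#'   `path` with `.bed`.
#' @return invisibly, the written data.frame.
#' @export
write_circle_table <- function(calls, path,
                               bed_path = paste0(tools::file_path_sans_ext(path), ".bed")) {
  cols <- c("chrom", "start", "end", "size_bp", "confidence", "n_reads",
            "n_split", "n_softclip", "n_discordant", "mean_coverage",
            "coverage_fraction", "flank_coverage_sum", "gene_names")
  df <- as.data.frame(calls)[, intersect(cols, names(calls)), drop = FALSE]
  for (miss in setdiff(cols, names(df))) df[[miss]] <- NA
  df <- df[, cols]
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  out <- df
  out$mean_coverage <- sprintf("%.2f", df$mean_coverage)
  out$flank_coverage_sum <- sprintf("%.2f", df$flank_coverage_sum)
  out$coverage_fraction <- sprintf("%.4f", df$coverage_fraction)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- df[, c("chrom", "start", "end")]
  bed$name <- sprintf("%s:%d-%d|%s", df$chrom, df$start, df$end, df$confidence)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(df)
}

#' @rdname write_circle_table
#' @export
read_circle_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(gene_names = "character"))
  df$gene_names[is.na(df$gene_names)] <- ""
  class(df) <- c("ecc_calls", "data.frame")
  df
}
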
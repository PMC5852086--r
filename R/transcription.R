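# Transcription across circle junctions. An RNA read whose left part
# aligns downstream (3') of its right part -- back-splice geometry --
# evidences transcription running across the junction of a circle.

#' Split-transcript reads from a table or from split alignments
#'
#' `read_split_transcripts()` reads a tab-separated table with columns
#' `read_name`, `chrom`, `left_start`, `left_end`, `right_start`,
#' `right_end` and optionally `n_loci` (multi-mapping count of the
#' junction sequence; defaults to 1). `split_transcript_reads()` derives
#' the same table from an `ecc_alignments` data.frame in which each split
#' read appears as a primary plus a supplementary record: the record
#' covering the first portion of the query (smaller leading clip) is the
#' left part. Only same-chromosome, same-strand pairs in back-splice
#' orientation (left part downstream of right part) are kept.
#'
#' @param path tab-separated file with header.
#' @return data.frame of split-transcript reads with an
#'   `implied_start`/`implied_end` interval (right-part start to
#'   left-part end, 0-based half-open).
#' @export
read_split_transcripts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("read_name", "chrom", "left_start", "left_end",
            "right_start", "right_end")
  stopifnot(all(need %in% names(df)))
  if (is.null(df$n_loci)) df$n_loci <- 1L
  finish_split_reads(df)
}

#' @rdname read_split_transcripts
#' @param aln an `ecc_alignments` data.frame of RNA split alignments.
#' @export
split_transcript_reads <- function(aln) {
  a <- aln[!aln$is_unmapped & !aln$is_secondary & !aln$is_duplicate, , drop = FALSE]
  out <- lapply(split(seq_len(nrow(a)), a$read_name), function(idx) {
    if (length(idx) != 2L) return(NULL)
    x <- a[idx, , drop = FALSE]
    if (x$chrom[1] != x$chrom[2] || x$strand[1] != x$strand[2]) return(NULL)
    left_i <- which.min(x$left_clip_len)   # first portion of the query
    right_i <- 3L - left_i
    data.frame(read_name = x$read_name[1], chrom = x$chrom[1],
               left_start = x$start[left_i], left_end = x$end[left_i],
               right_start = x$start[right_i], right_end = x$end[right_i],
               n_loci = 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) out <- data.frame(read_name = character(), chrom = character(),
                                      left_start = integer(), left_end = integer(),
                                      right_start = integer(), right_end = integer(),
                                      n_loci = integer(), stringsAsFactors = FALSE)
  finish_split_reads(out)
}

finish_split_reads <- function(df) {
  # back-splice geometry: left part downstream of right part
  keep <- df$left_start >= df$right_start & df$right_start < df$left_end
  df <- df[keep, , drop = FALSE]
  df$implied_start <- df$right_start
  df$implied_end <- df$left_end
  rownames(df) <- NULL
  df
}

#' Detect transcription across circle junctions
#'
#' A split-transcript read supports a circle when its implied interval
#' (right-part start to left-part end) lies entirely within the circle
#' and its start deviates from the circle start by at most
#' `rna_max_start_deviation` nucleotides (default 20; larger deviations
#' are discarded as likely trans-splicing). Only circles with at least
#' one soft-clip or split evidence -- i.e. exact junction coordinates --
#' are eligible; reads on the mitochondrial sequence are excluded.
#'
#' @param rna split-transcript reads (see [read_split_transcripts()]).
#' @param calls an `ecc_calls` data.frame.
#' @param cfg a [detection_config()].
#' @param mito_chroms chromosome names treated as mitochondrial.
#' @return data.frame of transcribed circles: circle coordinates,
#'   `n_supporting`, `rank` (see [rank_transcribed_circle()]) and a list
#'   column `reads`.
#' @export
detect_junction_transcripts <- function(rna, calls, cfg = detection_config(),
                                        mito_chroms = c("chrM", "MT")) {
  calls <- as.data.frame(calls)
  eligible <- calls[(calls$n_split + calls$n_softclip) >= 1L, , drop = FALSE]
  rna <- rna[!rna$chrom %in% mito_chroms, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      confidence = character(), n_supporting = integer(),
                      rank = character(), stringsAsFactors = FALSE)
  empty$reads <- list()
  if (nrow(eligible) == 0L || nrow(rna) == 0L) return(empty)
  recs <- lapply(seq_len(nrow(eligible)), function(i) {
    circ <- eligible[i, ]
    same <- rna$chrom == circ$chrom
    contained <- same & rna$implied_start >= circ$start & rna$implied_end <= circ$end
    close_start <- abs(rna$implied_start - circ$start) <= cfg$rna_max_start_deviation
    sup <- rna[contained & close_start, , drop = FALSE]
    if (nrow(sup) == 0L) return(NULL)
    rec <- data.frame(chrom = circ$chrom, start = circ$start, end = circ$end,
                      confidence = circ$confidence, n_supporting = nrow(sup),
                      rank = rank_transcribed_circle(sup, circ$start, circ$end),
                      stringsAsFactors = FALSE)
    rec$reads <- list(sup)
    rec
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0L) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Rank a transcribed circle
#'
#' `hconf`: some supporting read matches both circle coordinates
#' perfectly and its junction sequence is unique in the genome
#' (`n_loci == 1`). `conf`: a perfect both-end match whose junction
#' sequence occurs at multiple loci. `lowq`: only one coordinate matches
#' and the read is multi-mapping. Adding a perfectly matching unique read
#' never lowers a circle's rank.
#'
#' @param reads data.frame of supporting split-transcript reads
#'   (`implied_start`, `implied_end`, `n_loci`).
#' @param circle_start,circle_end the circle's junction coordinates.
#' @return `"hconf"`, `"conf"` or `"lowq"`.
#' @export
rank_transcribed_circle <- function(reads, circle_start, circle_end) {
  n_loci <- reads$n_loci
  n_loci[is.na(n_loci)] <- 1L
  both <- reads$implied_start == circle_start & reads$implied_end == circle_end
  if (any(both & n_loci == 1L)) return("hconf")
  if (any(both & n_loci > 1L)) return("conf")
  "lowq"
}

#' Count acceptable genomic loci of a junction-spanning sequence
#'
#' Realigns the sequence over every chromosome with the clipped-fragment
#' realigner's seeding-and-identity rule and counts accepted loci; a
#' desk-scale substitute for a genome-wide aligner's mapping-quality
#' flag.
#'
#' @param sequence nucleotide string.
#' @param reference named `DNAStringSet`.
#' @param cfg a [detection_config()].
#' @return integer count of loci with identity at or above
#'   `realign_min_identity`.
#' @export
count_genomic_loci <- function(sequence, reference, cfg = detection_config()) {
  len <- nchar(sequence)
  max_mm <- floor((1 - cfg$realign_min_identity) * len)
  total <- 0L
  for (chr in names(reference)) {
    hits <- Biostrings::matchPattern(sequence, reference[[chr]],
                                     max.mismatch = max_mm)
    total <- total + length(hits)
  }
  total
}

#' Monte Carlo p-value for circle / transcript overlap
#'
#' Randomizes both interval sets on the genome (lengths preserved,
#' chromosome weighted by length, intervals wholly within chromosomes)
#' `mc_randomizations` times and counts the replicates whose number of
#' overlapping circle-transcript pairs reaches the observed number;
#' `p = (hits + 1) / (n + 1)`.
#'
#' @param circles data.frame of intervals (`chrom`, `start`, `end`).
#' @param transcripts data.frame of intervals (`chrom`, `start`, `end`).
#' @param genome an `ecc_genome_index`.
#' @param cfg a [detection_config()].
#' @param seed RNG seed.
#' @return empirical p-value in `[1/(n+1), 1]`.
#' @export
monte_carlo_overlap_p <- function(circles, transcripts, genome,
                                  cfg = detection_config(), seed = cfg$seed) {
  n <- cfg$mc_randomizations
  if (nrow(circles) == 0L || nrow(transcripts) == 0L) {
    warning("empty interval set; p = 1")
    return(1)
  }
  count_overlaps <- function(a, b) {
    total <- 0L
    for (chr in unique(a$chrom)) {
      ai <- a[a$chrom == chr, , drop = FALSE]
      bi <- b[b$chrom == chr, , drop = FALSE]
      if (nrow(bi) == 0L) next
      for (i in seq_len(nrow(ai))) {
        total <- total + sum(bi$start < ai$end[i] & bi$end > ai$start[i])
      }
    }
    total
  }
  observed <- count_overlaps(circles, transcripts)
  set.seed(seed)
  len_c <- circles$end - circles$start
  len_t <- transcripts$end - transcripts$start
  hits <- 0L
  for (r in seq_len(n)) {
    rc <- place_random_intervals(len_c, genome)
    rt <- place_random_intervals(len_t, genome)
    if (count_overlaps(rc, rt) >= observed) hits <- hits + 1L
  }
  (hits + 1) / (n + 1)
}
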
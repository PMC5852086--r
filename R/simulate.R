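# Synthetic-data generator: toy genomes, planted circles, spike-ins, and
# DNA/RNA reads with the exact junction geometry the detector consumes.
# The simulator emits post-alignment records directly (what an ideal
# aligner would report), so the package's scope can begin at aligned
# reads; sequences are real substrings of the toy genome, so the
# clipped-fragment realigner can be exercised against them.

#' Simulate a toy genome
#'
#' @param lengths named vector of chromosome lengths.
#' @param gc_content target GC fraction.
#' @param seed RNG seed; the same seed reproduces the sequence exactly.
#' @return list: `seqs` (named `DNAStringSet`), `index`
#'   (`ecc_genome_index`).
#' @export
#' @examples
#' g <- simulate_genome(c(chr1 = 2e4), seed = 1)
simulate_genome <- function(lengths, gc_content = 0.5, seed = 1L) {
  stopifnot(!is.null(names(lengths)), all(lengths > 0),
            gc_content > 0, gc_content < 1)
  set.seed(seed)
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  seqs <- vapply(lengths, function(L) {
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
           collapse = "")
  }, character(1))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- names(lengths)
  list(seqs = dss, index = genome_index(lengths))
}

#' Plant circles on a genome
#'
#' Samples circle sizes from a two-component log-normal mixture whose
#' modes default to 0.1 kb and 5 kb (the two characteristic size peaks of
#' circle-enriched libraries) and places non-overlapping intervals
#' uniformly, keeping a flank-sized margin between circles so that
#' coverage flanks stay unconfounded. Copy numbers follow a log-normal
#' scaled by `(size/ref)^-alpha`, a phenomenological stand-in for the
#' small-template bias of rolling-circle amplification.
#'
#' @param genome list from [simulate_genome()].
#' @param n number of circles.
#' @param size_model list: `meanlog`, `sdlog`, `weights` (two components),
#'   `min_size`, or `fixed` for a degenerate size.
#' @param copy_model list: `meanlog`, `sdlog`, `alpha`, `ref_size`.
#' @param seed RNG seed.
#' @param max_tries placement retries before giving up.
#' @return `sim_truth` list: `genome`, `circles` (data.frame `circle_id`,
#'   `chrom`, `start`, `end`, `size_bp`, `copy_number`), `seed`.
#' @export
plant_circles <- function(genome, n,
                          size_model = list(meanlog = c(log(100), log(5000)),
                                            sdlog = c(0.25, 0.3),
                                            weights = c(0.5, 0.5),
                                            min_size = 60),
                          copy_model = list(meanlog = log(2), sdlog = 0.5,
                                            alpha = 1, ref_size = 1000),
                          seed = 1L, max_tries = 1000L * max(n, 1L)) {
  set.seed(seed)
  index <- genome$index
  draw_size <- function() {
    if (!is.null(size_model$fixed)) return(as.integer(size_model$fixed))
    k <- sample.int(2L, 1L, prob = size_model$weights)
    max(size_model$min_size,
        round(stats::rlnorm(1, size_model$meanlog[k], size_model$sdlog[k])))
  }
  circles <- data.frame(circle_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        size_bp = integer(), copy_number = integer(),
                        stringsAsFactors = FALSE)
  if (n == 0L) return(new_sim_truth(genome, circles, seed))
  chr_len <- as.numeric(unclass(index))
  placed <- list()
  tries <- 0L
  while (nrow(circles) < n) {
    tries <- tries + 1L
    if (tries > max_tries) stop("could not place circles without overlap; ",
                                "genome too small for n = ", n)
    L <- draw_size()
    fit <- chr_len >= 3 * L  # room for the circle plus both flanks
    if (!any(fit)) next
    w <- chr_len * fit
    ci <- sample.int(length(chr_len), 1L, prob = w / sum(w))
    s <- floor(stats::runif(1, L, chr_len[ci] - 2 * L))
    e <- s + L
    chr <- names(index)[ci]
    clash <- FALSE
    for (pl in placed) {
      if (pl$chrom == chr && s - L < pl$end + pl$len && e + L > pl$start - pl$len) {
        clash <- TRUE; break
      }
    }
    if (clash) next
    placed[[length(placed) + 1L]] <- list(chrom = chr, start = s, end = e, len = L)
    cn <- max(1L, as.integer(round(
      stats::rlnorm(1, copy_model$meanlog, copy_model$sdlog) *
        (L / copy_model$ref_size)^(-copy_model$alpha))))
    circles <- rbind(circles, data.frame(
      circle_id = sprintf("circ%04d", nrow(circles) + 1L),
      chrom = chr, start = as.integer(s), end = as.integer(e),
      size_bp = L, copy_number = cn, stringsAsFactors = FALSE))
  }
  new_sim_truth(genome, circles, seed)
}

new_sim_truth <- function(genome, circles, seed) {
  structure(list(genome = genome, circles = circles, seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("simulated truth:", nrow(x$circles), "circles on",
      length(x$genome$index), "chromosome(s)\n")
  invisible(x)
}

# --- read emission -----------------------------------------------------

# Map a read of length rl starting at circle offset q0 (0-based) on
# circle [s, e) of length L. Returns the primary alignment geometry in
# forward reference coordinates: pos/cigar, clip side and length, and
# the supplementary locus of the clipped fragment. SAM stores every SEQ
# in forward orientation, so the same geometry serves both strands.
map_circle_read <- function(s, e, L, q0, rl) {
  q0 <- q0 %% L
  if (q0 + rl <= L) {
    return(list(pos = s + q0, end = s + q0 + rl,
                cigar = sprintf("%dM", rl), wraps = FALSE, clip_len = 0L))
  }
  a <- L - q0            # first part, aligns at [s + q0, e)
  cc <- rl - a           # second part, wraps to [s, s + cc)
  if (a >= cc) {
    list(pos = s + q0, end = e, cigar = sprintf("%dM%dS", a, cc),
         wraps = TRUE, clip_side = "right", clip_len = cc,
         sa_pos = s, sa_cigar = sprintf("%dS%dM", a, cc))
  } else {
    list(pos = s, end = s + cc, cigar = sprintf("%dS%dM", a, cc),
         wraps = TRUE, clip_side = "left", clip_len = a,
         sa_pos = e - a, sa_cigar = sprintf("%dM%dS", a, cc))
  }
}

# Forward-orientation sequence of a (possibly wrapping) circle read.
circle_read_seq <- function(chr_str, s, e, L, q0, rl) {
  q0 <- q0 %% L
  if (q0 + rl <= L) {
    substring(chr_str, s + q0 + 1L, s + q0 + rl)
  } else {
    a <- L - q0
    paste0(substring(chr_str, s + q0 + 1L, e),
           substring(chr_str, s + 1L, s + (rl - a)))
  }
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste0(v, collapse = "")
}

sam_record <- function(qname, chrom, g, strand, seq, mate_pos, mate_strand,
                       first, paired = TRUE) {
  flag <- if (paired) 1L + (if (first) 64L else 128L) else 0L
  if (strand == "-") flag <- flag + 16L
  if (paired && mate_strand == "-") flag <- flag + 32L
  sa <- NA_character_
  if (isTRUE(g$wraps)) {
    sa <- sprintf("%s,%d,%s,%s,60,0;", chrom, g$sa_pos + 1L, strand, g$sa_cigar)
  }
  list(qname = qname, flag = flag, chrom = chrom, pos = g$pos, mapq = 60L,
       cigar = g$cigar, mate_chrom = if (paired) "=" else "*",
       mate_pos = if (paired) mate_pos else -1L, seq = seq, sa = sa)
}

records_to_df <- function(recs) {
  if (length(recs) == 0L) {
    return(data.frame(qname = character(), flag = integer(),
                      chrom = character(), pos = numeric(), mapq = integer(),
                      cigar = character(), mate_chrom = character(),
                      mate_pos = numeric(), seq = character(),
                      sa = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    qname = vapply(recs, `[[`, "", "qname"),
    flag = vapply(recs, `[[`, 0L, "flag"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    pos = vapply(recs, function(r) as.numeric(r$pos), 0),
    mapq = vapply(recs, `[[`, 0L, "mapq"),
    cigar = vapply(recs, `[[`, "", "cigar"),
    mate_chrom = vapply(recs, `[[`, "", "mate_chrom"),
    mate_pos = vapply(recs, function(r) as.numeric(r$mate_pos), 0),
    seq = vapply(recs, `[[`, "", "seq"),
    sa = vapply(recs, `[[`, "", "sa"),
    stringsAsFactors = FALSE)
}

#' Simulate circle-enriched paired-end DNA reads
#'
#' Samples fragments on circular coordinates (wrapping at the junction)
#' and emits what an ideal aligner would report: a read crossing the
#' junction becomes a soft-clipped primary alignment (clipped sequence
#' included) with a supplementary-locus annotation for the clipped part;
#' a pair straddling the junction with neither read crossing it becomes a
#' reverse-forward discordant pair; internal fragments become concordant
#' forward-reverse pairs. Every circle is guaranteed at least
#' `junction_read_min` distinct junction-crossing reads whose clip is
#' long enough to count as evidence (`min_clip`). Optional uniform
#' background pairs on the linear genome and chimeric artifact pairs
#' (random ligations of two loci) stress false-positive handling. Read
#' names carry source tags (`circ*`, `bg:*`, `chim:*`).
#'
#' @param truth a `sim_truth` from [plant_circles()].
#' @param read_len read length (default 100, 2 x 100 nt pairs).
#' @param insert_mean,insert_sd fragment-size model (default 430 +- 30
#'   nt); fragments are clamped to the circle size.
#' @param internal_depth target mean coverage inside each circle.
#' @param junction_read_min guaranteed evidence-grade junction reads per
#'   circle.
#' @param min_clip clip length that counts as evidence-grade.
#' @param background_depth mean linear-genome coverage (0 disables).
#' @param chimera_rate expected chimeric pairs per circle fragment.
#' @param substitution_rate uniform per-base substitution rate.
#' @param seed RNG seed.
#' @return list: `records` (SAM record data.frame for [write_sam()]),
#'   `truth` (circles gain `n_junction`, `n_discordant_pairs`,
#'   `n_internal_pairs` counts).
#' @export
simulate_dna_reads <- function(truth, read_len = 100L, insert_mean = 430,
                               insert_sd = 30, internal_depth = 20,
                               junction_read_min = 3L, min_clip = 50L,
                               background_depth = 0, chimera_rate = 0,
                               substitution_rate = 0, seed = truth$seed) {
  set.seed(seed)
  genome <- truth$genome
  circles <- truth$circles
  chr_strs <- lapply(as.list(as.character(genome$seqs)), identity)
  names(chr_strs) <- names(genome$seqs)
  recs <- vector("list", 0L)
  n_c <- nrow(circles)
  stats_junction <- integer(n_c)
  stats_disc <- integer(n_c)
  stats_int <- integer(n_c)

  emit_pair <- function(qname, chrom, chr_str, s, e, L, p, f) {
    rl <- min(read_len, f)
    g1 <- map_circle_read(s, e, L, p, rl)
    g2 <- map_circle_read(s, e, L, p + f - rl, rl)
    seq1 <- circle_read_seq(chr_str, s, e, L, p, rl)
    seq2 <- circle_read_seq(chr_str, s, e, L, p + f - rl, rl)
    if (substitution_rate > 0) {
      seq1 <- mutate_seq(seq1, substitution_rate)
      seq2 <- mutate_seq(seq2, substitution_rate)
    }
    list(sam_record(qname, chrom, g1, "+", seq1, g2$pos, "-", TRUE),
         sam_record(qname, chrom, g2, "-", seq2, g1$pos, "+", FALSE),
         junction = isTRUE(g1$wraps) || isTRUE(g2$wraps),
         strong = (isTRUE(g1$wraps) && g1$clip_len >= min_clip) ||
           (isTRUE(g2$wraps) && g2$clip_len >= min_clip),
         discordant = !isTRUE(g1$wraps) && !isTRUE(g2$wraps) && (p + f > L))
  }

  for (i in seq_len(n_c)) {
    chrom <- circles$chrom[i]; s <- circles$start[i]; e <- circles$end[i]
    L <- circles$size_bp[i]
    chr_str <- chr_strs[[chrom]]
    n_frag <- max(1L, ceiling(internal_depth * L /
                                (2 * min(read_len, min(insert_mean, L)))))
    n_strong <- 0L
    for (k in seq_len(n_frag)) {
      f <- max(min(read_len, L), min(L, round(stats::rnorm(1, insert_mean, insert_sd))))
      p <- sample.int(L, 1L) - 1L
      pr <- emit_pair(sprintf("%s:frag%05d", circles$circle_id[i], k),
                      chrom, chr_str, s, e, L, p, f)
      recs[[length(recs) + 1L]] <- pr[[1]]
      recs[[length(recs) + 1L]] <- pr[[2]]
      if (pr$strong) n_strong <- n_strong + 1L
      if (pr$junction) stats_junction[i] <- stats_junction[i] + 1L
      else if (pr$discordant) stats_disc[i] <- stats_disc[i] + 1L
      else stats_int[i] <- stats_int[i] + 1L
    }
    # guarantee evidence-grade junction reads. For circles at least one
    # read long, place R1 so that it wraps with an evidence-grade clip.
    # Smaller circles cannot yield a long clip from a size-clamped read;
    # there the simulator emits a merged-pair singleton contig covering
    # the whole circle plus `min_clip` wrapped bases, mimicking the
    # longer contigs that read-pair merging produces for small circles.
    topup <- 0L
    while (n_strong < junction_read_min && L >= min_clip) {
      topup <- topup + 1L
      qn <- sprintf("%s:junc%05d", circles$circle_id[i], topup)
      if (L >= read_len) {
        clip <- max(min_clip, read_len %/% 2L)
        f <- max(read_len, min(L, round(stats::rnorm(1, insert_mean, insert_sd))))
        p <- (L - (read_len - clip)) %% L
        pr <- emit_pair(qn, chrom, chr_str, s, e, L, p, f)
        recs[[length(recs) + 1L]] <- pr[[1]]
        recs[[length(recs) + 1L]] <- pr[[2]]
        if (pr$strong) n_strong <- n_strong + 1L
      } else {
        rl_j <- L + min_clip
        g <- map_circle_read(s, e, L, 0L, rl_j)
        sq <- circle_read_seq(chr_str, s, e, L, 0L, rl_j)
        if (substitution_rate > 0) sq <- mutate_seq(sq, substitution_rate)
        recs[[length(recs) + 1L]] <- sam_record(qn, chrom, g, "+", sq,
                                                -1L, "+", TRUE, paired = FALSE)
        n_strong <- n_strong + 1L
      }
      stats_junction[i] <- stats_junction[i] + 1L
    }
    if (chimera_rate > 0) {
      n_chim <- stats::rpois(1, chimera_rate * n_frag)
      for (k in seq_len(n_chim)) {
        ch <- chimera_pair(genome, chr_strs, read_len,
                           sprintf("chim:%s:%d", circles$circle_id[i], k))
        recs[[length(recs) + 1L]] <- ch[[1]]
        recs[[length(recs) + 1L]] <- ch[[2]]
      }
    }
  }
  df <- records_to_df(recs)

  if (background_depth > 0) {
    bg <- lapply(seq_along(genome$index), function(ci) {
      chrom <- names(genome$index)[ci]
      chr_len <- as.integer(unclass(genome$index)[ci])
      chr_str <- chr_strs[[chrom]]
      n_bg <- ceiling(background_depth * chr_len / (2 * read_len))
      f <- pmax(2L * read_len,
                pmin(chr_len, round(stats::rnorm(n_bg, insert_mean, insert_sd))))
      x <- floor(stats::runif(n_bg, 0, chr_len - f + 1))
      qn <- sprintf("bg:%s:%06d", chrom, seq_len(n_bg))
      cig <- sprintf("%dM", read_len)
      r1 <- data.frame(qname = qn, flag = 1L + 64L + 32L, chrom = chrom,
                       pos = x, mapq = 60L, cigar = cig, mate_chrom = "=",
                       mate_pos = x + f - read_len,
                       seq = substring(chr_str, x + 1, x + read_len),
                       sa = NA_character_, stringsAsFactors = FALSE)
      r2 <- data.frame(qname = qn, flag = 1L + 128L + 16L, chrom = chrom,
                       pos = x + f - read_len, mapq = 60L, cigar = cig,
                       mate_chrom = "=", mate_pos = x,
                       seq = substring(chr_str, x + f - read_len + 1, x + f),
                       sa = NA_character_, stringsAsFactors = FALSE)
      rbind(r1, r2)
    })
    df <- rbind(df, do.call(rbind, bg))
  }

  df <- df[order(match(df$chrom, names(genome$index)), df$pos), , drop = FALSE]
  rownames(df) <- NULL
  truth$circles$n_junction <- stats_junction
  truth$circles$n_discordant_pairs <- stats_disc
  truth$circles$n_internal_pairs <- stats_int
  list(records = df, truth = truth)
}

chimera_pair <- function(genome, chr_strs, read_len, qname) {
  ci <- sample.int(length(genome$index), 1L)
  chrom <- names(genome$index)[ci]
  chr_len <- as.integer(unclass(genome$index)[ci])
  x1 <- sample.int(chr_len - read_len, 1L) - 1L
  x2 <- min(chr_len - read_len,
            max(0L, x1 + sample.int(500000L, 1L) - 250000L))
  chr_str <- chr_strs[[chrom]]
  lo <- min(x1, x2); hi <- max(x1, x2)
  g1 <- list(pos = lo, cigar = sprintf("%dM", read_len), wraps = FALSE)
  g2 <- list(pos = hi, cigar = sprintf("%dM", read_len), wraps = FALSE)
  # reverse-forward orientation: mimics a junction-crossing pair
  list(sam_record(qname, chrom, g1, "-",
                  substring(chr_str, lo + 1L, lo + read_len), hi, "+", TRUE),
       sam_record(qname, chrom, g2, "+",
                  substring(chr_str, hi + 1L, hi + read_len), lo, "-", FALSE))
}

#' Write simulator records as a coordinate-sorted SAM file
#'
#' @param records record data.frame from [simulate_dna_reads()].
#' @param genome an `ecc_genome_index` (or the `index` of a simulated
#'   genome).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                     as.integer(unclass(genome))), con)
  if (nrow(records) > 0L) {
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*",
                     records$qname, records$flag, records$chrom,
                     as.integer(records$pos) + 1L, records$mapq,
                     records$cigar, records$mate_chrom,
                     as.integer(records$mate_pos) + 1L, records$seq)
    has_sa <- !is.na(records$sa) & records$sa != ""
    lines[has_sa] <- paste0(lines[has_sa], "\tSA:Z:", records$sa[has_sa])
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write the simulated genome and truth set
#'
#' @param truth a `sim_truth`.
#' @param fasta_path,bed_path,table_path output paths (`NULL` skips).
#' @return invisibly, the truth circle data.frame.
#' @export
write_truth <- function(truth, fasta_path = NULL, bed_path = NULL,
                        table_path = NULL) {
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(truth$genome$seqs, fasta_path)
  }
  if (!is.null(bed_path)) {
    utils::write.table(truth$circles[, c("chrom", "start", "end", "circle_id")],
                       bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(table_path)) {
    utils::write.table(truth$circles, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(truth$circles)
}

#' Simulate RNA reads across circle junctions
#'
#' For each selected circle, emits split-transcript reads in back-splice
#' orientation: the left part of the read aligns just upstream of the
#' circle end, the right part at the circle start (shifted by `jitter`
#' nucleotides, a test knob for the start-deviation filter).
#'
#' @param truth a `sim_truth`.
#' @param subset circle ids to transcribe (default: all).
#' @param read_len total read length; each half is `read_len/2`.
#' @param n_reads_per_circle reads emitted per circle.
#' @param jitter start-coordinate shift in nucleotides.
#' @param seed RNG seed.
#' @return split-transcript read data.frame (see
#'   [read_split_transcripts()]).
#' @export
simulate_rna_junction_reads <- function(truth, subset = truth$circles$circle_id,
                                        read_len = 100L, n_reads_per_circle = 2L,
                                        jitter = 0L, seed = truth$seed) {
  set.seed(seed)
  circles <- truth$circles[truth$circles$circle_id %in% subset, , drop = FALSE]
  half <- read_len %/% 2L
  out <- lapply(seq_len(nrow(circles)), function(i) {
    s <- circles$start[i]; e <- circles$end[i]
    a <- min(half, circles$size_bp[i] %/% 2L)  # each aligned half
    data.frame(read_name = sprintf("rna:%s:%d", circles$circle_id[i],
                                   seq_len(n_reads_per_circle)),
               chrom = circles$chrom[i],
               left_start = e - a, left_end = e,
               right_start = s + jitter, right_end = s + jitter + a,
               n_loci = 1L, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (is.null(df)) df <- data.frame(read_name = character(), chrom = character(),
                                    left_start = integer(), left_end = integer(),
                                    right_start = integer(), right_end = integer(),
                                    n_loci = integer(), stringsAsFactors = FALSE)
  finish_split_reads(df)
}

#' Simulate single-end reads over labelled contigs
#'
#' Emits `n_reads` primary single-end alignments over a set of contigs
#' with the given sampling probabilities (e.g. spike-in plasmids at
#' copy-number x length weights); the multinomial ground truth for
#' [read_class_fractions()].
#'
#' @param contig_lengths named vector of contig lengths.
#' @param probs named sampling probabilities (same names).
#' @param n_reads total reads.
#' @param read_len read length.
#' @param seed RNG seed.
#' @return an `ecc_alignments`-shaped data.frame with its genome index.
#' @export
simulate_class_reads <- function(contig_lengths, probs, n_reads,
                                 read_len = 100L, seed = 1L) {
  set.seed(seed)
  stopifnot(setequal(names(contig_lengths), names(probs)))
  probs <- probs[names(contig_lengths)]
  contig <- sample(names(contig_lengths), n_reads, replace = TRUE,
                   prob = probs / sum(probs))
  start <- vapply(contig, function(ch)
    sample.int(max(1L, as.integer(contig_lengths[[ch]]) - read_len), 1L) - 1L,
    integer(1))
  df <- data.frame(
    read_name = sprintf("cls:%06d", seq_len(n_reads)),
    chrom = contig, start = start, end = start + read_len,
    strand = "+", mapq = 60L, cigar = sprintf("%dM", read_len),
    is_read1 = TRUE, is_paired = FALSE, is_secondary = FALSE,
    is_supplementary = FALSE, is_duplicate = FALSE, is_unmapped = FALSE,
    mate_chrom = NA_character_, mate_start = NA_integer_,
    mate_strand = NA_character_, left_clip_len = 0L, right_clip_len = 0L,
    clipped_seq_left = NA_character_, clipped_seq_right = NA_character_,
    sa_chrom = NA_character_, sa_start = NA_integer_,
    sa_strand = NA_character_, sa_ref_width = NA_integer_,
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, genome_index = genome_index(contig_lengths),
            class = c("ecc_alignments", "data.frame"))
}
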
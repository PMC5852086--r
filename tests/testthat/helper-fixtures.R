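# Shared fixtures and independent oracles. Oracles are deliberately
# naive (per-base counting, full scans, adjacency-matrix closure) and
# never call the code paths they check.

# A 5-record SAM with clips, reverse strand, a pair, hard clips and an
# SA tag; expected values below were frozen from an independent SAM
# parser run on the same records.
write_fix5_sam <- function(path) {
  seq100 <- paste(rep("ACGT", 25), collapse = "")
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:100000",
    "@SQ\tSN:chr2\tLN:50000",
    paste("r1", 0, "chr1", 100, 60, "50S50M", "*", 0, 0, seq100, "*",
          "SA:Z:chr1,500,+,50M50S,60,0;", sep = "\t"),
    paste("r2", 0, "chr1", 1, 60, "100M", "*", 0, 0, seq100, "*", sep = "\t"),
    paste("r3", 16, "chr1", 2000, 37, "60M40S", "*", 0, 0, seq100, "*", sep = "\t"),
    paste("r4", 99, "chr2", 300, 60, "100M", "=", 700, 500, seq100, "*", sep = "\t"),
    paste("r5", 2048, "chr1", 5000, 60, "20M80H", "*", 0, 0,
          substr(seq100, 1, 20), "*", sep = "\t"))
  writeLines(lines, path)
  path
}

# Fabricate one ecc_alignments row with sensible defaults.
make_aln <- function(read_name = "r", chrom = "chr1", start = 0L, end = 100L,
                     strand = "+", mapq = 60L, cigar = "100M",
                     is_read1 = TRUE, is_paired = TRUE,
                     left_clip_len = 0L, right_clip_len = 0L,
                     clipped_seq_left = NA_character_,
                     clipped_seq_right = NA_character_,
                     sa_chrom = NA_character_, sa_start = NA_integer_,
                     sa_strand = NA_character_, sa_ref_width = NA_integer_,
                     is_secondary = FALSE, is_supplementary = FALSE,
                     is_duplicate = FALSE, is_unmapped = FALSE,
                     mate_chrom = NA_character_, mate_start = NA_integer_,
                     mate_strand = NA_character_) {
  data.frame(read_name = read_name, chrom = chrom, start = start, end = end,
             strand = strand, mapq = mapq, cigar = cigar,
             is_read1 = is_read1, is_paired = is_paired,
             is_secondary = is_secondary, is_supplementary = is_supplementary,
             is_duplicate = is_duplicate, is_unmapped = is_unmapped,
             mate_chrom = mate_chrom, mate_start = mate_start,
             mate_strand = mate_strand,
             left_clip_len = left_clip_len, right_clip_len = right_clip_len,
             clipped_seq_left = clipped_seq_left,
             clipped_seq_right = clipped_seq_right,
             sa_chrom = sa_chrom, sa_start = sa_start, sa_strand = sa_strand,
             sa_ref_width = sa_ref_width, stringsAsFactors = FALSE)
}

make_aln_set <- function(..., genome = genome_index(c(chr1 = 1e6, chr2 = 1e6))) {
  df <- do.call(rbind, list(...))
  structure(df, genome_index = genome,
            class = c("ecc_alignments", "data.frame"))
}

# Fabricate circle calls.
make_call <- function(chrom = "chr1", start = 0L, end = 1000L,
                      confidence = "hconf", n_reads = 3L, n_split = 1L,
                      n_softclip = 1L, n_discordant = 1L,
                      mean_coverage = 20, coverage_fraction = 1,
                      flank_coverage_sum = 0, gene_names = "",
                      n_merged = 1L) {
  structure(data.frame(chrom = chrom, start = start, end = end,
                       size_bp = end - start, confidence = confidence,
                       n_reads = n_reads, n_split = n_split,
                       n_softclip = n_softclip, n_discordant = n_discordant,
                       mean_coverage = mean_coverage,
                       coverage_fraction = coverage_fraction,
                       flank_coverage_sum = flank_coverage_sum,
                       gene_names = gene_names, n_merged = n_merged,
                       stringsAsFactors = FALSE),
            class = c("ecc_calls", "data.frame"))
}

bind_calls <- function(...) {
  structure(do.call(rbind, lapply(list(...), as.data.frame)),
            class = c("ecc_calls", "data.frame"))
}

# --- independent oracles ----------------------------------------------

# reciprocal overlap by explicit position sets
brute_ro <- function(s1, e1, s2, e2) {
  a <- seq.int(s1, e1 - 1L)
  b <- seq.int(s2, e2 - 1L)
  ov <- length(intersect(a, b))
  if (ov == 0) return(0)
  min(ov / length(a), ov / length(b))
}

# per-base depth by incrementing a counter vector
brute_depth <- function(aln, chrom, chrom_len) {
  v <- integer(chrom_len)
  keep <- !aln$is_unmapped & !aln$is_secondary & !aln$is_supplementary &
    !aln$is_duplicate & aln$chrom == chrom
  a <- aln[keep, , drop = FALSE]
  for (i in seq_len(nrow(a))) {
    idx <- seq.int(a$start[i] + 1L, a$end[i])
    v[idx] <- v[idx] + 1L
  }
  v
}

# transitive closure clustering via adjacency matrix + repeated expansion
oracle_partition <- function(ev, cfg) {
  n <- nrow(ev)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      adj[i, j] <- oracle_compatible(ev[i, ], ev[j, ], cfg)
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        nb <- which(adj[f, ] & is.na(comp))
        comp[nb] <- cid
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  comp
}

oracle_compatible <- function(a, b, cfg) {
  if (a$chrom != b$chrom) return(FALSE)
  shared <- FALSE
  if (!is.na(a$start_hint) && !is.na(b$start_hint)) {
    tol <- if (a$start_exact && b$start_exact) cfg$exact_tolerance_bp else cfg$cluster_tolerance_bp
    if (abs(a$start_hint - b$start_hint) > tol) return(FALSE)
    shared <- TRUE
  }
  if (!is.na(a$end_hint) && !is.na(b$end_hint)) {
    tol <- if (a$end_exact && b$end_exact) cfg$exact_tolerance_bp else cfg$cluster_tolerance_bp
    if (abs(a$end_hint - b$end_hint) > tol) return(FALSE)
    shared <- TRUE
  }
  if (!shared) return(FALSE)
  lo <- suppressWarnings(min(a$start_hint, b$start_hint, na.rm = TRUE))
  hi <- suppressWarnings(max(a$end_hint, b$end_hint, na.rm = TRUE))
  is.finite(lo) && is.finite(hi) && lo < hi && (hi - lo) <= cfg$max_circle_size
}

# partition equality up to labelling
same_partition <- function(p1, p2) {
  length(p1) == length(p2) &&
    all(outer(p1, p1, "==") == outer(p2, p2, "=="))
}

# brute-force full-scan ungapped aligner: best identity locus of frag on chr
brute_realign <- function(frag, chr_str) {
  len <- nchar(frag)
  fv <- strsplit(frag, "")[[1]]
  n <- nchar(chr_str) - len + 1L
  best <- -1; best_pos <- integer(0)
  for (s in seq_len(n)) {
    cv <- strsplit(substring(chr_str, s, s + len - 1L), "")[[1]]
    id <- sum(fv == cv) / len
    if (id > best + 1e-12) { best <- id; best_pos <- s - 1L }
    else if (abs(id - best) < 1e-12) best_pos <- c(best_pos, s - 1L)
  }
  list(identity = best, starts = best_pos)
}

# a small end-to-end scenario shared by several files
sim_scenario <- function(n = 10, seed = 11, background_depth = 0,
                         internal_depth = 20, junction_read_min = 3,
                         lengths = c(chr1 = 600000, chr2 = 400000), ...) {
  g <- simulate_genome(lengths, seed = seed)
  tr <- plant_circles(g, n, seed = seed + 1)
  sim <- simulate_dna_reads(tr, internal_depth = internal_depth,
                            junction_read_min = junction_read_min,
                            background_depth = background_depth,
                            seed = seed + 2, ...)
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$records, g$index, sam)
  aln <- read_alignments(sam)
  list(genome = g, truth = sim$truth, records = sim$records,
       sam = sam, aln = aln)
}
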
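cfg <- detection_config()

test_that("pair orientation distinguishes concordant FR from junction RF", {
  L <- list(chrom = "chr1", start = 100, strand = "+", is_unmapped = FALSE)
  R <- list(chrom = "chr1", start = 400, strand = "-", is_unmapped = FALSE)
  expect_equal(classify_pair_orientation(L, R), "FR")
  L$strand <- "-"; R$strand <- "+"
  expect_equal(classify_pair_orientation(L, R), "RF")
  expect_equal(classify_pair_orientation(R, L), "RF")  # argument order irrelevant
  R$strand <- "-"
  expect_equal(classify_pair_orientation(L, R), "other")
  R$chrom <- "chr2"; R$strand <- "+"
  expect_equal(classify_pair_orientation(L, R), "other")
  R$is_unmapped <- TRUE
  expect_error(classify_pair_orientation(L, R), "unmapped")
})

test_that("RF pairs yield inexact junction evidence; FR and oversized pairs do not", {
  rf <- make_aln_set(
    make_aln("p1", start = 1000L, end = 1100L, cigar = "100M", strand = "-",
             is_read1 = TRUE, mate_chrom = "chr1", mate_start = 4900L,
             mate_strand = "+"),
    make_aln("p1", start = 4900L, end = 5000L, cigar = "100M", strand = "+",
             is_read1 = FALSE, mate_chrom = "chr1", mate_start = 1000L,
             mate_strand = "-"))
  ev <- extract_discordant(rf, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "discordant")
  expect_equal(ev$start_hint, 1000L)
  expect_equal(ev$end_hint, 5000L)
  expect_false(ev$start_exact); expect_false(ev$end_exact)

  fr <- make_aln_set(
    make_aln("p2", start = 1000L, end = 1100L, strand = "+", is_read1 = TRUE),
    make_aln("p2", start = 4900L, end = 5000L, strand = "-", is_read1 = FALSE))
  expect_equal(nrow(extract_discordant(fr, cfg)), 0L)

  far <- make_aln_set(
    make_aln("p3", start = 0L, end = 100L, strand = "-", is_read1 = TRUE),
    make_aln("p3", start = 1200000L - 100L, end = 1200000L, strand = "+",
             is_read1 = FALSE),
    genome = genome_index(c(chr1 = 2e6)))
  ev <- extract_discordant(far, cfg)
  expect_equal(nrow(ev), 0L)
  expect_equal(attr(ev, "n_dropped_span"), 1L)
})

test_that("soft-clip evidence needs 50 clipped bases and marks one exact boundary", {
  at49 <- make_aln_set(make_aln("a", start = 200L, end = 251L, cigar = "49S51M",
                                left_clip_len = 49L))
  expect_equal(nrow(extract_softclip(at49, cfg)), 0L)
  at50 <- make_aln_set(make_aln("a", start = 200L, end = 250L, cigar = "50S50M",
                                left_clip_len = 50L))
  ev <- extract_softclip(at50, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$side, "left_clip")
  expect_equal(ev$start_hint, 200L)
  expect_true(ev$start_exact)
  expect_true(is.na(ev$end_hint))
  both <- make_aln_set(make_aln("b", start = 300L, end = 340L,
                                cigar = "60S40M60S",
                                left_clip_len = 60L, right_clip_len = 60L))
  ev2 <- extract_softclip(both, cfg)
  expect_equal(nrow(ev2), 2L)
  expect_setequal(ev2$side, c("left_clip", "right_clip"))
  # duplicates, secondary and low-mapq records never seed evidence
  dup <- make_aln_set(make_aln("d", left_clip_len = 60L, is_duplicate = TRUE),
                      make_aln("s", left_clip_len = 60L, is_secondary = TRUE),
                      make_aln("q", left_clip_len = 60L, mapq = 0L))
  expect_equal(nrow(extract_softclip(dup, cfg)), 0L)
})

test_that("clipped-fragment realignment fixes both junction coordinates", {
  g <- simulate_genome(c(chrA = 30000, chrB = 30000), seed = 5)
  chrA <- as.character(g$seqs[["chrA"]])
  s <- 10000L; e <- 15000L
  frag <- substring(chrA, e - 60 + 1, e)  # the 60 bases ending at the circle end
  hit <- realign_clipped_fragment(frag, "chrA", s, g$seqs, cfg)
  expect_equal(hit$start, e - 60L)
  expect_equal(hit$end, e)
  # left-clip anchor at s: fragment end gives circle [s, e)
  sc <- extract_softclip(make_aln_set(
    make_aln("lc", chrom = "chrA", start = s, end = s + 40L, cigar = "60S40M",
             left_clip_len = 60L, clipped_seq_left = frag)), cfg)
  up <- circlescan:::upgrade_softclips(sc, g$seqs, cfg)
  expect_equal(up$kind, "split")
  expect_equal(up$start_hint, s)
  expect_equal(up$end_hint, e)
  expect_true(up$start_exact && up$end_exact)

  # a fragment present only as reverse complement is not accepted
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  if (length(Biostrings::matchPattern(rc, g$seqs[["chrA"]])) == 0) {
    expect_null(realign_clipped_fragment(rc, "chrA", s, g$seqs, cfg))
  }
  # a fragment from another chromosome is not accepted on the anchor one
  fragB <- substring(as.character(g$seqs[["chrB"]]), 1001, 1060)
  expect_null(realign_clipped_fragment(fragB, "chrA", s, g$seqs, cfg))
})

test_that("realigner agrees with a brute-force full-scan aligner", {
  g <- simulate_genome(c(chrA = 20000), seed = 9)
  chrA <- as.character(g$seqs[["chrA"]])
  set.seed(10)
  for (k in 1:8) {
    pos <- sample.int(20000 - 60, 1)
    frag <- substring(chrA, pos, pos + 59)
    oracle <- brute_realign(frag, chrA)
    hit <- realign_clipped_fragment(frag, "chrA", sample.int(20000, 1) - 1L,
                                    g$seqs, cfg)
    if (length(oracle$starts) == 1L && oracle$identity >= cfg$realign_min_identity) {
      expect_equal(hit$start, oracle$starts)
    } else {
      expect_null(hit)  # ambiguous ties are rejected
    }
  }
  # planted ambiguity: the same 60-mer at two loci must be rejected
  dup <- paste0(substring(chrA, 1, 5000), substring(chrA, 101, 160),
                substring(chrA, 5061, 12000), substring(chrA, 101, 160),
                substring(chrA, 12061, 20000))
  ref <- Biostrings::DNAStringSet(dup); names(ref) <- "chrA"
  frag <- substring(chrA, 101, 160)
  expect_null(realign_clipped_fragment(frag, "chrA", 5000L, ref, cfg))
})

test_that("evidence clustering matches a transitive-closure oracle and ignores input order", {
  # worked example: one split plus one discordant hint pair form one
  # cluster with consensus from the exact coordinates
  ev <- rbind(
    data.frame(kind = "split", chrom = "chr1", start_hint = 1000L,
               end_hint = 5000L, start_exact = TRUE, end_exact = TRUE,
               read_name = "sr", side = "left_clip", stringsAsFactors = FALSE),
    data.frame(kind = "discordant", chrom = "chr1", start_hint = 950L,
               end_hint = 5050L, start_exact = FALSE, end_exact = FALSE,
               read_name = "dp", side = "pair", stringsAsFactors = FALSE))
  cl <- cluster_evidence(ev, cfg)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$consensus_start, 1000L)
  expect_equal(cl$consensus_end, 5000L)
  expect_equal(cl$n_distinct_reads, 2L)

  # two splits 1 bp apart cluster; 1 kb apart at the start do not
  near <- ev[c(1, 1), ]; near$start_hint[2] <- 1001L; near$end_hint[2] <- 5001L
  near$read_name[2] <- "sr2"
  expect_equal(nrow(cluster_evidence(near, cfg)), 1L)
  far <- near; far$start_hint[2] <- 2000L
  expect_equal(nrow(cluster_evidence(far, cfg)), 2L)

  # randomized ≤20-item sets against the adjacency-matrix closure oracle
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(2:20, 1)
    kind <- sample(c("split", "softclip", "discordant"), n, replace = TRUE)
    anchor <- sample(c(1000L, 1300L, 8000L, 50000L), n, replace = TRUE)
    size <- sample(c(400L, 450L, 3000L), n, replace = TRUE)
    ev <- data.frame(kind = kind, chrom = sample(c("c1", "c2"), n, TRUE),
                     start_hint = anchor + sample(-300:300, n, TRUE),
                     end_hint = NA_integer_, start_exact = FALSE,
                     end_exact = FALSE,
                     read_name = sprintf("r%02d", seq_len(n)),
                     side = "pair", stringsAsFactors = FALSE)
    ev$end_hint <- ev$start_hint + size
    ev$start_exact <- kind != "discordant" & sample(c(TRUE, FALSE), n, TRUE)
    ev$end_exact <- kind == "split"
    sc_side <- which(kind == "softclip")
    ev$start_hint[sc_side[sc_side %% 2 == 0]] <- NA  # some END-only clips
    ev$end_hint[sc_side[sc_side %% 2 == 1]] <- NA    # some START-only clips
    drop <- is.na(ev$start_hint) & is.na(ev$end_hint)
    ev <- ev[!drop, , drop = FALSE]
    if (nrow(ev) < 2) next
    cl <- cluster_evidence(ev, cfg)
    got <- integer(nrow(ev))
    for (i in seq_len(nrow(cl))) got[cl$members[[i]]] <- i
    expect_true(same_partition(got, oracle_partition(ev, cfg)))
    # order invariance
    perm <- sample(nrow(ev))
    cl2 <- cluster_evidence(ev[perm, ], cfg)
    expect_equal(cl[, c("chrom", "consensus_start", "consensus_end",
                        "n_distinct_reads")],
                 cl2[, c("chrom", "consensus_start", "consensus_end",
                         "n_distinct_reads")])
  }
})

test_that("a read upgraded to split is never double-counted inside a cluster", {
  sc <- sim_scenario(n = 5, seed = 41)
  ev <- extract_evidence(sc$aln, cfg)
  cl <- cluster_evidence(ev, cfg)
  for (i in seq_len(nrow(cl))) {
    m <- ev[cl$members[[i]], ]
    expect_equal(cl$n_distinct_reads[i], length(unique(m$read_name)))
    expect_lte(cl$n_distinct_reads[i], nrow(m))
  }
})

test_that("planted circles produce clusters at the exact truth coordinates", {
  sc <- sim_scenario(n = 8, seed = 51)
  ev <- extract_evidence(sc$aln, cfg)
  cl <- cluster_evidence(ev, cfg)
  for (i in seq_len(nrow(sc$truth$circles))) {
    tr <- sc$truth$circles[i, ]
    hit <- cl[cl$chrom == tr$chrom & cl$consensus_start == tr$start &
                cl$consensus_end == tr$end, ]
    expect_gte(nrow(hit), 1)
  }
})
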
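cfg <- detection_config()

test_that("junction transcripts require containment and a 20-nt start agreement", {
  circ <- make_call("chr1", 10000L, 15000L, n_split = 1L, n_softclip = 0L)
  mk_rna <- function(dev, name = "t1") {
    data.frame(read_name = name, chrom = "chr1",
               left_start = 14950L, left_end = 15000L,
               right_start = 10000L + dev, right_end = 10050L + dev,
               n_loci = 1L, implied_start = 10000L + dev, implied_end = 15000L,
               stringsAsFactors = FALSE)
  }
  # exact match is supported
  tc <- detect_junction_transcripts(mk_rna(0L), circ, cfg)
  expect_equal(nrow(tc), 1L)
  expect_equal(tc$n_supporting, 1L)
  expect_equal(tc$rank, "hconf")
  # 20 nt deviation passes, 21 is discarded
  expect_equal(nrow(detect_junction_transcripts(mk_rna(20L), circ, cfg)), 1L)
  expect_equal(nrow(detect_junction_transcripts(mk_rna(21L), circ, cfg)), 0L)
  # a circle detected only from discordant pairs has no exact junction
  disc_only <- make_call("chr1", 10000L, 15000L, n_split = 0L, n_softclip = 0L,
                         n_discordant = 2L)
  expect_equal(nrow(detect_junction_transcripts(mk_rna(0L), disc_only, cfg)), 0L)
  # mitochondrial reads are excluded upstream
  mito <- mk_rna(0L); mito$chrom <- "chrM"
  circM <- circ; circM$chrom <- "chrM"
  expect_equal(nrow(detect_junction_transcripts(mito, circM, cfg)), 0L)
})

test_that("transcribed-circle ranks follow match exactness and junction uniqueness", {
  mk <- function(s, e, loci) data.frame(implied_start = s, implied_end = e,
                                        n_loci = loci)
  expect_equal(rank_transcribed_circle(mk(100L, 900L, 1L), 100L, 900L), "hconf")
  expect_equal(rank_transcribed_circle(mk(100L, 900L, 2L), 100L, 900L), "conf")
  expect_equal(rank_transcribed_circle(mk(100L, 880L, 3L), 100L, 900L), "lowq")
  # dominance: adding a perfect unique read never lowers the rank
  two <- rbind(mk(100L, 880L, 3L), mk(100L, 900L, 1L))
  expect_equal(rank_transcribed_circle(two, 100L, 900L), "hconf")
})

test_that("junction uniqueness counting matches planted duplications", {
  g <- simulate_genome(c(chrA = 20000), seed = 15)
  chrA <- as.character(g$seqs[["chrA"]])
  frag <- substring(chrA, 501, 560)
  expect_equal(count_genomic_loci(frag, g$seqs, cfg), 1L)
  dup <- Biostrings::DNAStringSet(c(chrA = chrA, chrB = chrA))
  expect_equal(count_genomic_loci(frag, dup, cfg), 2L)
})

test_that("split alignments in SAM form reduce to back-splice interval pairs", {
  # primary covers the first half of the query at the circle end; the
  # supplementary covers the second half at the circle start
  aln <- make_aln_set(
    make_aln("t1", "chr1", 14950L, 15000L, cigar = "50M50S",
             right_clip_len = 50L, is_paired = FALSE),
    make_aln("t1", "chr1", 10000L, 10050L, cigar = "50S50M",
             left_clip_len = 50L, is_supplementary = TRUE, is_paired = FALSE))
  sp <- split_transcript_reads(aln)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$implied_start, 10000L)
  expect_equal(sp$implied_end, 15000L)
  # forward-splice geometry (left part upstream) is not kept
  fwd <- make_aln_set(
    make_aln("t2", "chr1", 10000L, 10050L, cigar = "50M50S",
             right_clip_len = 50L, is_paired = FALSE),
    make_aln("t2", "chr1", 14950L, 15000L, cigar = "50S50M",
             left_clip_len = 50L, is_supplementary = TRUE, is_paired = FALSE))
  expect_equal(nrow(split_transcript_reads(fwd)), 0L)
  # the table reader applies the same geometry filter
  tab <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(read_name = c("a", "b"), chrom = "chr1",
                                left_start = c(14950L, 100L),
                                left_end = c(15000L, 150L),
                                right_start = c(10000L, 5000L),
                                right_end = c(10050L, 5050L)),
                     tab, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- read_split_transcripts(tab)
  expect_equal(rt$read_name, "a")
  expect_equal(rt$n_loci, 1L)
})

test_that("simulated junction transcripts recover exactly the transcribed subset", {
  g <- simulate_genome(c(chr1 = 300000), seed = 71)
  tr <- plant_circles(g, 12, seed = 72)
  sub <- tr$circles$circle_id[c(2, 5, 9)]
  rna <- simulate_rna_junction_reads(tr, subset = sub, jitter = 0L)
  calls <- do.call(bind_calls, lapply(seq_len(nrow(tr$circles)), function(i)
    make_call(tr$circles$chrom[i], tr$circles$start[i], tr$circles$end[i])))
  tc <- detect_junction_transcripts(rna, calls, cfg)
  want <- tr$circles[tr$circles$circle_id %in% sub, ]
  expect_equal(nrow(tc), 3L)
  expect_setequal(paste(tc$chrom, tc$start, tc$end),
                  paste(want$chrom, want$start, want$end))
  expect_true(all(tc$rank == "hconf"))
  # forced 21-nt jitter: every read is filtered
  rna21 <- simulate_rna_junction_reads(tr, subset = sub, jitter = 21L)
  expect_equal(nrow(detect_junction_transcripts(rna21, calls, cfg)), 0L)
})

test_that("the Monte Carlo overlap p-value is seeded, bounded and add-one", {
  gi <- genome_index(c(c1 = 5e6, c2 = 5e6))
  cfg200 <- detection_config(mc_randomizations = 200)
  circles <- data.frame(chrom = "c1", start = c(1e5, 9e5, 2e6),
                        end = c(1e5, 9e5, 2e6) + 2000)
  # observed overlap 0 -> p = 1
  far <- data.frame(chrom = "c2", start = 1e5, end = 1e5 + 500)
  expect_warning(p_empty <- monte_carlo_overlap_p(circles[0, ], far, gi, cfg200), "empty")
  expect_equal(p_empty, 1)
  expect_equal(monte_carlo_overlap_p(circles, far, gi, cfg200, seed = 3), 1)
  # planted perfect overlap on a large genome: the estimator floor
  p <- monte_carlo_overlap_p(circles, circles, gi, cfg200, seed = 3)
  expect_equal(p, 1 / 201)
  # reproducible under the seed, bounded below by 1/(n+1)
  expect_equal(monte_carlo_overlap_p(circles, circles, gi, cfg200, seed = 5), p)
  expect_gte(p, 1 / 201)
})
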
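cfg <- detection_config()

test_that("coverage statistics match a brute-force per-base counter", {
  gi <- genome_index(c(chr1 = 20000))
  set.seed(3)
  n <- 120
  starts <- sample.int(19000, n) - 1L
  rows <- lapply(seq_len(n), function(i)
    make_aln(sprintf("r%03d", i), "chr1", starts[i], starts[i] + 100L))
  aln <- do.call(make_aln_set, c(rows, list(genome = gi)))
  cov <- coverage_depth(aln, gi)
  depth <- brute_depth(aln, "chr1", 20000L)
  for (k in 1:60) {
    s <- sample.int(15000, 1); L <- sample(50:2000, 1); e <- s + L
    st <- coverage_stats("chr1", s, e, cov, gi)
    inside <- depth[(s + 1):e]
    expect_equal(st$mean_cov, mean(inside))
    expect_equal(st$fraction_covered, mean(inside > 0))
    up <- depth[max(1, s - L + 1):s]
    if (s - L >= 0) expect_equal(st$flank_up_mean, mean(up))
    if (e + L <= 20000) expect_equal(st$flank_down_mean, mean(depth[(e + 1):(e + L)]))
  }
  expect_error(coverage_stats("chr1", 19990, 20010, cov, gi), "outside")
})

test_that("flank handling: uniform interior, empty genome, truncation fallback", {
  gi <- genome_index(c(chr1 = 10000))
  aln <- make_aln_set(
    make_aln("u1", "chr1", 1000L, 2000L, cigar = "1000M"),
    genome = gi)
  # 10 identical reads -> depth 10 inside, 0 outside
  rows <- lapply(1:10, function(i) make_aln(sprintf("u%d", i), "chr1",
                                            1000L, 2000L, cigar = "1000M"))
  aln <- do.call(make_aln_set, c(rows, list(genome = gi)))
  cov <- coverage_depth(aln, gi)
  st <- coverage_stats("chr1", 1000, 2000, cov, gi)
  expect_equal(st$mean_cov, 10)
  expect_equal(st$fraction_covered, 1)
  expect_equal(st$flank_sum, 0)
  # depth zero everywhere
  st0 <- coverage_stats("chr1", 5000, 6000, coverage_depth(aln[0, , drop = FALSE], gi), gi)
  expect_equal(st0$mean_cov, 0)
  expect_equal(st0$fraction_covered, 0)
  # interval at the chromosome start: upstream flank unavailable, so the
  # downstream mean is doubled
  st1 <- coverage_stats("chr1", 0, 1500, cov, gi)
  expect_true(st1$flank_truncated)
  expect_equal(st1$flank_sum, 2 * st1$flank_down_mean)
})

test_that("confidence tiers follow the coverage and fold thresholds exactly", {
  mk <- function(frac, mean, fsum) list(fraction_covered = frac, mean_cov = mean,
                                        flank_sum = fsum, flank_union_mean = fsum / 2)
  expect_equal(assign_confidence(mk(0.99, 40, 10), cfg), "hconf")
  expect_equal(assign_confidence(mk(0.99, 15, 10), cfg), "conf")
  expect_equal(assign_confidence(mk(0.90, 100, 0), cfg), "lowq")
  # the 95% boundary itself stays lowq; strictly above it is conf
  expect_equal(assign_confidence(mk(0.95, 100, 0), cfg), "lowq")
  expect_equal(assign_confidence(mk(0.9501, 100, 1000), cfg), "conf")
  # fold boundary: exactly 2x the flank sum is conf, strictly above hconf
  expect_equal(assign_confidence(mk(1, 20, 10), cfg), "conf")
  expect_equal(assign_confidence(mk(1, 20.01, 10), cfg), "hconf")
  # alternative comparator: mean over the flank union
  cfg_mean <- detection_config(flank_mode = "mean")
  expect_equal(assign_confidence(mk(1, 15, 10), cfg_mean), "hconf")  # 15 > 2*5
  expect_equal(assign_confidence(mk(1, 15, 10), cfg), "conf")
})

test_that("confidence is monotone in flank coverage and covered fraction", {
  rank_of <- c(lowq = 1L, conf = 2L, hconf = 3L)
  set.seed(8)
  for (k in 1:200) {
    st <- list(fraction_covered = stats::runif(1), mean_cov = stats::runif(1, 0, 50),
               flank_sum = stats::runif(1, 0, 50))
    st$flank_union_mean <- st$flank_sum / 2
    base <- rank_of[assign_confidence(st, cfg)]
    worse <- st; worse$flank_sum <- st$flank_sum + stats::runif(1, 0, 20)
    worse$flank_union_mean <- worse$flank_sum / 2
    expect_lte(rank_of[assign_confidence(worse, cfg)], base)
    better <- st; better$fraction_covered <- min(1, st$fraction_covered + stats::runif(1))
    expect_gte(rank_of[assign_confidence(better, cfg)], base)
  }
})

test_that("calls require two distinct supporting reads and the size cap", {
  gi <- genome_index(c(chr1 = 1e6))
  cov <- coverage_depth(make_aln_set(make_aln("x", "chr1", 100L, 200L),
                                     genome = gi), gi)
  clusters <- data.frame(chrom = "chr1",
                         consensus_start = c(1000L, 3000L, NA, 5000L),
                         consensus_end = c(2000L, 4000L, 4500L, 5000L + 999999L + 2L),
                         n_distinct_reads = c(1L, 2L, 3L, 5L),
                         n_split = 1L, n_softclip = 1L, n_discordant = 0L)
  clusters$members <- list(1L, 2L, 3L, 4L)
  calls <- call_circles(clusters, cov, gi, cfg)
  expect_equal(nrow(calls), 1L)            # only the 2-read, sized, resolved one
  expect_equal(calls$start, 3000L)
  expect_equal(attr(calls, "n_dropped_few_reads"), 1L)
  expect_equal(attr(calls, "n_dropped_unresolved"), 1L)
  expect_equal(attr(calls, "n_dropped_size"), 1L)
})

test_that("reciprocal overlap is symmetric and equals the per-base computation", {
  a <- list(chrom = "c", start = 0, end = 100)
  expect_equal(reciprocal_overlap(a, a), 1.0)
  b <- list(chrom = "c", start = 50, end = 150)
  expect_equal(reciprocal_overlap(a, b), 0.5)
  expect_equal(reciprocal_overlap(b, a), 0.5)
  expect_equal(reciprocal_overlap(a, list(chrom = "c", start = 200, end = 300)), 0)
  expect_equal(reciprocal_overlap(a, list(chrom = "d", start = 0, end = 100)), 0)
  set.seed(19)
  for (k in 1:1000) {
    s1 <- sample.int(3000, 1); e1 <- s1 + sample.int(2000, 1)
    s2 <- sample.int(3000, 1); e2 <- s2 + sample.int(2000, 1)
    x <- reciprocal_overlap(list(chrom = "c", start = s1, end = e1),
                            list(chrom = "c", start = s2, end = e2))
    expect_equal(x, brute_ro(s1, e1, s2, e2))
  }
})

test_that("merging collapses at 50% reciprocal overlap and is idempotent", {
  # RO 0.49: both kept
  a <- make_call("chr1", 0L, 1000L, n_reads = 5L)
  b <- make_call("chr1", 510L, 1510L, n_reads = 2L)   # RO = 490/1000 = 0.49
  m <- merge_calls(bind_calls(a, b), cfg)
  expect_equal(nrow(m), 2L)
  # RO 0.50: merged
  b2 <- make_call("chr1", 500L, 1500L, n_reads = 2L)  # RO = 0.50
  m2 <- merge_calls(bind_calls(a, b2), cfg)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$n_reads, 5L)           # representative = most reads
  expect_equal(m2$n_merged, 2L)
  expect_equal(nrow(attr(m2, "merged_members")[[1]]), 2L)
  # RO 0.95, evidence 5 vs 2
  c2 <- make_call("chr1", 25L, 1025L, n_reads = 2L)
  m3 <- merge_calls(bind_calls(c2, a), cfg)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$n_reads, 5L)
  # idempotence and order independence on fuzzed call sets
  set.seed(23)
  for (k in 1:25) {
    n <- sample(2:12, 1)
    s <- sample.int(50000, n)
    calls <- do.call(bind_calls, lapply(seq_len(n), function(i)
      make_call("chr1", s[i], s[i] + sample(500:2000, 1),
                n_reads = sample(2:9, 1),
                coverage_fraction = stats::runif(1))))
    cols <- c("chrom", "start", "end", "confidence", "n_reads", "n_merged")
    m1 <- merge_calls(calls, cfg)
    m2 <- merge_calls(m1, cfg)
    expect_equal(as.data.frame(m1)[, cols], as.data.frame(m2)[, cols])
    perm <- sample(n)
    m3 <- merge_calls(bind_calls(calls[perm, ]), cfg)
    expect_equal(as.data.frame(m1)[, cols], as.data.frame(m3)[, cols])
  }
})

test_that("gene annotation uses any-overlap and sorts names", {
  genes <- data.frame(chrom = "chr1", start = c(100L, 900L, 5000L),
                      end = c(600L, 1500L, 6000L),
                      name = c("GB", "GA", "GC"), stringsAsFactors = FALSE)
  calls <- bind_calls(make_call("chr1", 200L, 1000L),     # spans GB and GA
                      make_call("chr1", 2000L, 3000L),    # none
                      make_call("chr1", 4001L, 5001L))    # 1 bp into GC
  out <- annotate_genes(calls, genes)
  expect_equal(out$gene_names, c("GA,GB", "", "GC"))
})

test_that("sample summaries count tiers, frequencies and log-binned sizes", {
  calls <- do.call(bind_calls, c(
    lapply(1:3, function(i) make_call("chr1", i * 10000L, i * 10000L + 5000L, "hconf")),
    lapply(1:2, function(i) make_call("chr2", i * 10000L, i * 10000L + 100L, "conf")),
    list(make_call("chr2", 90000L, 91000L, "lowq"))))
  s <- summarize_sample(calls, nuclei_count = 1e4)
  expect_equal(s$n_hconf, 3L)
  expect_equal(s$n_conf, 2L)
  expect_equal(s$n_lowq, 1L)
  expect_equal(s$n_total, 6L)
  expect_equal(s$per_100_nuclei, 6 / 1e4 * 100)
  expect_equal(sum(s$size_hist$count), 6L)
  # the 0.1-kb and 5-kb circles land in bins around log10(0.1) and log10(5)
  expect_true(any(abs(s$size_hist$log10_kb_bin - (-1)) < 0.11))
  expect_true(any(abs(s$size_hist$log10_kb_bin - log10(5)) < 0.11))
  s0 <- summarize_sample(empty_calls_public(), 1e6)
  expect_equal(s0$n_total, 0L)
  expect_equal(s0$per_100_nuclei, 0)
})
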
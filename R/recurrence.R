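# Cross-sample recurrence of circle calls and co-occurrence with external
# variant intervals, plus a seeded Monte Carlo placement null.

# Length-preserving uniform placement: chromosome drawn proportional to
# length among chromosomes that can hold the interval, start uniform.
place_random_intervals <- function(lengths, genome) {
  chroms <- names(genome)
  chr_len <- as.numeric(unclass(genome))
  out_chrom <- character(length(lengths))
  out_start <- numeric(length(lengths))
  for (i in seq_along(lengths)) {
    fit <- chr_len >= lengths[i]
    if (!any(fit)) stop("interval longer than every chromosome")
    w <- chr_len * fit
    ci <- sample.int(length(chroms), 1L, prob = w / sum(w))
    out_chrom[i] <- chroms[ci]
    out_start[i] <- floor(stats::runif(1, 0, chr_len[ci] - lengths[i] + 1))
  }
  data.frame(chrom = out_chrom, start = out_start,
             end = out_start + lengths, stringsAsFactors = FALSE)
}

#' Recurrent circles across samples
#'
#' Groups calls from distinct samples whose intervals agree at a
#' reciprocal overlap of at least `recurrence_reciprocal_overlap`
#' (default 0.90). Grouping is single linkage followed by a pairwise
#' check: groups in which some pair falls below the threshold are split
#' greedily (seed each subgroup with the best-supported remaining member
#' and add members compatible with all current ones). Only groups seen in
#' two or more distinct samples are reported, sorted by the number of
#' samples, descending.
#'
#' @param samples named list, sample id -> `ecc_calls` data.frame.
#' @param cfg a [detection_config()].
#' @return data.frame of recurrence records: representative `chrom`,
#'   `start`, `end`, `n_samples`, `n_calls`, `min_pairwise_ro`, `samples`
#'   (comma-separated ids), plus list column `hits` of the member calls
#'   (with a `sample_id` column).
#' @export
recurrent_circles <- function(samples, cfg = detection_config()) {
  stopifnot(length(samples) >= 2, !is.null(names(samples)))
  pooled <- do.call(rbind, lapply(names(samples), function(id) {
    df <- as.data.frame(samples[[id]])
    if (nrow(df) == 0L) return(NULL)
    data.frame(sample_id = id, chrom = df$chrom, start = df$start,
               end = df$end, confidence = df$confidence,
               n_reads = df$n_reads, stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_samples = integer(), n_calls = integer(),
                      min_pairwise_ro = numeric(), samples = character(),
                      stringsAsFactors = FALSE)
  empty$hits <- list()
  if (is.null(pooled) || nrow(pooled) < 2L) return(empty)
  o <- order(pooled$chrom, pooled$start, pooled$end, pooled$sample_id)
  pooled <- pooled[o, , drop = FALSE]
  n <- nrow(pooled)
  gr <- GenomicRanges::GRanges(pooled$chrom, IRanges::IRanges(pooled$start + 1L, pooled$end))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ro <- ro_vec(pooled$start[qi], pooled$end[qi], pooled$start[si], pooled$end[si])
  link <- ro >= cfg$recurrence_reciprocal_overlap
  parent <- seq_len(n)
  for (k in which(link)) {
    ri <- uf_find(parent, qi[k]); rj <- uf_find(parent, si[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  groups <- split(seq_len(n), root)

  pair_ok <- function(g) {
    if (length(g) < 2L) return(TRUE)
    cmb <- utils::combn(g, 2L)
    all(ro_vec(pooled$start[cmb[1, ]], pooled$end[cmb[1, ]],
               pooled$start[cmb[2, ]], pooled$end[cmb[2, ]]) >=
          cfg$recurrence_reciprocal_overlap)
  }
  # greedy split of chained groups
  refine <- function(g) {
    if (pair_ok(g)) return(list(g))
    rest <- g[order(-pooled$n_reads[g], pooled$start[g])]
    out <- list()
    while (length(rest)) {
      cur <- rest[1]; rest <- rest[-1]
      keep <- logical(length(rest))
      for (i in seq_along(rest)) {
        ok <- all(ro_vec(pooled$start[cur], pooled$end[cur],
                         pooled$start[rest[i]], pooled$end[rest[i]]) >=
                    cfg$recurrence_reciprocal_overlap)
        if (ok) { cur <- c(cur, rest[i]); keep[i] <- TRUE }
      }
      rest <- rest[!keep]
      out <- c(out, list(cur))
    }
    out
  }
  groups <- do.call(c, lapply(groups, refine))
  recs <- lapply(groups, function(g) {
    ids <- unique(pooled$sample_id[g])
    if (length(ids) < 2L) return(NULL)
    m <- pooled[g, , drop = FALSE]
    rep_i <- g[order(-pooled$n_reads[g], pooled$start[g])[1]]
    min_ro <- if (length(g) >= 2L) {
      cmb <- utils::combn(g, 2L)
      min(ro_vec(pooled$start[cmb[1, ]], pooled$end[cmb[1, ]],
                 pooled$start[cmb[2, ]], pooled$end[cmb[2, ]]))
    } else 1
    rec <- data.frame(chrom = pooled$chrom[rep_i], start = pooled$start[rep_i],
                      end = pooled$end[rep_i], n_samples = length(ids),
                      n_calls = length(g), min_pairwise_ro = min_ro,
                      samples = paste(sort(ids), collapse = ","),
                      stringsAsFactors = FALSE)
    rec$hits <- list(m)
    rec
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0L) return(empty)
  out <- do.call(rbind, recs)
  out <- out[order(-out$n_samples, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect large circle calls with a variant database
#'
#' Calls larger than `min_size` (default 25 kb) are intersected against
#' external variant intervals at a reciprocal overlap of at least
#' `variantdb_reciprocal_overlap` (default 0.99).
#'
#' @param calls an `ecc_calls` data.frame.
#' @param db data.frame of intervals (`chrom`, `start`, `end`, optional
#'   `name`), e.g. from [read_intervals()].
#' @param cfg a [detection_config()].
#' @param min_size size filter applied to the calls, in bp.
#' @return data.frame of hits: call coordinates, db coordinates, db
#'   `name`, `ro`.
#' @export
intersect_variant_db <- function(calls, db, cfg = detection_config(),
                                 min_size = 25000L) {
  calls <- as.data.frame(calls)
  calls <- calls[(calls$end - calls$start) > min_size, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      db_start = integer(), db_end = integer(),
                      db_name = character(), ro = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0L || nrow(db) == 0L) return(empty)
  gr_c <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$start + 1L, calls$end))
  gr_d <- GenomicRanges::GRanges(db$chrom, IRanges::IRanges(db$start + 1L, db$end))
  hits <- GenomicRanges::findOverlaps(gr_c, gr_d)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ro <- ro_vec(calls$start[qi], calls$end[qi], db$start[si], db$end[si])
  keep <- ro >= cfg$variantdb_reciprocal_overlap
  out <- data.frame(chrom = calls$chrom[qi][keep], start = calls$start[qi][keep],
                    end = calls$end[qi][keep], db_start = db$start[si][keep],
                    db_end = db$end[si][keep],
                    db_name = if (!is.null(db$name)) db$name[si][keep] else NA_character_,
                    ro = ro[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Monte Carlo null probability of cross-sample recurrence
#'
#' Places `calls_per_sample` length-preserving random intervals per
#' sample uniformly on the genome and counts replicates in which any
#' cross-sample pair reaches a reciprocal overlap of at least `ro`. The
#' add-one estimator `(hits + 1) / (replicates + 1)` keeps the
#' probability in `[1/(n+1), 1]`.
#'
#' @param interval_length length (bp) of the intervals to place.
#' @param genome an `ecc_genome_index`.
#' @param n_samples_total number of samples.
#' @param calls_per_sample intervals placed per sample.
#' @param cfg a [detection_config()] (supplies `mc_randomizations`).
#' @param seed RNG seed.
#' @param ro reciprocal-overlap threshold counted as a chance hit.
#' @return empirical probability.
#' @export
recurrence_null_probability <- function(interval_length, genome,
                                        n_samples_total = 2L,
                                        calls_per_sample = 1L,
                                        cfg = detection_config(),
                                        seed = cfg$seed, ro = 0.95) {
  n <- cfg$mc_randomizations
  if (n < 1L) stop("at least one randomization is required")
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(n)) {
    placed <- lapply(seq_len(n_samples_total), function(s)
      place_random_intervals(rep(interval_length, calls_per_sample), genome))
    found <- FALSE
    for (a in seq_len(n_samples_total - 1L)) {
      for (b in seq((a + 1L), n_samples_total)) {
        pa <- placed[[a]]; pb <- placed[[b]]
        for (i in seq_len(nrow(pa))) {
          same <- pb$chrom == pa$chrom[i]
          if (any(same) &&
              any(ro_vec(pa$start[i], pa$end[i], pb$start[same], pb$end[same]) >= ro)) {
            found <- TRUE; break
          }
        }
        if (found) break
      }
      if (found) break
    }
    if (found) hits <- hits + 1L
  }
  (hits + 1) / (n + 1)
}
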
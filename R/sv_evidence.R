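# Junction-evidence extraction. Three read classes point at a circle
# junction: reverse-forward discordant pairs (approximate coordinates),
# soft-clipped reads (one exact boundary), and split reads -- soft-clipped
# reads whose clipped fragment realigns on the same chromosome and strand,
# fixing both boundaries at base-pair resolution.

empty_evidence <- function() {
  data.frame(kind = character(), chrom = character(),
             start_hint = integer(), end_hint = integer(),
             start_exact = logical(), end_exact = logical(),
             read_name = character(), side = character(),
             stringsAsFactors = FALSE)
}

#' Classify the orientation of a mate pair
#'
#' Concordant mate pairs map forward-reverse (FR): the leftmost-starting
#' mate on the forward strand. A pair crossing a circle junction maps
#' reverse-forward (RF) instead.
#'
#' @param a,b single-row alignment records (lists or one-row data.frames
#'   with `chrom`, `start`, `strand`, `is_unmapped`).
#' @return `"FR"`, `"RF"` or `"other"`.
#' @export
classify_pair_orientation <- function(a, b) {
  if (isTRUE(a$is_unmapped) || isTRUE(b$is_unmapped)) {
    stop("cannot classify a pair with an unmapped mate")
  }
  if (a$chrom != b$chrom || a$strand == b$strand) return("other")
  left <- if (a$start <= b$start) a else b
  right <- if (a$start <= b$start) b else a
  if (left$strand == "+" && right$strand == "-") return("FR")
  if (left$strand == "-" && right$strand == "+") return("RF")
  "other"
}

evidence_eligible <- function(aln, cfg) {
  !aln$is_unmapped & !aln$is_secondary & !aln$is_supplementary &
    aln$mapq >= cfg$min_mapq &
    (cfg$use_duplicates | !aln$is_duplicate)
}

#' Extract discordant-pair junction evidence
#'
#' Reverse-forward mate pairs on one chromosome yield approximate circle
#' coordinates: the leftmost (reverse) mate start hints at the circle
#' start, the rightmost (forward) mate end at the circle end. Pairs whose
#' implied span exceeds the maximum circle size are dropped and counted.
#'
#' @param aln an `ecc_alignments` data.frame.
#' @param cfg a [detection_config()].
#' @return evidence data.frame (kind `"discordant"`) with attribute
#'   `n_dropped_span`.
#' @export
extract_discordant <- function(aln, cfg = detection_config()) {
  ok <- evidence_eligible(aln, cfg) & aln$is_paired
  r1 <- aln[ok & aln$is_read1, , drop = FALSE]
  r2 <- aln[ok & !aln$is_read1, , drop = FALSE]
  m <- match(r1$read_name, r2$read_name)
  keep <- !is.na(m)
  r1 <- r1[keep, , drop = FALSE]
  r2 <- r2[m[keep], , drop = FALSE]
  same <- r1$chrom == r2$chrom & r1$strand != r2$strand
  r1 <- r1[same, , drop = FALSE]; r2 <- r2[same, , drop = FALSE]
  if (nrow(r1) == 0L) return(structure(empty_evidence(), n_dropped_span = 0L))
  swap <- r1$start > r2$start
  L <- ifelse(swap, r2$strand, r1$strand)
  R <- ifelse(swap, r1$strand, r2$strand)
  rf <- L == "-" & R == "+"
  start_hint <- pmin(r1$start, r2$start)
  end_hint <- pmax(r1$end, r2$end)
  span_ok <- (end_hint - start_hint) <= cfg$max_circle_size
  n_drop <- sum(rf & !span_ok)
  sel <- rf & span_ok
  if (!any(sel)) return(structure(empty_evidence(), n_dropped_span = n_drop))
  ev <- data.frame(kind = "discordant", chrom = r1$chrom[sel],
                   start_hint = start_hint[sel], end_hint = end_hint[sel],
                   start_exact = FALSE, end_exact = FALSE,
                   read_name = r1$read_name[sel], side = "pair",
                   stringsAsFactors = FALSE)
  structure(ev, n_dropped_span = n_drop)
}

#' Extract soft-clip junction evidence
#'
#' A clip of at least `min_softclip_bases` marks one circle boundary
#' exactly: a left clip marks a candidate circle START at the read start,
#' a right clip a candidate END at the read end; the other boundary is
#' left open (`NA`) for clustering. Hard clips count toward the length
#' threshold but carry no sequence, so they can never seed realignment.
#'
#' @inheritParams extract_discordant
#' @return evidence data.frame (kind `"softclip"`), 0-2 rows per read.
#' @export
extract_softclip <- function(aln, cfg = detection_config()) {
  ok <- evidence_eligible(aln, cfg)
  a <- aln[ok, , drop = FALSE]
  lefts <- a[a$left_clip_len >= cfg$min_softclip_bases, , drop = FALSE]
  rights <- a[a$right_clip_len >= cfg$min_softclip_bases, , drop = FALSE]
  ev_l <- if (nrow(lefts)) data.frame(
    kind = "softclip", chrom = lefts$chrom,
    start_hint = lefts$start, end_hint = NA_integer_,
    start_exact = TRUE, end_exact = FALSE,
    read_name = lefts$read_name, side = "left_clip",
    clipped_seq = lefts$clipped_seq_left, anchor_strand = lefts$strand,
    sa_chrom = lefts$sa_chrom, sa_start = lefts$sa_start,
    sa_strand = lefts$sa_strand, sa_ref_width = lefts$sa_ref_width,
    stringsAsFactors = FALSE) else NULL
  ev_r <- if (nrow(rights)) data.frame(
    kind = "softclip", chrom = rights$chrom,
    start_hint = NA_integer_, end_hint = rights$end,
    start_exact = FALSE, end_exact = TRUE,
    read_name = rights$read_name, side = "right_clip",
    clipped_seq = rights$clipped_seq_right, anchor_strand = rights$strand,
    sa_chrom = rights$sa_chrom, sa_start = rights$sa_start,
    sa_strand = rights$sa_strand, sa_ref_width = rights$sa_ref_width,
    stringsAsFactors = FALSE) else NULL
  ev <- rbind(ev_l, ev_r)
  if (is.null(ev)) ev <- cbind(empty_evidence(),
                               data.frame(clipped_seq = character(),
                                          anchor_strand = character(),
                                          sa_chrom = character(),
                                          sa_start = integer(),
                                          sa_strand = character(),
                                          sa_ref_width = integer()))
  ev
}

#' Realign a clipped fragment near its anchor
#'
#' Searches the anchor chromosome within one maximum circle size of the
#' clip coordinate for an ungapped, same-strand match of the clipped
#' sequence, using exact k-mer seeding plus identity scoring. The best
#' locus is accepted at identity >= `realign_min_identity`; a tie between
#' distinct best loci is treated as ambiguous and rejected.
#'
#' @param clipped_seq clipped nucleotide sequence (genome-forward
#'   orientation, as stored in the alignment record).
#' @param chrom,anchor_pos anchor chromosome and clip coordinate (0-based).
#' @param reference named `Biostrings::DNAStringSet`.
#' @param cfg a [detection_config()].
#' @return `NULL`, or `list(start, end)` of the fragment's alignment
#'   (0-based half-open).
#' @export
realign_clipped_fragment <- function(clipped_seq, chrom, anchor_pos,
                                     reference, cfg = detection_config()) {
  if (is.na(clipped_seq) || !chrom %in% names(reference)) return(NULL)
  len <- nchar(clipped_seq)
  if (len < cfg$realign_kmer) return(NULL)
  chr_seq <- reference[[chrom]]
  chr_len <- length(chr_seq)
  win_lo <- max(0L, as.integer(anchor_pos) - cfg$max_circle_size)  # 0-based
  win_hi <- min(chr_len, as.integer(anchor_pos) + cfg$max_circle_size)
  window <- Biostrings::subseq(chr_seq, win_lo + 1L, win_hi)

  offsets <- unique(c(1L, max(1L, (len - cfg$realign_kmer) %/% 2L + 1L),
                      len - cfg$realign_kmer + 1L))
  cand <- integer(0)
  for (off in offsets) {
    seed <- substring(clipped_seq, off, off + cfg$realign_kmer - 1L)
    hits <- Biostrings::matchPattern(seed, window)
    if (length(hits)) {
      # candidate fragment starts, 0-based on the chromosome
      cand <- c(cand, win_lo + BiocGenerics::start(hits) - 1L - (off - 1L))
    }
  }
  cand <- unique(cand)
  cand <- cand[cand >= 0L & cand + len <= chr_len]
  if (length(cand) == 0L) return(NULL)
  frag <- Biostrings::DNAString(clipped_seq)
  ident <- vapply(cand, function(s) {
    ref_sub <- Biostrings::subseq(chr_seq, s + 1L, s + len)
    1 - Biostrings::neditStartingAt(frag, ref_sub, starting.at = 1L) / len
  }, numeric(1))
  best <- max(ident)
  if (best < cfg$realign_min_identity) return(NULL)
  winners <- cand[ident == best]
  if (length(winners) > 1L) return(NULL)  # ambiguous
  list(start = winners, end = winners + len)
}

# Upgrade soft-clip evidence to split evidence where the clipped fragment
# locus is known: from the SA tag when it is consistent (same chromosome,
# same strand), otherwise by realignment against the reference.
upgrade_softclips <- function(sc, reference = NULL, cfg = detection_config()) {
  if (nrow(sc) == 0L) return(sc)
  for (i in seq_len(nrow(sc))) {
    frag <- NULL
    if (!is.na(sc$sa_chrom[i]) && sc$sa_chrom[i] == sc$chrom[i] &&
        !is.na(sc$sa_strand[i]) && sc$sa_strand[i] == sc$anchor_strand[i] &&
        !is.na(sc$sa_ref_width[i])) {
      frag <- list(start = sc$sa_start[i], end = sc$sa_start[i] + sc$sa_ref_width[i])
    } else if (!is.null(reference) && !is.na(sc$clipped_seq[i]) &&
               nchar(sc$clipped_seq[i]) >= cfg$min_softclip_bases) {
      frag <- realign_clipped_fragment(sc$clipped_seq[i], sc$chrom[i],
                                       if (sc$side[i] == "left_clip") sc$start_hint[i] else sc$end_hint[i],
                                       reference, cfg)
    }
    if (is.null(frag)) next
    if (sc$side[i] == "left_clip") {
      # anchor starts the circle at s; the fragment is the junction-side
      # end of the circle, so its alignment end is the circle end
      s <- sc$start_hint[i]; e <- frag$end
    } else {
      # anchor ends the circle at e; fragment alignment start is the start
      s <- frag$start; e <- sc$end_hint[i]
    }
    if (!is.na(s) && !is.na(e) && s < e && (e - s) <= cfg$max_circle_size) {
      sc$kind[i] <- "split"
      sc$start_hint[i] <- s; sc$end_hint[i] <- e
      sc$start_exact[i] <- TRUE; sc$end_exact[i] <- TRUE
    }
  }
  sc
}

#' Extract all junction evidence from an alignment set
#'
#' Runs discordant-pair, soft-clip and split-read extraction and returns
#' one combined evidence table. A soft-clipped read whose clipped fragment
#' places on the same chromosome and strand (via its supplementary-locus
#' annotation, or by realignment when a reference is given) is upgraded to
#' a single split evidence -- never double-counted.
#'
#' @inheritParams extract_discordant
#' @param reference optional named `DNAStringSet` for clipped-fragment
#'   realignment.
#' @return evidence data.frame with columns `kind`, `chrom`, `start_hint`,
#'   `end_hint`, `start_exact`, `end_exact`, `read_name`, `side`.
#' @export
extract_evidence <- function(aln, cfg = detection_config(), reference = NULL) {
  sc <- upgrade_softclips(extract_softclip(aln, cfg), reference, cfg)
  sc <- sc[, names(empty_evidence())]
  disc <- extract_discordant(aln, cfg)
  ev <- rbind(sc, disc[, names(empty_evidence())])
  rownames(ev) <- NULL
  structure(ev, n_dropped_span = attr(disc, "n_dropped_span"))
}

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster junction evidence into candidate circles
#'
#' Groups evidence whose implied circle intervals are mutually compatible,
#' by transitive closure: exact coordinates must agree within a few bases,
#' inexact hints within about one insert size. Consensus coordinates come
#' from the modal exact coordinate where one exists, otherwise from the
#' extremal hints. The result is independent of input order.
#'
#' @param ev evidence data.frame from [extract_evidence()].
#' @param cfg a [detection_config()].
#' @return data.frame of clusters: `chrom`, `consensus_start`,
#'   `consensus_end`, `n_distinct_reads`, `n_split`, `n_softclip`,
#'   `n_discordant`, plus a list column `members` of evidence row indices.
#' @export
cluster_evidence <- function(ev, cfg = detection_config()) {
  out <- data.frame(chrom = character(), consensus_start = integer(),
                    consensus_end = integer(), n_distinct_reads = integer(),
                    n_split = integer(), n_softclip = integer(),
                    n_discordant = integer(), stringsAsFactors = FALSE)
  out$members <- list()
  if (nrow(ev) == 0L) return(out)
  # canonical order so clustering is invariant to input order
  o <- order(ev$chrom, ifelse(is.na(ev$start_hint), ev$end_hint, ev$start_hint),
             ifelse(is.na(ev$end_hint), ev$start_hint, ev$end_hint),
             ev$kind, ev$read_name, ev$side)
  ev <- ev[o, , drop = FALSE]
  orig_idx <- o
  n <- nrow(ev)
  parent <- seq_len(n)
  s <- ev$start_hint; e <- ev$end_hint
  sx <- ev$start_exact; ex <- ev$end_exact
  for (chr in unique(ev$chrom)) {
    idx <- which(ev$chrom == chr)
    if (length(idx) < 2L) next
    for (a in seq_len(length(idx) - 1L)) {
      i <- idx[a]
      j <- idx[seq(a + 1L, length(idx))]
      s_both <- !is.na(s[i]) & !is.na(s[j])
      tol_s <- ifelse(sx[i] & sx[j], cfg$exact_tolerance_bp, cfg$cluster_tolerance_bp)
      ok_s <- !s_both | (abs(s[i] - s[j]) <= tol_s)
      e_both <- !is.na(e[i]) & !is.na(e[j])
      tol_e <- ifelse(ex[i] & ex[j], cfg$exact_tolerance_bp, cfg$cluster_tolerance_bp)
      ok_e <- !e_both | (abs(e[i] - e[j]) <= tol_e)
      lo <- pmin(s[i], s[j], na.rm = TRUE)
      hi <- pmax(e[i], e[j], na.rm = TRUE)
      sane <- !is.na(lo) & !is.na(hi) & lo < hi & (hi - lo) <= cfg$max_circle_size
      ok <- (s_both | e_both) & ok_s & ok_e & sane
      for (jj in j[ok]) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, jj)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  groups <- split(seq_len(n), root)
  res <- lapply(groups, function(g) {
    m <- ev[g, , drop = FALSE]
    cs <- consensus_coord(m$start_hint, m$start_exact, extremal = min)
    ce <- consensus_coord(m$end_hint, m$end_exact, extremal = max)
    data.frame(chrom = m$chrom[1], consensus_start = cs, consensus_end = ce,
               n_distinct_reads = length(unique(m$read_name)),
               n_split = sum(m$kind == "split"),
               n_softclip = sum(m$kind == "softclip"),
               n_discordant = sum(m$kind == "discordant"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$members <- lapply(groups, function(g) sort(orig_idx[g]))
  o2 <- order(out$chrom, out$consensus_start, out$consensus_end)
  out <- out[o2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

consensus_coord <- function(hints, exact, extremal) {
  ex <- hints[exact & !is.na(hints)]
  if (length(ex)) {
    tab <- table(ex)
    cands <- as.integer(names(tab)[tab == max(tab)])
    return(min(cands))
  }
  h <- hints[!is.na(hints)]
  if (length(h) == 0L) return(NA_integer_)
  as.integer(extremal(h))
}
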
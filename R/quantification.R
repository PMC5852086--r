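# Spike-in anchored quantification, read-class fractions, saturation
# decimation curves, and the qPCR genome-count helper.

#' Fraction of mapped reads per sequence class
#'
#' For alignments against a custom reference whose contigs carry class
#' labels (repeat consensus sequences, spike-in plasmids, ...), computes
#' the fraction of mapped primary reads assigned to each class. Contigs
#' without a label are counted under `"other"`.
#'
#' @param aln an `ecc_alignments` data.frame.
#' @param class_map named character vector, contig name -> class label,
#'   or a two-column data.frame (`contig`, `class`).
#' @return named numeric vector of fractions summing to 1 (including
#'   `"other"`), with attribute `n_reads` (total mapped primary reads).
#' @export
read_class_fractions <- function(aln, class_map) {
  if (is.data.frame(class_map)) {
    class_map <- stats::setNames(as.character(class_map[[2]]),
                                 as.character(class_map[[1]]))
  }
  keep <- !aln$is_unmapped & !aln$is_secondary & !aln$is_supplementary
  a <- aln[keep, , drop = FALSE]
  cls <- unname(class_map[a$chrom])
  cls[is.na(cls)] <- "other"
  n <- nrow(a)
  if (n == 0L) return(structure(stats::setNames(numeric(0), character(0)), n_reads = 0L))
  tab <- table(cls)
  structure(stats::setNames(as.numeric(tab) / n, names(tab)), n_reads = n)
}

#' Copies per nucleus from spike-in read fractions
#'
#' Anchors a target's abundance to a spike-in plasmid of known copy
#' number: `copies = (target_fraction / spike_fraction) *
#' (copies_added / nuclei_in_sample) * (spike_length / target_length)`.
#' The length correction reflects that read counts scale with template
#' mass rather than copy number; `length_correction = FALSE` disables it
#' to mimic the equal-length case. These are rough estimates: rolling
#' circle amplification biases read counts toward abundant, small
#' templates.
#'
#' @param target_fraction fraction of mapped reads on the target class.
#' @param target_length_bp target template length.
#' @param spike one row of [spike_in_controls()] (or any list with
#'   `length_bp`, `copies_added`, `nuclei_in_sample`).
#' @param spike_fraction fraction of mapped reads on the spike-in; must be
#'   positive (a spike-in that was not recaptured cannot anchor anything).
#' @param length_correction apply the template-length correction.
#' @return estimated copies per nucleus.
#' @export
#' @examples
#' sp <- spike_in_controls()[spike_in_controls()$name == "pUG72", ]
#' copies_per_nucleus(0.001, sp$length_bp, sp, 0.001)  # 50000/1e6 = 0.05
copies_per_nucleus <- function(target_fraction, target_length_bp, spike,
                               spike_fraction, length_correction = TRUE) {
  if (spike_fraction <= 0) stop("spike-in not recaptured (fraction <= 0)")
  stopifnot(target_fraction >= 0, target_length_bp > 0)
  est <- (target_fraction / spike_fraction) *
    (spike$copies_added / spike$nuclei_in_sample)
  if (length_correction) est <- est * (spike$length_bp / target_length_bp)
  est
}

# Deterministic nested subsampling: a seeded permutation rank over the
# sorted set of read names; the fraction-f subset is the first
# round(f * n) names, so smaller fractions are subsets of larger ones and
# pair integrity is automatic (both mates share the name).
subsample_ranks <- function(read_names, seed) {
  nm <- sort(unique(read_names))
  set.seed(seed)
  stats::setNames(sample.int(length(nm)), nm)
}

#' Read-decimation saturation curve
#'
#' Reruns detection on nested read subsets at fractions `step, 2*step,
#' ..., 1` (default 10% intervals), keeping or dropping read pairs
#' together, and records the number of circles called at each level. The
#' fraction-1 point reproduces the full run exactly; smaller fractions
#' are subsets of larger ones, so the curve is smooth and reproducible
#' for a given seed.
#'
#' @param aln an `ecc_alignments` data.frame.
#' @param cfg a [detection_config()] (supplies `decimation_step` and
#'   `seed`).
#' @param pipeline_callback function(subset alignment data.frame) ->
#'   `ecc_calls`; defaults to [detect_circles()] with `cfg`.
#' @return data.frame: `fraction`, `n_reads`, `n_pairs`, `n_circles`,
#'   `circles_per_million_reads`.
#' @export
decimation_curve <- function(aln, cfg = detection_config(),
                             pipeline_callback = NULL) {
  if (is.null(pipeline_callback)) {
    pipeline_callback <- function(a) detect_circles(a, cfg = cfg)
  }
  fractions <- seq(cfg$decimation_step, 1, by = cfg$decimation_step)
  ranks <- subsample_ranks(aln$read_name, cfg$seed)
  n_pairs_total <- length(ranks)
  res <- lapply(fractions, function(f) {
    k <- round(f * n_pairs_total)
    sub <- aln[ranks[aln$read_name] <= k, , drop = FALSE]
    calls <- pipeline_callback(sub)
    n_reads <- nrow(sub)
    data.frame(fraction = f, n_reads = n_reads, n_pairs = k,
               n_circles = nrow(calls),
               circles_per_million_reads =
                 if (n_reads > 0) nrow(calls) / n_reads * 1e6 else 0)
  })
  do.call(rbind, res)
}

#' Diploid genome count from a DNA mass
#'
#' Converts a DNA mass to a diploid genome (cell) equivalent using the
#' published constant of 6.77e-3 ng DNA per diploid cell (derived from a
#' genome length of 3.14e9 bp at 650 g/mol per base pair; recomputing
#' from those constants gives 6.78e-3 ng -- the printed value is kept as
#' the default and can be overridden).
#'
#' @param dna_mass_ng DNA mass in nanograms (>= 0).
#' @param ng_per_diploid_cell mass constant; default `6.77e-3`.
#' @return number of diploid genomes.
#' @export
#' @examples
#' genomes_from_mass(6.77e-3)  # one cell
genomes_from_mass <- function(dna_mass_ng, ng_per_diploid_cell = 6.77e-3) {
  if (any(dna_mass_ng < 0)) stop("mass must be non-negative")
  dna_mass_ng / ng_per_diploid_cell
}

#' The per-cell DNA mass derived from first principles
#'
#' `2 * genome_length * bp_molar_mass / N_A`, in ng; with the default
#' constants this is 6.78e-3 ng, marginally above the published 6.77e-3.
#'
#' @param genome_length_bp haploid genome length.
#' @param bp_molar_mass g/mol per base pair.
#' @return ng of DNA per diploid cell.
#' @export
derive_ng_per_diploid_cell <- function(genome_length_bp = 3.14e9,
                                       bp_molar_mass = 650) {
  2 * genome_length_bp * bp_molar_mass / 6.02214076e23 * 1e9
}
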
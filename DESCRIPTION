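Package: circlescan
Title: Detection of Extrachromosomal Circular DNA from Circle-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects extrachromosomal circular DNA (eccDNA) from
    coordinate-sorted paired-end alignments of circle-enriched sequencing
    libraries. Junction-crossing evidence (reverse-forward discordant pairs,
    soft-clipped reads, and split reads obtained by realigning clipped
    fragments) is clustered into candidate circles, which are ranked into
    three confidence tiers by internal read coverage relative to flanking
    regions. Includes cross-sample recurrence analysis by reciprocal
    overlap, junction-transcript detection from RNA split reads with a
    Monte Carlo overlap null, spike-in based per-nucleus copy estimation,
    read-decimation saturation curves, and a simulator that generates toy
    genomes and reads with the exact junction geometry the detector
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
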
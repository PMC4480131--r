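Package: mnasechip
Title: Fragment-Level Analysis and Simulation of High-Resolution MNase ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of MNase-fragmented crosslinking ChIP-seq
    (X-ChIP-seq), where paired-end fragments delimit protein-protected DNA
    footprints. Reads fragments from BEDPE, fragment BED or paired-end BAM;
    stratifies them into insert-length size classes; computes per-base
    coverage normalized as the fraction of mapped fragments spanning each
    position times the genome size; builds motif-centered signal matrices,
    fragment-end profiles and midpoint-versus-length V-plots with strand
    flipping; and quantifies resolution with per-site half-height peak
    widths, end-peak pair separations and a motif spacing filter. Includes
    a seeded synthetic-data generator (footprint protection with geometric
    exonuclease chew-back, nucleosomal and composite background,
    accessibility-biased sonication, logistic bead size selection) with
    full ground truth, and a configured end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    IRanges,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
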
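Package: fusionframe
Title: Reading-Frame Annotation of Gene Fusions and Cohort Statistics for
    Diffuse Gastric Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for annotating chimeric (fusion) transcripts from
    breakpoint coordinates: mapping genomic breakpoints onto transcript
    models, constructing the fused cDNA, classifying the reading frame of
    the chimera (in-frame, frameshift, promoter swap, junction stop),
    computing retained amino-acid spans and retained protein domains
    (e.g. RhoGAP, PAP2), and scoring breakpoint-consistent exon-level
    expression imbalance.  A cohort layer provides recurrence and
    prevalence counting, mutual-exclusivity tests, Kaplan-Meier and Cox
    proportional-hazards survival analysis, and log-rank sample-size
    estimation.  A synthetic-data generator produces genomes, gene
    models, fusion candidates with known truth labels, exon expression
    matrices and clinical cohorts so the whole pipeline is testable
    without access to patient-level sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    survival,
    optparse,
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
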
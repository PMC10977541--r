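Package: rcnvseq
Title: Low-Pass Whole-Genome Copy Number Analysis for Rapid Prenatal Diagnosis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bin-based copy number estimation from shallow single-end
    whole-genome sequencing of prenatal samples. Reads are trimmed, filtered
    for unique mapping, counted in fixed-width genomic bins (20 kb by
    default), GC-corrected and normalized to the diploid copy-number scale;
    segments are detected with a deterministic multi-scale scan and
    classified as duplication, mosaic trisomy, disomy, mosaic monosomy or
    deletion. Calls are reported in ISCN-style cytoband nomenclature with
    HGVS-like g. coordinates and triaged into diagnostic categories (common
    and rare aneuploidies, sex-chromosome aneuploidy, multi-chromosome
    abnormality, pathogenic and uncertain copy number variants). Includes a
    synthetic sequencing simulator with configurable karyotypes, mosaic
    fractions and GC bias, an ISCN karyotype-string parser, and cohort-level
    detection-rate, demographic and outcome summaries, together with a
    reconstructed high-risk prenatal cohort for end-to-end checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
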
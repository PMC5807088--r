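Package: tetraBSA
Title: Bulk Segregant Analysis of Pooled Diploid Segregants from Tetraploid Meiosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for mapping recessive loci in
    infertile mutants by somatic hybridization followed by bulk segregant
    analysis (BSA). Models tetrasomic meiosis of a duplex (m/m/+/+) hybrid with
    random bivalent pairing, produces diploid segregant pools, simulates pooled
    sequencing read counts at strain-distinguishing markers, and recovers the
    causal interval from the characteristic mutant-pool allele-frequency peak
    of 1 and wild-type-pool frequency of 0.4. Includes coverage/quality variant
    filters, sliding-window frequency tracks, candidate-interval detection,
    premature-stop-codon effect annotation with HGVS-like labels, and
    chi-square goodness-of-fit machinery for the 1:4:1 tetrasomic segregation
    ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
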
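Package: zombiefish
Title: Image Cytometry and Statistics for Phage-Infected and Zombie SAR11 Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification machinery for multi-channel FISH surveys of
    pelagiphage infection in SAR11 (Pelagibacterales) populations: a
    ground-truthed synthetic microscopy field generator (DNA / 16S rRNA /
    phage-gene channels under Gaussian point-spread blur and additive
    noise), image cytometry with size gating and four-way cell
    classification (total, SAR11, phage-infected, zombie) including
    free-phage exclusion and the frequency-of-dividing-cells statistic,
    direct-geneFISH polynucleotide probe design under length, GC and
    nucleotide-identity constraints, RPKM-based metagenomic abundance
    formulas, and the survey's statistical models: Welch's t-test,
    one-within-factor repeated-measures ANOVA, and logit-link Bayesian
    beta regression fitted by adaptive random-walk Metropolis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    igraph,
    EBImage,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmmTMB,
    knitr,
    rmarkdown
Config/testthat/edition: 3
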
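Package: popgenstats
Title: Basic Statistics of Molecular Population Genetics from Summary Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes 45 classical statistics of molecular population
    genetics directly from descriptive summary metadata (allele and
    haplotype frequencies, segregating-site and mutation-class counts,
    site-frequency spectra, mismatch distributions, per-population
    genotype counts and microsatellite allele sizes) rather than from raw
    sequence alignments.  The catalogue covers three classes: genetic
    diversity (heterozygosity, haplotype diversity, nucleotide diversity,
    mean pairwise differences, polymorphism information content),
    site-frequency-spectrum, haplotype and mismatch neutrality tests
    (Tajima's D, the Fu and Li family, Ewens-sampling haplotype tests,
    Fay and Wu's H, Zeng's E, the Ramos-Onsins singleton family,
    mismatch raggedness, Kelly's linkage-disequilibrium Z statistics) and
    population differentiation (Wright's F statistics, Nei's gene
    diversity decomposition, Hedrick's standardized G'ST, Jost's D,
    allele-size R_ST and the Weir-Cockerham variance-component
    estimators).  Each statistic is one independent, individually
    testable function; a subcommand-per-statistic command line interface
    and a small neutral-coalescent and Dirichlet-multinomial simulator
    for calibration and testing are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
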
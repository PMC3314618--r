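Package: amphap454
Title: Diploid Haplotype Calling from Multiplexed 454 Amplicon Pyrosequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted amplicon pyrosequencing of nuclear intron
    (EPIC) markers in non-model organisms. Demultiplexes clonally amplified
    454-style reads by dual-end MID barcode and locus-specific primer,
    applies length, mean-quality and modified-Mott trimming filters, builds
    per-individual per-locus read pileups by star alignment, calls diploid
    genotypes with a 75 percent consensus heterozygote rule, arbitrates
    homopolymer length variants by majority consensus and quality, detects
    and removes PCR-chimeric (recombinant) reads, and curates alleles at the
    population level by singleton homopolymer correction. Includes a
    ground-truthed simulator of multiplexed amplicon libraries, summary
    statistics (coverage, heterozygosity, allelic ratios), and closed-form
    experiment-design and Sanger-versus-pyrosequencing cost arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
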
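Package: methApT
Title: Symmetric ApT 6mA Methylome Analysis for Haploid Fungal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream characterization of N6-methyldeoxyadenine (6mA)
    methylomes from single-molecule per-strand modification calls, aimed at
    coenocytic fungi with haploid nuclei where the per-site methylation ratio
    reflects the fraction of nuclei carrying the mark. Filters
    kineticsTools-style calls, pairs plus- and minus-strand calls into
    symmetric ApT dinucleotide sites, summarizes motif spectra and
    methylation-ratio distributions, tests per-site ratio divergence between
    samples with Clopper-Pearson intervals, assigns sites to promoter, gene
    body and downstream regions, relates gene-body methylation density to
    expression via Kendall's tau-b, compares structural-variant callsets by
    reciprocal overlap with Jaccard-distance clustering and bootstrap support,
    and converts LC-MS nucleoside quantities into percent 5mC and 6mA. A
    seeded synthetic-data generator emits every input format with known ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
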
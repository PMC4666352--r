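Package: intriplex
Title: Intrastrand Triplex DNA Motifs and Their Genomic Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans DNA sequences for intrastrand triplex motifs of the four
    conformational classes (I-IV) using stem/loop/mismatch rules, finds and
    classifies the G/C-rich TM consensus motif abundant in Escherichia coli
    (types A and B, inverted-repeat pairs), produces mononucleotide-scrambled
    control genomes, summarises scans against those controls, and quantifies
    the genetic variability of motif-associated loci from multiple alignments
    (windowed column-diversity statistic, variable-region calling) and from
    BLAST tabular homology (locus categorisation). Includes seeded generators
    for synthetic genomes and alignments, a packaged reference set of the 23
    E. coli K-12 MG1655 TM motifs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
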
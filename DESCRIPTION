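Package: denovoscan
Title: Identification of Candidate De Novo Genes from Assembled Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying candidate de novo genes
    (genes born from ancestrally intergenic DNA) among de novo assembled
    transcripts. Implements a multi-database homology screening cascade with
    an explicit match criterion (80 percent identity over at least 100
    alignment columns), genomic placement, structural filters (transcript
    length, distance to the nearest annotated exon, intergenic context), a
    TPM expression filter with an isoform-rescue rule, microsynteny
    validation of candidate loci against outgroup genomes via flanking
    orthologs, and six-frame ORF discovery for downstream coding-potential
    tools. Ships a fully labelled synthetic genome/transcriptome simulator
    so that every filter stage can be tested against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
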
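Package: agioskit
Title: Average Genomic Identity of Orthologous Gene Sequences for Bacterial Taxonomy
Version: 0.1.0
Authors@R: person("agioskit", "developers", role = c("aut", "cre"),
    email = "agioskit@example.org")
Description: Genome-relatedness statistics for bacterial taxono-genomics.
    Detects orthologous genes between annotated genomes by reciprocal best
    hit over Smith-Waterman protein similarity, then computes the mean
    Needleman-Wunsch nucleotide percent identity over orthologous gene
    pairs (AGIOS), assembling multi-genome matrices of gene counts, shared
    ortholog counts, and mean identities. Also provides ORFan
    classification under E-value/alignment-length thresholds, genome
    summary statistics (size, G+C content, coding density, COG category
    tables), 16S rRNA identity with the 98.7 percent species-delineation
    threshold, and a synthetic ancestor-descendant genome simulator that
    supplies ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
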
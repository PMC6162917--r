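Package: sagmag
Title: Comparative Evaluation of Single-Amplified and Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing bacterial genomes recovered by single-cell
    sequencing (single-amplified genomes, SAGs) with genomes recovered by
    metagenome binning (metagenome-assembled genomes, MAGs): MinHash genome
    sketching and single-linkage clustering, attribution of SAG reads to
    categories of binned metagenome contigs with a false-negative binning-rate
    statistic, detection of MDA inversion-chimera reads from soft-clipped
    alignments, a tetranucleotide-composition and coverage contamination
    screen, single-copy-gene completeness and redundancy quality control,
    and permutation ANOSIM on Poisson dissimilarities of functional profiles.
    A fully labelled synthetic community generator plants every artifact
    class (misbinned contigs, amplification dropout, inversion chimeras,
    foreign contamination) so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    Rsamtools,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
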
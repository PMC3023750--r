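Package: traitscan
Title: Partial Phylogenetic Profiling, Subsequence Trait Mapping and Short-ORF
    Motif Discovery for Comparative Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining genome collections for proteins whose
    distribution tracks a phenotypic or genomic trait. Implements Partial
    Phylogenetic Profiling (PPP): each protein's ranked similarity hit list is
    walked over all score cutoffs and scored by the log10 binomial upper-tail
    probability of the trait-positive genome count at the optimal cutoff.
    Implements SIMBAL-style subsequence mapping: every window of a probe
    protein is scored the same way against a trait-partitioned, dereplicated
    training set, yielding a triangular window-by-length score surface whose
    hot spots localize trait-diagnostic sites. Also provides six-frame
    translation and short-ORF scanning for conserved C-terminal peptide
    motifs, alignment column conservation statistics, a deterministic
    Smith-Waterman similarity backend, a BLAST tabular (outfmt 6) reader, and
    a seeded synthetic genome-collection generator with planted marker
    systems, trait-restricted paralog families, diagnostic subsequence
    windows and precursor genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
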
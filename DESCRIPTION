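Package: repframe
Title: Framework-Mutation Scoring of Antibodies from Baseline Repertoire PSSMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds germline-specific position-specific scoring matrices (PSSMs)
    for antibody heavy-chain framework mutations from baseline immunoglobulin
    repertoire sequences, and scores framework mutations of query antibodies
    against them. Per-position amino-acid substitution counts are masked for
    wild-type and allelic residues, pseudocounted, and log-transformed with a
    germline-specific centering constant so that a randomly chosen framework
    mutation scores zero on average. Antibody-level framework (FR) scores
    normalize the sum of mutation scores by a quadratic least-squares model of
    typical repertoire score sums at the same mutation load. Supporting
    analyses include minimum nucleotide-substitution distances between codons
    and residues, maturation summaries (per-position mutation frequency,
    germline identity, dN/dS), PSSM correlation and UPGMA clustering,
    subsampling convergence, and binning of peptide:MHC-II affinity
    fold-changes. A mechanistic somatic-hypermutation simulator provides
    ground-truth repertoires for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
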
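# Synthetic germline references bundled for examples, tests and simulation.
# These are NOT real immunoglobulin germline genes: the nucleotide sequences
# were generated once (random sense codons behind a fixed leader) and frozen,
# so nothing here reproduces a database sequence. Gene names carry an "S"
# (synthetic) family tag.

SYN_GL1_NT <- paste0(
  "GAAGTCCAGCTTGTAGAATCAGGGGGTGGGTTAGTACAACCAGGGGGTTCTCTTCGACTATCATGCGCC",
  "GCGTCGAAGGAAAGGTCCAAGAGATTGATCTGTCAAACATCCTACTGTGCCCTCCCGCTCTTACGTACC",
  "CGGGTGCATGCAACCCCAACCAGCTTCCCGGCCTTCCGGCTGAGCGCAAGTGATGCGAGCATTGCGTCA",
  "TCTTTGGAACCTAACGATCCTCTCAGACGTACGCATATGGAGACAATTCGTCGCATGGCTCTTGGGGGC",
  "CAGGGTCTGGCTACCCAA")

# Allele *02 of the same gene: one nonsynonymous difference at amino-acid
# position 75 (GAT -> ATG, D75M), mimicking a framework allelic variant.
SYN_GL1_02_NT <- paste0(
  "GAAGTCCAGCTTGTAGAATCAGGGGGTGGGTTAGTACAACCAGGGGGTTCTCTTCGACTATCATGCGCC",
  "GCGTCGAAGGAAAGGTCCAAGAGATTGATCTGTCAAACATCCTACTGTGCCCTCCCGCTCTTACGTACC",
  "CGGGTGCATGCAACCCCAACCAGCTTCCCGGCCTTCCGGCTGAGCGCAAGTGATGCGAGCATTGCGTCA",
  "TCTTTGGAACCTAACATGCCTCTCAGACGTACGCATATGGAGACAATTCGTCGCATGGCTCTTGGGGGC",
  "CAGGGTCTGGCTACCCAA")

# A related synthetic gene: ~20% of codons replaced relative to SYN_GL1.
SYN_GL2_NT <- paste0(
  "GAAGTCCAGCTTGTAGAATCAGGGGGTGGGTTAGTAGCAGCAGGGGGTCCTCTTGTCTTATCATGCGCC",
  "CGACCAAAGTCCAGGTCCAAGGACTTGATCTGTCAAACATCCTACTGTGCCCTCTATCTCTTACGTACC",
  "CGGGTGCATGCAACCCCAACCAGCTTCCCGGCCTTCCGGGCGAGCCCTGGCGATGCGCGGATTGCGTCA",
  "TCTTTGGAACCTAACGATCCTCTCAGAGGAGCCCATATGCAAGTAATTTCTCGCATGGCTCTTCGGGGC",
  "CAGGGTCTGGCTACCCAA")

#' Region windows of the bundled 98-residue synthetic germlines
#'
#' Sequential (ungapped) coordinates: FR1 = 1-25, CDR1 = 26-33, FR2 = 34-50,
#' CDR2 = 51-58, FR3 = 59-98.
#'
#' @return Data frame with columns `region`, `start`, `end`.
#' @export
synthetic_vh_regions <- function() {
  data.frame(region = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
             start = c(1L, 26L, 34L, 51L, 59L),
             end   = c(25L, 33L, 50L, 58L, 98L))
}

#' Bundled synthetic germline references
#'
#' `synthetic_germline()` returns one of the frozen synthetic V-heavy-like
#' references shipped with the package (294 nt / 98 aa, no relation to real
#' IMGT genes): gene `"VH3-S1"` with alleles `*01` and `*02` (the alleles
#' differ by a single nonsynonymous change, D75M, emulating a framework
#' allelic variant) and a related gene `"VH3-S2"`.
#'
#' @param allele One of `"VH3-S1*01"`, `"VH3-S1*02"`, `"VH3-S2*01"`.
#' @return A [germline_reference()].
#' @export
synthetic_germline <- function(allele = "VH3-S1*01") {
  regs <- synthetic_vh_regions()
  switch(allele,
    "VH3-S1*01" = germline_reference("VH3-S1", "VH3-S1*01", SYN_GL1_NT, regs),
    "VH3-S1*02" = germline_reference("VH3-S1", "VH3-S1*02", SYN_GL1_02_NT, regs),
    "VH3-S2*01" = germline_reference("VH3-S2", "VH3-S2*01", SYN_GL2_NT, regs),
    stop("unknown bundled synthetic allele: ", allele))
}

#' @rdname synthetic_germline
#' @return `synthetic_germline_set()`: a named list of all three references.
#' @export
synthetic_germline_set <- function() {
  alleles <- c("VH3-S1*01", "VH3-S1*02", "VH3-S2*01")
  setNames(lapply(alleles, synthetic_germline), alleles)
}
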
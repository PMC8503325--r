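# Minimum nucleotide-substitution distances between codons and residues.
# Somatic hypermutation is dominated by single-nucleotide events, so the
# number of substitutions needed to reach a residue from the germline codon
# partitions a PSSM's cells into mechanistically distinct 1/2/3-nt classes.
# Distances are direct Hamming distances (no pathway through intermediate
# codons is modeled) and stop codons are excluded as targets.

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

codon_hamming <- function(a, b) {
  sum(substring(a, 1:3, 1:3) != substring(b, 1:3, 1:3))
}

#' Minimum nucleotide substitutions from a codon to an amino acid
#'
#' The minimum Hamming distance from `codon` to any sense codon encoding
#' `target_aa`. Zero iff the codon already encodes the target.
#'
#' @param codon A 3-mer from the standard genetic code (A/C/G/T).
#' @param target_aa One of the 20 standard residues (vectorized).
#' @return Integer vector of distances in 0..3.
#' @export
min_nt_from_codon <- function(codon, target_aa) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("invalid codon: ", codon)
  gc <- Biostrings::GENETIC_CODE
  target_aa <- toupper(target_aa)
  if (any(!target_aa %in% AA20))
    stop("invalid target amino acid(s): ",
         paste(setdiff(target_aa, AA20), collapse = ", "))
  vapply(target_aa, function(aa) {
    cands <- names(gc)[gc == aa]
    min(vapply(cands, codon_hamming, 0L, a = codon))
  }, 0L, USE.NAMES = FALSE)
}

#' Amino-acid-level minimum nucleotide distance
#'
#' Minimum of [min_nt_from_codon()] over all codons of the source residue;
#' the appropriate distance when the germline codon is unknown. When the
#' germline nucleotide sequence is available, prefer the codon-level distance
#' (different codons of one residue can need different substitution counts).
#'
#' @param source_aa,target_aa Standard residues (scalars).
#' @return Integer in 0..3.
#' @export
min_nt_aa_level <- function(source_aa, target_aa) {
  source_aa <- toupper(source_aa)
  if (!source_aa %in% AA20) stop("invalid source amino acid: ", source_aa)
  gc <- Biostrings::GENETIC_CODE
  src <- names(gc)[gc == source_aa]
  min(vapply(src, min_nt_from_codon, 0L, target_aa = target_aa))
}

#' Mean PSSM score by minimum-nucleotide class
#'
#' Partitions the unmasked PSSM cells by the minimum number of nucleotide
#' substitutions separating each residue from the germline codon at its
#' position, and summarizes scores per class. Under a single-nucleotide
#' mutation mechanism, 1-nt-accessible substitutions are enriched and score
#' higher than 2- or 3-nt ones; one-tailed Welch t-tests between classes
#' quantify that ordering.
#'
#' @param pssm A `pssm`.
#' @param germline The [germline_reference()] it was built on (nucleotide
#'   sequence required; its translation must match the PSSM wild types).
#' @return List with `summary` (data frame: `class`, `n`, `mean_score`; empty
#'   classes have `n = 0` and `NA` mean) and `tests` (data frame of pairwise
#'   one-tailed Welch p-values, lower class tested as greater).
#' @export
class_score_summary <- function(pssm, germline) {
  stopifnot(inherits(pssm, "pssm"), inherits(germline, "germline_reference"))
  gl_aa <- strsplit(germline$aa_seq, "")[[1]]
  if (!identical(gl_aa[pssm$positions], pssm$wt))
    stop("frame mismatch: translation of the germline nucleotide sequence ",
         "does not reproduce the PSSM wild-type residues")
  codons <- germline_codons(germline)
  cls <- matrix(NA_integer_, nrow = length(pssm$positions), ncol = 20L)
  for (k in seq_along(pssm$positions))
    cls[k, ] <- min_nt_from_codon(codons[pssm$positions[k]], AA20)
  use <- !pssm$masked
  by_class <- lapply(1:3, function(d) pssm$scores[use & cls == d])
  summary <- data.frame(
    class = 1:3,
    n = vapply(by_class, length, 0L),
    mean_score = vapply(by_class, function(x) if (length(x)) mean(x) else NA_real_, 0))
  pairs <- list(c(1, 2), c(2, 3), c(1, 3))
  tests <- do.call(rbind, lapply(pairs, function(p) {
    a <- by_class[[p[1]]]; b <- by_class[[p[2]]]
    pval <- if (length(a) >= 2 && length(b) >= 2)
      t.test(a, b, alternative = "greater")$p.value else NA_real_
    data.frame(comparison = paste0(p[1], "nt_gt_", p[2], "nt"), p = pval)
  }))
  list(summary = summary, tests = tests)
}
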
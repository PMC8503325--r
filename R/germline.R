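#' Construct a germline V-gene reference
#'
#' A germline reference holds the unmutated nucleotide V-segment of a heavy
#' chain variable gene, its translation, and a region annotation assigning
#' every amino-acid position to FR1/CDR1/FR2/CDR2/FR3. Framework positions
#' (FR1-FR3) are the ones scored; CDRs and the J-encoded FR4 are excluded.
#'
#' @param gene_name Gene-level name, e.g. `"VH3-23"`.
#' @param allele_name Allele name, e.g. `"VH3-23*01"`. Defaults to `*01`.
#' @param nt_seq Nucleotide sequence (A/C/G/T), length a multiple of 3,
#'   translating without internal stops.
#' @param regions Data frame with columns `region`, `start`, `end` (1-based,
#'   inclusive, amino-acid coordinates) covering every position exactly once.
#'   Region labels must come from FR1/CDR1/FR2/CDR2/FR3.
#' @return An object of class `germline_reference` with fields `gene_name`,
#'   `allele_name`, `nt_seq`, `aa_seq`, `regions` and `region_of` (a character
#'   vector giving the region label of each amino-acid position).
#' @export
germline_reference <- function(gene_name, allele_name = paste0(gene_name, "*01"),
                               nt_seq, regions) {
  nt_seq <- toupper(nt_seq)
  if (nchar(nt_seq) %% 3L != 0L)
    stop("germline nt_seq length (", nchar(nt_seq), ") is not a multiple of 3")
  if (grepl("[^ACGT]", nt_seq))
    stop("germline nt_seq contains characters outside A/C/G/T")
  aa_seq <- translate_nt(nt_seq)
  if (grepl("\\*", aa_seq))
    stop("germline nt_seq translates with an internal stop codon")
  L <- nchar(aa_seq)
  region_of <- region_vector(regions, L)
  structure(
    list(gene_name = gene_name, allele_name = allele_name,
         nt_seq = nt_seq, aa_seq = aa_seq,
         regions = regions, region_of = region_of),
    class = "germline_reference")
}

VALID_REGIONS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3")
FR_REGIONS <- c("FR1", "FR2", "FR3")

# Expand a regions table into a per-position label vector, checking that the
# windows tile 1..L exactly once.
region_vector <- function(regions, L) {
  stopifnot(is.data.frame(regions), all(c("region", "start", "end") %in% names(regions)))
  bad <- setdiff(regions$region, VALID_REGIONS)
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  out <- rep(NA_character_, L)
  for (k in seq_len(nrow(regions))) {
    idx <- regions$start[k]:regions$end[k]
    idx <- idx[idx >= 1 & idx <= L]
    if (any(!is.na(out[idx])))
      stop("region windows overlap at position(s) ",
           paste(idx[!is.na(out[idx])][1], collapse = ","))
    out[idx] <- regions$region[k]
  }
  if (anyNA(out))
    stop("region windows leave position(s) uncovered: ",
         paste(which(is.na(out))[1], "..."))
  out
}

#' Default IMGT-numbered V-heavy region windows
#'
#' FR1 = 1-26, CDR1 = 27-38, FR2 = 39-55, CDR2 = 56-65, FR3 = 66-104 on the
#' IMGT unique numbering. Use these when input sequences are already
#' IMGT-gapped; ungapped references need their own windows (the FR1 end in
#' particular varies between V-heavy genes).
#'
#' @return Data frame with columns `region`, `start`, `end`.
#' @export
imgt_vh_regions <- function() {
  data.frame(region = VALID_REGIONS,
             start = c(1L, 27L, 39L, 56L, 66L),
             end   = c(26L, 38L, 55L, 65L, 104L))
}

#' @export
print.germline_reference <- function(x, ...) {
  cat("<germline_reference> ", x$allele_name, " (gene ", x$gene_name, ")\n",
      "  ", nchar(x$nt_seq), " nt / ", nchar(x$aa_seq), " aa; FR positions: ",
      sum(x$region_of %in% FR_REGIONS), "\n", sep = "")
  invisible(x)
}

# ---- translation helpers ----------------------------------------------------

# Translate an in-frame nucleotide string with the standard genetic code.
translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt)))
}

# Codon -> amino acid lookup for character work; gap codon "---" maps to "-",
# anything unresolvable (ambiguity, partial gap) maps to "X".
codon_to_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[codons == "---"] <- "-"
  aa[is.na(aa)] <- "X"
  aa
}

# Translate an n x (3L) nucleotide character matrix (germline frame) into an
# n x L amino-acid character matrix. Stops translate to "*".
translate_nt_matrix <- function(nt_mat) {
  L <- ncol(nt_mat) %/% 3L
  n <- nrow(nt_mat)
  out <- matrix(NA_character_, nrow = n, ncol = L)
  for (i in seq_len(L)) {
    cod <- paste0(nt_mat[, 3L * i - 2L], nt_mat[, 3L * i - 1L], nt_mat[, 3L * i])
    out[, i] <- codon_to_aa(cod)
  }
  out
}

# Split equal-length sequences into a character matrix (rows = sequences).
seqs_to_matrix <- function(seqs) {
  n <- length(seqs)
  w <- unique(nchar(seqs))
  stopifnot(length(w) == 1L)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = w, byrow = TRUE)
}

# Germline codons as a character vector (one 3-mer per aa position).
germline_codons <- function(germline) {
  nt <- germline$nt_seq
  L <- nchar(nt) %/% 3L
  substring(nt, 3L * seq_len(L) - 2L, 3L * seq_len(L))
}
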
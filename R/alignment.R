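# Germline assignment, germline-anchored pairwise alignment, and mapping of
# alignment columns to framework positions. A full progressive MSA of the
# repertoire is deliberately avoided: each sequence is aligned to the common
# germline independently (identical column semantics at far lower cost), and
# an externally produced alignment can be supplied as a matrix instead.

nt_submat <- function(match = 1, mismatch = -1) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}

#' Assign a query sequence to its closest germline gene
#'
#' Globally aligns the query against every reference and returns the gene with
#' the highest percent nucleotide identity (matches over alignment columns).
#' Ties are broken lexicographically by gene name and reported via the `tie`
#' field.
#'
#' @param query_nt Nucleotide sequence.
#' @param refs List of [germline_reference()] objects (multiple alleles per
#'   gene allowed; the best allele identity represents its gene).
#' @param min_identity Assignment floor in percent; best identity below it is
#'   an error (default 60).
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @return List with `gene_name`, `percent_identity`, `allele_name`, `tie`.
#' @export
assign_germline <- function(query_nt, refs, min_identity = 60,
                            gap_open = 5, gap_extend = 1) {
  stopifnot(length(refs) >= 1)
  query_nt <- toupper(query_nt)
  genes <- vapply(refs, `[[`, "", "gene_name")
  ids <- vapply(refs, function(r) {
    pa <- Biostrings::pairwiseAlignment(
      query_nt, r$nt_seq, type = "global",
      substitutionMatrix = nt_submat(),
      gapOpening = gap_open, gapExtension = gap_extend)
    Biostrings::pid(pa, type = "PID1")
  }, 0.0)
  best_by_gene <- tapply(ids, genes, max)
  best_by_gene <- best_by_gene[order(names(best_by_gene))]
  top <- max(best_by_gene)
  if (top < min_identity)
    stop("unassigned: best germline identity ", sprintf("%.2f", top),
         "% is below the ", min_identity, "% floor")
  hits <- names(best_by_gene)[best_by_gene == top]
  gene <- hits[1]
  allele_idx <- which(genes == gene)[which.max(ids[genes == gene])]
  list(gene_name = gene, percent_identity = unname(top),
       allele_name = refs[[allele_idx]]$allele_name,
       tie = if (length(hits) > 1) hits else character(0))
}

#' Pairwise global alignment of a query to its germline
#'
#' Needleman-Wunsch with affine gaps (match +1, mismatch -1 by default),
#' anchored on the germline reference. A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param query_nt Query nucleotide sequence.
#' @param ref A [germline_reference()].
#' @inheritParams assign_germline
#' @return List with gapped strings `query` and `germline` (equal length),
#'   `score`, and `insertion_columns` (alignment columns where the germline
#'   row is gapped, i.e. query insertions).
#' @export
align_to_germline <- function(query_nt, ref, gap_open = 5, gap_extend = 1) {
  stopifnot(nzchar(query_nt), inherits(ref, "germline_reference"))
  pa <- Biostrings::pairwiseAlignment(
    toupper(query_nt), ref$nt_seq, type = "global",
    substitutionMatrix = nt_submat(),
    gapOpening = gap_open, gapExtension = gap_extend)
  q <- as.character(Biostrings::alignedPattern(pa))
  g <- as.character(Biostrings::alignedSubject(pa))
  gl_chars <- strsplit(g, "")[[1]]
  list(query = q, germline = g, score = Biostrings::score(pa),
       insertion_columns = which(gl_chars == "-"))
}

#' Align a repertoire onto germline coordinates
#'
#' Produces the germline-frame nucleotide and amino-acid matrices that the
#' counting and scoring steps consume. Sequences the same length as the
#' germline are taken as substitution-only (columns are germline positions
#' directly); others are pairwise-aligned to the germline and their residues
#' read off at germline positions, with deletions as `"-"`. Query insertions
#' are tallied per flanking germline position but not columnized; [
#' build_column_map()] warns if any would survive the occupancy filter.
#'
#' @param x A [repertoire_set()] or character vector of nucleotide sequences.
#' @param germline A [germline_reference()].
#' @inheritParams assign_germline
#' @return Object of class `aligned_repertoire`: `nt` (n x 3L matrix), `aa`
#'   (n x L matrix; untranslatable codons are `"X"`, deletions `"-"`),
#'   `germline`, and `insertion_count` (per germline aa position).
#' @export
align_repertoire <- function(x, germline, gap_open = 5, gap_extend = 1) {
  seqs <- if (inherits(x, "repertoire_set")) x$records$nt_seq else toupper(x)
  Lnt <- nchar(germline$nt_seq)
  L <- Lnt %/% 3L
  ins <- integer(L)
  same <- nchar(seqs) == Lnt
  nt <- matrix("-", nrow = length(seqs), ncol = Lnt)
  if (any(same)) nt[same, ] <- seqs_to_matrix(seqs[same])
  for (i in which(!same)) {
    al <- align_to_germline(seqs[i], germline, gap_open, gap_extend)
    qc <- strsplit(al$query, "")[[1]]
    gc <- strsplit(al$germline, "")[[1]]
    nt[i, ] <- qc[gc != "-"]
    if (length(al$insertion_columns)) {
      gl_pos_before <- cumsum(gc != "-")[al$insertion_columns]
      aa_pos <- pmin(pmax((gl_pos_before + 2L) %/% 3L, 1L), L)
      tab <- table(aa_pos)
      ins[as.integer(names(tab))] <- ins[as.integer(names(tab))] + as.integer(tab)
    }
  }
  structure(list(nt = nt, aa = translate_nt_matrix(nt), germline = germline,
                 insertion_count = ins),
            class = "aligned_repertoire")
}

#' @export
print.aligned_repertoire <- function(x, ...) {
  cat("<aligned_repertoire> ", nrow(x$aa), " sequences x ", ncol(x$aa),
      " germline aa positions (", x$germline$gene_name, ")\n", sep = "")
  invisible(x)
}

#' Map alignment columns to germline framework positions
#'
#' Columns occupied by fewer than `min_occupancy` of the sequences (strictly
#' under: such columns are more than `1 - min_occupancy` gaps, insertions in
#' practice) are dropped; retained columns are numbered against the germline
#' and labeled with their region. A column at exactly the threshold is
#' retained.
#'
#' @param aln An `aligned_repertoire`, or a pre-aligned amino-acid character
#'   matrix (rows = sequences, gaps as `"-"`), in which case `germline_row`
#'   must give the gapped germline amino-acid string on the same columns.
#' @param germline A [germline_reference()] (defaults to the one carried by
#'   `aln`).
#' @param min_occupancy Occupancy threshold, default 0.10.
#' @param germline_row Gapped germline row for the matrix input path.
#' @return Object of class `column_map`: data frame with `column`,
#'   `germline_position`, `occupancy`, `region`; dropped columns (with their
#'   occupancies) in `attr(, "dropped")`.
#' @export
build_column_map <- function(aln, germline = NULL, min_occupancy = 0.10,
                             germline_row = NULL) {
  if (inherits(aln, "aligned_repertoire")) {
    if (is.null(germline)) germline <- aln$germline
    mat <- aln$aa
    gl_pos <- seq_len(ncol(mat))
    ins_frac <- aln$insertion_count / nrow(mat)
    if (any(ins_frac >= min_occupancy))
      warning("insertion(s) near germline position(s) ",
              paste(which(ins_frac >= min_occupancy), collapse = ","),
              " reach ", sprintf("%.0f%%", 100 * max(ins_frac)),
              " of sequences but are not columnized by the pairwise path; ",
              "supply a pre-aligned matrix to retain them")
  } else {
    mat <- aln
    if (is.null(germline_row))
      stop("matrix input requires 'germline_row' (gapped germline amino acids)")
    glc <- if (length(germline_row) == 1L) strsplit(germline_row, "")[[1]] else germline_row
    if (length(glc) != ncol(mat))
      stop("germline row length (", length(glc), ") does not match alignment width (",
           ncol(mat), ")")
    gl_pos <- ifelse(glc != "-", cumsum(glc != "-"), NA_integer_)
  }
  if (is.null(germline)) stop("a germline_reference is required")
  occ <- colMeans(mat != "-")
  keep <- occ >= min_occupancy & !is.na(gl_pos)
  orphan <- occ >= min_occupancy & is.na(gl_pos)
  if (any(orphan))
    warning(sum(orphan), " insertion column(s) pass the occupancy filter but map ",
            "to no germline position; dropped")
  cm <- data.frame(column = which(keep),
                   germline_position = gl_pos[keep],
                   occupancy = occ[keep],
                   region = germline$region_of[gl_pos[keep]])
  attr(cm, "dropped") <- data.frame(column = which(!keep), occupancy = occ[!keep])
  attr(cm, "min_occupancy") <- min_occupancy
  class(cm) <- c("column_map", "data.frame")
  cm
}
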
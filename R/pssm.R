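# Count tables and position-specific scoring matrices. The score of amino
# acid j at framework position i is
#
#     S_ij = log_{1.26}( alpha * N_ij / T_i )
#
# where N_ij is the observation count (pseudocounted to 1 when zero), T_i the
# number of gap-free sequences at the position, and alpha the germline-
# specific centering constant chosen so that the mean score over all unmasked
# framework entries is zero. Because mean S = (log alpha + mean log f) /
# log 1.26 with f_ij = N_ij / T_i, the centering alpha has the closed form
# alpha = exp(-mean(log f)), i.e. the reciprocal of the geometric mean of the
# observed substitution frequencies; no iteration is needed.

#' Tally amino-acid observation counts per framework position
#'
#' Collapses an aligned repertoire into per-position, per-residue counts.
#' Gap characters are excluded from the per-position totals; sequences whose
#' codon at a position cannot be translated (ambiguity) are skipped at that
#' position and tallied in `attr(, "n_untranslatable")`.
#'
#' @param aln An `aligned_repertoire` from [align_repertoire()].
#' @param column_map A [build_column_map()] result.
#' @param region_filter `"FR"` (default) keeps FR1/FR2/FR3 columns only;
#'   `"all"` keeps every mapped column.
#' @return Object of class `count_table`: `counts` (positions x 20 integer
#'   matrix), `totals` (gap-free sequence count per position), `masked`
#'   (logical matrix, all `FALSE` until [mask_wt_and_alleles()]), `wt`,
#'   `positions`, `region`, `germline`, `n_sequences`.
#' @export
tally_counts <- function(aln, column_map, region_filter = c("FR", "all")) {
  region_filter <- match.arg(region_filter)
  stopifnot(inherits(aln, "aligned_repertoire"), inherits(column_map, "column_map"))
  cm <- column_map
  if (region_filter == "FR") cm <- cm[cm$region %in% FR_REGIONS, ]
  P <- nrow(cm)
  counts <- matrix(0L, nrow = P, ncol = 20L, dimnames = list(cm$germline_position, AA20))
  totals <- integer(P)
  n_untr <- 0L
  gl_aa <- strsplit(aln$germline$aa_seq, "")[[1]]
  for (k in seq_len(P)) {
    res <- aln$aa[, cm$germline_position[k]]
    counts[k, ] <- tabulate(factor(res, levels = AA20), nbins = 20L)
    totals[k] <- sum(counts[k, ])
    n_untr <- n_untr + sum(res == "X")
  }
  out <- structure(
    list(germline = aln$germline$gene_name,
         positions = cm$germline_position,
         region = cm$region,
         wt = gl_aa[cm$germline_position],
         counts = counts, totals = totals,
         masked = matrix(FALSE, P, 20L, dimnames = dimnames(counts)),
         pseudocounted = NULL,
         n_sequences = nrow(aln$aa),
         filter = list(region_filter = region_filter,
                       min_occupancy = attr(column_map, "min_occupancy"))),
    class = "count_table")
  attr(out, "n_untranslatable") <- n_untr
  out
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", x$germline, ": ", length(x$positions), " positions, ",
      x$n_sequences, " sequences; ", sum(x$masked), " masked cells\n", sep = "")
  invisible(x)
}

#' Mask wild-type and allelic residues
#'
#' At every position the wild-type residue, and any residue that is wild type
#' in another allele of the same gene, is excluded from scoring (otherwise
#' population-level allelic variation would masquerade as somatic mutation).
#' Totals are unchanged: the per-position frequencies remain true
#' per-sequence frequencies. Idempotent.
#'
#' @param table A [tally_counts()] result.
#' @param germline The gene-level [germline_reference()].
#' @param allele_refs List of additional [germline_reference()] alleles of the
#'   same gene (same amino-acid length after alignment, or an error).
#' @return The `count_table` with an updated `masked` matrix.
#' @export
mask_wt_and_alleles <- function(table, germline, allele_refs = list()) {
  stopifnot(inherits(table, "count_table"))
  refs <- c(list(germline), allele_refs)
  L <- nchar(germline$aa_seq)
  for (r in refs) {
    if (!identical(r$gene_name, germline$gene_name))
      stop("allele ", r$allele_name, " belongs to gene ", r$gene_name,
           ", not ", germline$gene_name)
    if (nchar(r$aa_seq) != L)
      stop("allele ", r$allele_name, " has amino-acid length ", nchar(r$aa_seq),
           " != ", L, " after alignment")
    wt <- strsplit(r$aa_seq, "")[[1]][table$positions]
    idx <- match(wt, AA20)
    table$masked[cbind(seq_along(idx), idx)] <- TRUE
  }
  table
}

#' Replace zero counts with a pseudocount of one
#'
#' Every unmasked zero count becomes 1 so its score is defined; the
#' pseudocount acts as the per-position lower bound on scores. Masked cells
#' stay outside scoring. Apply after the masked set is final.
#'
#' @param table A `count_table` with masking applied.
#' @return The table with pseudocounts applied and a `pseudocounted` logical
#'   matrix recorded.
#' @export
apply_pseudocounts <- function(table) {
  stopifnot(inherits(table, "count_table"))
  ps <- !table$masked & table$counts == 0L
  table$counts[ps] <- 1L
  table$pseudocounted <- ps
  table
}

#' Solve the germline-specific centering constant
#'
#' Returns the alpha that forces the mean score over all unmasked framework
#' entries (pseudocounted ones included) to zero: the reciprocal of the
#' geometric mean of the frequencies f_ij = N_ij / T_i.
#'
#' @param table A `count_table` after [apply_pseudocounts()].
#' @return Positive finite scalar alpha.
#' @export
solve_alpha <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$pseudocounted))
    stop("apply_pseudocounts() before solving alpha")
  use <- !table$masked & table$totals > 0L
  if (!any(use)) stop("no unmasked entries to center on")
  f <- sweep(table$counts, 1L, pmax(table$totals, 1L), "/")
  alpha <- exp(-mean(log(f[use])))
  stopifnot(is.finite(alpha), alpha > 0)
  alpha
}

new_pssm <- function(germline, positions, region, wt, scores, alpha,
                     n_sequences, filter = list(), pseudocounted = NULL) {
  structure(
    list(germline = germline, positions = positions, region = region, wt = wt,
         scores = scores, masked = is.na(scores), alpha = alpha,
         log_base = PSSM_LOG_BASE, n_sequences = n_sequences,
         filter = filter, pseudocounted = pseudocounted),
    class = "pssm")
}

#' Log-transform counts into a position-specific scoring matrix
#'
#' @param table A pseudocounted `count_table`.
#' @param alpha Centering constant, normally from [solve_alpha()].
#' @return Object of class `pssm` with `scores` (positions x 20, `NA` at
#'   masked cells), `alpha`, `log_base` (1.26), `wt`, `region`, `positions`,
#'   `n_sequences`.
#' @export
score_matrix <- function(table, alpha = solve_alpha(table)) {
  stopifnot(inherits(table, "count_table"), alpha > 0)
  if (is.null(table$pseudocounted))
    stop("apply_pseudocounts() before scoring")
  f <- sweep(table$counts, 1L, pmax(table$totals, 1L), "/")
  S <- log(alpha * f) / log(PSSM_LOG_BASE)
  S[table$masked | table$totals == 0L] <- NA_real_
  new_pssm(germline = table$germline, positions = table$positions,
           region = table$region, wt = table$wt, scores = S, alpha = alpha,
           n_sequences = table$n_sequences, filter = table$filter,
           pseudocounted = table$pseudocounted)
}

#' @export
print.pssm <- function(x, ...) {
  cat("<pssm> ", x$germline, ": ", length(x$positions), " FR positions, ",
      "alpha = ", sprintf("%.3g", x$alpha), ", log base ", x$log_base,
      ", n = ", x$n_sequences, " sequences\n", sep = "")
  invisible(x)
}

#' Build a framework PSSM from repertoire sequences
#'
#' Full pipeline: align to the germline, map and filter columns, tally
#' framework counts, mask wild-type/allelic residues, pseudocount, solve the
#' centering constant and score. A repertoire below `min_seqs` sequences
#' warns (matrices from shallow repertoires converge poorly) but still
#' builds.
#'
#' @param x A [repertoire_set()] or an `aligned_repertoire`.
#' @param germline The gene-level [germline_reference()] (optional when `x`
#'   is already aligned).
#' @param allele_refs Additional alleles of the gene, for masking.
#' @param min_occupancy Column occupancy filter, default 0.10.
#' @param min_seqs Depth below which a warning is issued (default 100000).
#' @param column_map Optional precomputed [build_column_map()].
#' @return A `pssm`.
#' @export
build_pssm <- function(x, germline = NULL, allele_refs = list(),
                       min_occupancy = 0.10, min_seqs = 100000,
                       column_map = NULL) {
  aln <- if (inherits(x, "aligned_repertoire")) x else {
    if (is.null(germline)) stop("a germline_reference is required")
    align_repertoire(x, germline)
  }
  if (is.null(germline)) germline <- aln$germline
  if (nrow(aln$aa) < min_seqs)
    warning("repertoire depth ", nrow(aln$aa), " is below the recommended ",
            min_seqs, " sequences; scores may not have converged")
  if (is.null(column_map))
    column_map <- build_column_map(aln, germline, min_occupancy = min_occupancy)
  ct <- tally_counts(aln, column_map, region_filter = "FR")
  ct <- mask_wt_and_alleles(ct, germline, allele_refs)
  ct <- apply_pseudocounts(ct)
  score_matrix(ct, solve_alpha(ct))
}
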
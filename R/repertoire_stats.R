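# Repertoire maturation summaries, PSSM comparison/clustering, and
# subsampling convergence analysis.

#' Per-position mutation frequency
#'
#' Fraction of gap-free, translatable sequences whose residue differs from
#' the germline at each mapped position, plus region-averaged framework and
#' CDR means.
#'
#' @param aln An `aligned_repertoire`.
#' @param column_map A [build_column_map()] result (typically built with all
#'   regions retained).
#' @return List with `per_position` (data frame: `position`, `region`,
#'   `frequency`), `fr_mean`, `cdr_mean`.
#' @export
per_position_frequency <- function(aln, column_map) {
  stopifnot(inherits(aln, "aligned_repertoire"))
  gl_aa <- strsplit(aln$germline$aa_seq, "")[[1]]
  pos <- column_map$germline_position
  freq <- vapply(seq_along(pos), function(k) {
    res <- aln$aa[, pos[k]]
    ok <- res %in% AA20
    if (!any(ok)) return(NA_real_)
    mean(res[ok] != gl_aa[pos[k]])
  }, 0.0)
  df <- data.frame(position = pos, region = column_map$region, frequency = freq)
  list(per_position = df,
       fr_mean = mean(df$frequency[df$region %in% FR_REGIONS], na.rm = TRUE),
       cdr_mean = mean(df$frequency[!df$region %in% FR_REGIONS], na.rm = TRUE))
}

#' Germline-identity summary of a repertoire
#'
#' Percent of sequences with greater than 98 percent nucleotide identity to
#' the germline (strict), and percent fully unmutated. Identity is computed
#' over the aligned germline positions (matches over germline length).
#'
#' @param aln An `aligned_repertoire`.
#' @return List with `pct_over_98_identity` and `pct_unmutated`, both in
#'   0..100; the unmutated bin is a subset of the >98 bin.
#' @export
identity_summary <- function(aln) {
  stopifnot(inherits(aln, "aligned_repertoire"))
  gl <- strsplit(aln$germline$nt_seq, "")[[1]]
  matches <- rowSums(aln$nt == matrix(gl, nrow(aln$nt), length(gl), byrow = TRUE))
  ident <- 100 * matches / length(gl)
  list(pct_over_98_identity = 100 * mean(ident > 98),
       pct_unmutated = 100 * mean(ident == 100))
}

#' Overall dN/dS ratio against the germline
#'
#' Counts one nonsynonymous event per codon whose translation differs from
#' the germline, and one synonymous event per codon identical in translation
#' but different in nucleotides; the ratio pools events over all sequences.
#' Codons containing gaps or ambiguities are skipped. Ratios above one
#' indicate selection at the protein level.
#'
#' @param aln An `aligned_repertoire`.
#' @return List with `dn`, `ds` (event totals) and `ratio` (`NA` with counts
#'   when no synonymous event is observed).
#' @export
dn_ds <- function(aln) {
  stopifnot(inherits(aln, "aligned_repertoire"))
  glc <- germline_codons(aln$germline)
  gl_aa <- strsplit(aln$germline$aa_seq, "")[[1]]
  dn <- 0L; ds <- 0L
  for (i in seq_along(glc)) {
    cod <- paste0(aln$nt[, 3L * i - 2L], aln$nt[, 3L * i - 1L], aln$nt[, 3L * i])
    valid <- !grepl("[^ACGT]", cod)
    changed <- valid & cod != glc[i]
    aa <- aln$aa[, i]
    dn <- dn + sum(changed & aa != gl_aa[i])
    ds <- ds + sum(changed & aa == gl_aa[i])
  }
  list(dn = dn, ds = ds, ratio = if (ds > 0) dn / ds else NA_real_)
}

#' Pearson correlation between two PSSMs
#'
#' Correlates scores over the intersection of unmasked (position, residue)
#' cells. `shared_codon_only` additionally restricts to positions where both
#' germlines carry an identical codon (removing the part of the correlation
#' driven by codon-structure differences); `one_nt_only` restricts to cells
#' one nucleotide away from the germline codon in both (the best-covered
#' cells). Both flags require the germline references.
#'
#' @param p1,p2 `pssm` objects.
#' @param shared_codon_only,one_nt_only Restriction flags (default off).
#' @param germline1,germline2 [germline_reference()]s matching `p1`, `p2`;
#'   needed only when a flag is set.
#' @return Pearson r; the number of cells used is in `attr(, "n")`.
#' @export
pssm_correlation <- function(p1, p2, shared_codon_only = FALSE,
                             one_nt_only = FALSE,
                             germline1 = NULL, germline2 = NULL) {
  stopifnot(inherits(p1, "pssm"), inherits(p2, "pssm"))
  pos <- intersect(p1$positions, p2$positions)
  i1 <- match(pos, p1$positions); i2 <- match(pos, p2$positions)
  keep <- !p1$masked[i1, , drop = FALSE] & !p2$masked[i2, , drop = FALSE]
  if (shared_codon_only || one_nt_only) {
    if (is.null(germline1) || is.null(germline2))
      stop("codon-based restrictions need germline1 and germline2")
    c1 <- germline_codons(germline1)[pos]
    c2 <- germline_codons(germline2)[pos]
    if (shared_codon_only) keep <- keep & (c1 == c2)
    if (one_nt_only) {
      for (k in seq_along(pos)) {
        d1 <- min_nt_from_codon(c1[k], AA20)
        d2 <- min_nt_from_codon(c2[k], AA20)
        keep[k, ] <- keep[k, ] & d1 == 1L & d2 == 1L
      }
    }
  }
  if (sum(keep) < 3)
    stop("fewer than 3 overlapping unmasked cells between the PSSMs")
  r <- cor(p1$scores[i1, , drop = FALSE][keep],
           p2$scores[i2, , drop = FALSE][keep])
  attr(r, "n") <- sum(keep)
  r
}

#' Pairwise PSSM correlation matrix
#'
#' @param pssms Named list of `pssm` objects.
#' @param germlines Optional named list of matching [germline_reference()]s,
#'   required when a restriction flag is set.
#' @inheritParams pssm_correlation
#' @return Object of class `comparison_matrix`: `labels`, symmetric `r` with
#'   unit diagonal, and the flags used.
#' @export
pssm_correlation_matrix <- function(pssms, germlines = NULL,
                                    shared_codon_only = FALSE,
                                    one_nt_only = FALSE) {
  n <- length(pssms)
  stopifnot(n >= 2)
  labels <- names(pssms)
  if (is.null(labels)) labels <- paste0("pssm", seq_len(n))
  r <- diag(1, n)
  dimnames(r) <- list(labels, labels)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r[i, j] <- r[j, i] <- as.numeric(pssm_correlation(
      pssms[[i]], pssms[[j]],
      shared_codon_only = shared_codon_only, one_nt_only = one_nt_only,
      germline1 = if (is.null(germlines)) NULL else germlines[[i]],
      germline2 = if (is.null(germlines)) NULL else germlines[[j]]))
  }
  structure(list(labels = labels, r = r,
                 shared_codon_restricted = shared_codon_only,
                 one_nt_restricted = one_nt_only),
            class = "comparison_matrix")
}

#' UPGMA clustering of PSSMs
#'
#' Average-linkage (UPGMA) hierarchical clustering on the distance `1 - r`
#' between PSSM score vectors, exported as a Newick string with branch
#' lengths. Deterministic given its inputs.
#'
#' @param x A named list of `pssm` objects or a `comparison_matrix`.
#' @param germlines Passed to [pssm_correlation_matrix()] when `x` is a list.
#' @return List with `newick` (string), `tree` (an `ape` phylo), and
#'   `hclust` (the merge heights are `$hclust$height`).
#' @export
cluster_pssms <- function(x, germlines = NULL) {
  if (!inherits(x, "comparison_matrix") && length(x) < 2)
    stop("need at least 2 PSSMs to cluster")
  cm <- if (inherits(x, "comparison_matrix")) x
        else pssm_correlation_matrix(x, germlines = germlines)
  if (length(cm$labels) < 2) stop("need at least 2 PSSMs to cluster")
  d <- as.dist(1 - cm$r)
  hc <- hclust(d, method = "average")
  tree <- ape::as.phylo(hc)
  list(newick = ape::write.tree(tree), tree = tree, hclust = hc)
}

#' Subsampling convergence of PSSM scores
#'
#' For each subsample size and replicate, rebuilds the PSSM on a uniform
#' random subsample (without replacement) and measures the absolute score
#' displacement `|S_sub - S_full|` over unmasked cells; reports the median
#' and the 97.5th percentile (the upper end of a 95 percent band) pooled over
#' replicates. Larger subsamples should displace less.
#'
#' @param aln An `aligned_repertoire` holding the full dataset.
#' @param sizes Integer vector of subsample sizes (each at most the number of
#'   sequences).
#' @param reps Replicates per size (default 3).
#' @param seed RNG seed (default 1).
#' @param allele_refs Alleles for masking, as in [build_pssm()].
#' @param min_occupancy Column filter, as in [build_pssm()].
#' @return Object of class `subsample_report`: data frame with `size`,
#'   `median_abs_ds`, `q975_abs_ds`, `reps`; the seed in `attr(, "seed")`.
#' @export
subsample_convergence <- function(aln, sizes, reps = 3, seed = 1,
                                  allele_refs = list(), min_occupancy = 0.10) {
  stopifnot(inherits(aln, "aligned_repertoire"))
  n <- nrow(aln$aa)
  if (any(sizes > n))
    stop("subsample size(s) ", paste(sizes[sizes > n], collapse = ","),
         " exceed the ", n, " available sequences")
  set.seed(seed)
  cm <- build_column_map(aln, min_occupancy = min_occupancy)
  full <- build_pssm(aln, allele_refs = allele_refs, min_seqs = 0,
                     column_map = cm)
  use <- !full$masked
  rows <- lapply(sizes, function(sz) {
    disp <- unlist(lapply(seq_len(reps), function(rep) {
      idx <- sample.int(n, sz, replace = FALSE)
      sub <- aln_subset(aln, idx)
      p <- build_pssm(sub, allele_refs = allele_refs, min_seqs = 0,
                      column_map = cm)
      abs(p$scores[use] - full$scores[use])
    }))
    data.frame(size = sz, median_abs_ds = median(disp),
               q975_abs_ds = quantile(disp, 0.975, names = FALSE), reps = reps)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("subsample_report", "data.frame")
  out
}

# Row-subset an aligned repertoire (insertion tallies scaled to the subset).
aln_subset <- function(aln, rows) {
  structure(list(nt = aln$nt[rows, , drop = FALSE],
                 aa = aln$aa[rows, , drop = FALSE],
                 germline = aln$germline,
                 insertion_count = as.integer(round(
                   aln$insertion_count * length(rows) / nrow(aln$aa)))),
            class = "aligned_repertoire")
}
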
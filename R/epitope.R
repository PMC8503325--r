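# Peptide:MHC-II affinity fold-change binning. The package never predicts
# binding itself; it consumes KD tables from external class-II predictors
# (see read_kd_table) and implements the downstream procedure: window the
# sequence into 15-mers, pair mutant peptides with their germline
# counterparts, bin by KD fold-change where the germline peptide binds with
# high affinity (KD < 1,000 nM), average PSSM scores per allele and bin, and
# compare bins with Welch t-tests under Benjamini-Hochberg correction.

KD_HIGH_AFFINITY_NM <- 1000

#' All 15-mer windows of a sequence
#'
#' @param aa_seq Amino-acid sequence of length at least 15.
#' @return Data frame with `start` (1-based) and `peptide`; the window
#'   starting at `s` covers sequence positions `s .. s+14`.
#' @export
window_peptides <- function(aa_seq) {
  L <- nchar(aa_seq)
  if (L < 15L) stop("sequence of length ", L, " is shorter than a 15-mer")
  starts <- seq_len(L - 14L)
  data.frame(start = starts, peptide = substring(aa_seq, starts, starts + 14L))
}

#' Bin mutant peptides by KD fold-change from their germline counterparts
#'
#' Each mutant (peptide, allele) measurement is matched to the germline
#' peptide's KD for the same allele. Peptides whose germline partner binds
#' with high affinity (KD < 1,000 nM) fall in one of three fold-change bins
#' (`fold < 0.5`, `0.5 <= fold <= 2`, middle bin closed on both ends,
#' `fold > 2`); every matched peptide is additionally tagged by the
#' high/low-affinity status of its germline partner. Mutant rows without a
#' germline partner for the same allele are excluded and counted in
#' `attr(, "n_unmatched")`.
#'
#' @param mutant,germline KD tables (columns `peptide`, `allele`, `kd_nM`).
#' @param pairing Data frame mapping `mutant_peptide` to `germline_peptide`
#'   (e.g. windows paired by identical start position on the germline).
#' @return Data frame: `peptide`, `allele`, `kd_mut`, `kd_gl`, `fold`,
#'   `gl_class` (`high_affinity_gl`/`low_affinity_gl`), `fold_bin` (`NA`
#'   outside the high-affinity gate).
#' @export
bin_by_fold_change <- function(mutant, germline, pairing) {
  validate_kd_table(mutant); validate_kd_table(germline)
  stopifnot(all(c("mutant_peptide", "germline_peptide") %in% names(pairing)))
  gl_pep <- pairing$germline_peptide[match(mutant$peptide, pairing$mutant_peptide)]
  gi <- match(paste(gl_pep, mutant$allele),
              paste(germline$peptide, germline$allele))
  matched <- !is.na(gi)
  n_unmatched <- sum(!matched)
  out <- data.frame(peptide = mutant$peptide[matched],
                    allele = mutant$allele[matched],
                    kd_mut = mutant$kd_nM[matched],
                    kd_gl = germline$kd_nM[gi[matched]])
  out$fold <- out$kd_mut / out$kd_gl
  out$gl_class <- ifelse(out$kd_gl < KD_HIGH_AFFINITY_NM,
                         "high_affinity_gl", "low_affinity_gl")
  out$fold_bin <- NA_character_
  hi <- out$gl_class == "high_affinity_gl"
  out$fold_bin[hi & out$fold < 0.5] <- "fold<0.5"
  out$fold_bin[hi & out$fold >= 0.5 & out$fold <= 2] <- "0.5<=fold<=2"
  out$fold_bin[hi & out$fold > 2] <- "fold>2"
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Map mutations to the peptides that contain them
#'
#' A window starting at `s` contains a mutation at position `p` iff
#' `s <= p <= s + 14`. Returns one row per (peptide, mutation) pair with the
#' mutation's PSSM score attached.
#'
#' @param windows Data frame from [window_peptides()] (mutant-sequence
#'   windows, positions on the germline-aligned coordinate).
#' @param mutations Data frame with `position` and `score` (e.g. from
#'   [list_fr_mutations()] with a PSSM).
#' @return Data frame `peptide`, `position`, `score`.
#' @export
peptide_mutation_scores <- function(windows, mutations) {
  hits <- lapply(seq_len(nrow(windows)), function(k) {
    inside <- mutations$position >= windows$start[k] &
              mutations$position <= windows$start[k] + 14L
    if (!any(inside)) return(NULL)
    data.frame(peptide = windows$peptide[k],
               position = mutations$position[inside],
               score = mutations$score[inside])
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) out <- data.frame(peptide = character(), position = integer(),
                                      score = numeric())
  out
}

#' Average PSSM scores per allele and KD bin, and test bin differences
#'
#' Peptides contribute their PSSM score (a peptide containing several
#' mutations contributes the mean of their scores by default, or one entry
#' per mutation with `expand = TRUE`). Scores are averaged per (allele, bin)
#' -- the same peptide can sit in different bins for different alleles -- and
#' the five groups (three fold bins plus all high-affinity-germline and all
#' low-affinity-germline peptides) are compared pairwise by Welch two-sample
#' t-tests over allele-level means, with Benjamini-Hochberg adjustment.
#'
#' @param binned Output of [bin_by_fold_change()].
#' @param peptide_scores Data frame with `peptide` and `score`, one or more
#'   rows per peptide (see [peptide_mutation_scores()]).
#' @param expand Keep one entry per mutation instead of averaging within a
#'   peptide (default `FALSE`).
#' @return List with `binned_scores` (data frame `allele`, `group`,
#'   `mean_score`, `n`), `tests` (data frame `group1`, `group2`, `p`,
#'   `p_adj`), and `skipped` (groups with fewer than 2 allele means).
#' @export
average_and_test <- function(binned, peptide_scores, expand = FALSE) {
  stopifnot(all(c("peptide", "score") %in% names(peptide_scores)))
  if (!expand) {
    peptide_scores <- aggregate(score ~ peptide, data = peptide_scores, FUN = mean)
  }
  long <- merge(binned, peptide_scores, by = "peptide")
  groups <- list("fold<0.5" = quote(fold_bin == "fold<0.5"),
                 "0.5<=fold<=2" = quote(fold_bin == "0.5<=fold<=2"),
                 "fold>2" = quote(fold_bin == "fold>2"),
                 "all_high_affinity_gl" = quote(gl_class == "high_affinity_gl"),
                 "all_low_affinity_gl" = quote(gl_class == "low_affinity_gl"))
  per_group <- lapply(names(groups), function(g) {
    sel <- long[eval(groups[[g]], long) & !is.na(eval(groups[[g]], long)), ]
    if (!nrow(sel)) return(NULL)
    agg <- aggregate(score ~ allele, data = sel, FUN = mean)
    cnt <- aggregate(score ~ allele, data = sel, FUN = length)
    data.frame(allele = agg$allele, group = g, mean_score = agg$score,
               n = cnt$score)
  })
  binned_scores <- do.call(rbind, per_group)
  grp_names <- names(groups)
  means_of <- function(g) binned_scores$mean_score[binned_scores$group == g]
  skipped <- grp_names[vapply(grp_names, function(g) length(means_of(g)) < 2, TRUE)]
  testable <- setdiff(grp_names, skipped)
  tests <- NULL
  if (length(testable) >= 2) {
    combs <- utils::combn(testable, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(combs, function(pr) {
      data.frame(group1 = pr[1], group2 = pr[2],
                 p = t.test(means_of(pr[1]), means_of(pr[2]))$p.value)
    }))
  }
  if (length(skipped))
    message("test skipped for group(s) with <2 allele means: ",
            paste(skipped, collapse = ", "))
  if (!is.null(tests)) tests$p_adj <- p.adjust(tests$p, method = "BH")
  list(binned_scores = binned_scores, tests = tests, skipped = skipped)
}
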
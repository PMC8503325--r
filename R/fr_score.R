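# Antibody-level framework scores. Individual framework mutation scores are
# assumed additive and independent (no epistasis); the sum over an antibody's
# m FR mutations is normalized by c0*m + c1*m^2, a least-squares estimate of
# the typical score sum of a repertoire antibody from the same germline with
# the same mutation load. Antibodies with no FR mutations score exactly 1.

#' List framework mutations of a query antibody
#'
#' Aligns a query amino-acid sequence to its germline and records one entry
#' per framework position where the residues differ. CDR differences are
#' excluded, gapped or untranslatable positions skipped. When a `pssm` is
#' supplied, each mutation is annotated with its score and its minimum
#' nucleotide distance from the germline codon; mutations onto a residue the
#' PSSM masks as allelic are treated as allelic variation, not somatic
#' mutation, and dropped (count in `attr(, "n_allelic_excluded")`).
#'
#' @param query_aa Amino-acid sequence of the query V segment.
#' @param germline A [germline_reference()].
#' @param pssm Optional `pssm` built for the same gene.
#' @param column_map Optional [build_column_map()]; restricts positions to its
#'   retained columns.
#' @param min_identity Error floor on percent amino-acid identity (default 60).
#' @return Data frame with columns `position`, `germline_residue`,
#'   `observed_residue`, `region`, plus `score` and `min_nt` when a PSSM is
#'   given.
#' @export
list_fr_mutations <- function(query_aa, germline, pssm = NULL,
                              column_map = NULL, min_identity = 60) {
  query_aa <- toupper(query_aa)
  gl_aa <- strsplit(germline$aa_seq, "")[[1]]
  if (nchar(query_aa) == length(gl_aa)) {
    q <- strsplit(query_aa, "")[[1]]
  } else {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    pa <- Biostrings::pairwiseAlignment(
      query_aa, germline$aa_seq, type = "global",
      substitutionMatrix = get("BLOSUM62", envir = environment()),
      gapOpening = 10, gapExtension = 1)
    qc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    gc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    q <- rep("-", length(gl_aa))
    q[cumsum(gc != "-")[gc != "-"]] <- qc[gc != "-"]
  }
  comparable <- q %in% AA20
  ident <- 100 * sum(q == gl_aa) / length(gl_aa)
  if (ident < min_identity)
    stop("query amino-acid identity ", sprintf("%.1f", ident),
         "% to ", germline$gene_name, " is below the ", min_identity, "% floor")
  pos_ok <- germline$region_of %in% FR_REGIONS
  if (!is.null(column_map))
    pos_ok <- pos_ok & seq_along(gl_aa) %in% column_map$germline_position
  hit <- which(pos_ok & comparable & q != gl_aa)
  out <- data.frame(position = hit,
                    germline_residue = gl_aa[hit],
                    observed_residue = q[hit],
                    region = germline$region_of[hit])
  n_allelic <- 0L
  if (!is.null(pssm)) {
    if (!identical(pssm$germline, germline$gene_name))
      stop("PSSM was built for ", pssm$germline, ", not ", germline$gene_name)
    row <- match(out$position, pssm$positions)
    col <- match(out$observed_residue, AA20)
    out$score <- pssm$scores[cbind(row, col)]
    out$score[is.na(row)] <- NA_real_
    codons <- germline_codons(germline)
    out$min_nt <- vapply(seq_len(nrow(out)), function(k)
      min_nt_from_codon(codons[out$position[k]], out$observed_residue[k]), 0L)
    allelic <- !is.na(row) & is.na(out$score)
    n_allelic <- sum(allelic)
    out <- out[!allelic & !is.na(row), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_allelic_excluded") <- n_allelic
  out
}

#' Per-antibody framework mutation load and score sum
#'
#' Vectorized over an aligned repertoire: for every sequence, the number of
#' scoreable FR mutations `m` and the sum of their PSSM scores. Mutations at
#' masked (wild-type/allelic) cells or unreadable positions contribute to
#' neither.
#'
#' @param aln An `aligned_repertoire`.
#' @param pssm A `pssm` for the same germline.
#' @return Data frame with one row per sequence: `m`, `score_sum`.
#' @export
repertoire_score_sums <- function(aln, pssm) {
  stopifnot(inherits(aln, "aligned_repertoire"), inherits(pssm, "pssm"))
  n <- nrow(aln$aa)
  m <- integer(n)
  ssum <- numeric(n)
  for (k in seq_along(pssm$positions)) {
    res <- aln$aa[, pssm$positions[k]]
    sc <- pssm$scores[k, ][match(res, AA20)]  # NA for WT/allelic/gap/X
    hit <- !is.na(sc)
    m <- m + hit
    ssum[hit] <- ssum[hit] + sc[hit]
  }
  data.frame(m = m, score_sum = ssum)
}

#' Fit the FR-score normalization model
#'
#' Least-squares fit of `score_sum ~ c0*m + c1*m^2` (no intercept) over
#' antibodies with at least one FR mutation. The fitted denominator estimates
#' the typical score sum of a randomly sampled repertoire antibody with the
#' same mutation load.
#'
#' @param sample Data frame with columns `m` and `score_sum` (e.g. from
#'   [repertoire_score_sums()]); rows with `m == 0` are ignored.
#' @param germline Optional germline gene name to stamp on the model.
#' @param per_m_means Fit on per-m mean score sums instead of individual
#'   antibodies (default `FALSE`: raw antibodies).
#' @return Object of class `fr_score_model` with `c0`, `c1`,
#'   `fit_sample_size`, `m_range`.
#' @export
fit_normalization <- function(sample, germline = NA_character_,
                              per_m_means = FALSE) {
  stopifnot(all(c("m", "score_sum") %in% names(sample)))
  s <- sample[sample$m >= 1, , drop = FALSE]
  if (length(unique(s$m)) < 2)
    stop("rank-deficient fit: need at least 2 distinct mutation loads m >= 1; ",
         "provide a larger repertoire sample")
  if (per_m_means) {
    agg <- aggregate(score_sum ~ m, data = s, FUN = mean)
    fit <- lm(score_sum ~ 0 + m + I(m^2), data = agg)
  } else {
    fit <- lm(score_sum ~ 0 + m + I(m^2), data = s)
  }
  cf <- coef(fit)
  model <- structure(
    list(germline = germline, c0 = unname(cf["m"]), c1 = unname(cf["I(m^2)"]),
         fit_sample_size = nrow(s), m_range = range(s$m)),
    class = "fr_score_model")
  mm <- seq(model$m_range[1], model$m_range[2])
  if (any(model$c0 * mm + model$c1 * mm^2 <= 0))
    warning("fitted denominator c0*m + c1*m^2 is non-positive inside the ",
            "fitted mutation-load range; the model is unusable there")
  model
}

#' @export
print.fr_score_model <- function(x, ...) {
  cat("<fr_score_model> ", ifelse(is.na(x$germline), "(unstamped)", x$germline),
      ": c0 = ", sprintf("%.4g", x$c0), ", c1 = ", sprintf("%.4g", x$c1),
      " (fit on ", x$fit_sample_size, " antibodies, m in [",
      x$m_range[1], ", ", x$m_range[2], "])\n", sep = "")
  invisible(x)
}

#' Sample repertoire score sums and fit the normalization in one step
#'
#' Draws a simple random sample (with replacement by default) of sequences
#' from an aligned repertoire, computes their mutation loads and score sums,
#' and fits [fit_normalization()].
#'
#' @inheritParams repertoire_score_sums
#' @param n Sample size (default 1000).
#' @param replace Sample with replacement (default `TRUE`).
#' @param seed Optional RNG seed for reproducibility.
#' @param per_m_means Passed to [fit_normalization()].
#' @return An `fr_score_model`.
#' @export
fit_fr_model <- function(aln, pssm, n = 1000, replace = TRUE, seed = NULL,
                         per_m_means = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  sums <- repertoire_score_sums(aln, pssm)
  idx <- sample.int(nrow(sums), n, replace = replace)
  fit_normalization(sums[idx, ], germline = pssm$germline,
                    per_m_means = per_m_means)
}

#' Compute the antibody-level FR score
#'
#' `FR = 1` exactly for an antibody with no framework mutations; otherwise
#' the sum of its mutation scores divided by `c0*m + c1*m^2`. A score of one
#' means "framework mutations typical of repertoire antibodies with the same
#' mutation count".
#'
#' @param mutations A data frame from [list_fr_mutations()] (with a `score`
#'   column) or a numeric vector of mutation scores.
#' @param model An `fr_score_model` from [fit_normalization()].
#' @return Numeric scalar.
#' @export
fr_score <- function(mutations, model) {
  stopifnot(inherits(model, "fr_score_model"))
  scores <- if (is.data.frame(mutations)) mutations$score else mutations
  if (anyNA(scores)) stop("mutation scores contain NA; was a PSSM supplied?")
  m <- length(scores)
  if (m == 0L) return(1)
  denom <- model$c0 * m + model$c1 * m^2
  if (denom <= 0)
    stop("normalization model for ", model$germline,
         " has non-positive denominator at m = ", m, "; unusable at this load")
  sum(scores) / denom
}

#' Score a batch of query antibodies
#'
#' @param queries Named character vector (or `AAStringSet`) of query
#'   amino-acid V-segment sequences.
#' @param pssm A `pssm`.
#' @param model An `fr_score_model` for the same germline.
#' @param germline The [germline_reference()] the PSSM was built on.
#' @return Data frame, one row per query in input order: `antibody_id`,
#'   `germline`, `m`, `fr_score`, `frac_negative` (fraction of the
#'   antibody's mutation scores below zero), `mutations` and `scores`
#'   (comma-separated).
#' @export
score_report <- function(queries, pssm, model, germline) {
  if (methods::is(queries, "AAStringSet")) {
    nm <- names(queries)
    queries <- setNames(as.character(queries), nm)
  }
  if (is.null(names(queries)))
    names(queries) <- sprintf("query%03d", seq_along(queries))
  if (!identical(pssm$germline, germline$gene_name) ||
      (!is.na(model$germline) && !identical(model$germline, germline$gene_name)))
    stop("germline mismatch between query germline (", germline$gene_name,
         "), PSSM (", pssm$germline, ") and model (", model$germline, ")")
  rows <- lapply(seq_along(queries), function(i) {
    mut <- list_fr_mutations(queries[[i]], germline, pssm = pssm)
    data.frame(
      antibody_id = names(queries)[i],
      germline = germline$gene_name,
      m = nrow(mut),
      fr_score = fr_score(mut, model),
      frac_negative = if (nrow(mut)) mean(mut$score < 0) else 0,
      mutations = paste(sprintf("%s%d%s", mut$germline_residue, mut$position,
                                mut$observed_residue), collapse = ","),
      scores = paste(sprintf("%.2f", mut$score), collapse = ","))
  })
  do.call(rbind, rows)
}
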
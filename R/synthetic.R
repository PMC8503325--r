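# Mechanistic somatic-hypermutation simulator. Sequences descend from a
# germline by independent single-nucleotide substitutions: a Poisson number
# of events per sequence, event positions drawn by per-position weights, and
# replacement bases drawn from a substitution-bias matrix (transitions
# favored 2:1 by default). This reproduces the core structure of SHM -- a
# point-mutation process at roughly uniform low per-base rate with a
# transition bias -- and therefore the enrichment of 1-nt-accessible amino
# acid substitutions; it deliberately models no selection, no clonal
# structure and no AID hotspot motifs, so absolute score magnitudes of real
# repertoires are not matched, only their mechanistic structure.

#' Default single-nucleotide substitution bias
#'
#' Transition:transversion ratio `ti_tv` (default 2), zero diagonal, rows
#' normalized to one. Rows/columns ordered A, C, G, T.
#'
#' @param ti_tv Transition weight relative to each transversion.
#' @return 4x4 row-stochastic matrix with zero diagonal.
#' @export
default_substitution_bias <- function(ti_tv = 2) {
  b <- matrix(1, 4, 4, dimnames = list(NT4, NT4))
  diag(b) <- 0
  b["A", "G"] <- b["G", "A"] <- b["C", "T"] <- b["T", "C"] <- ti_tv
  sweep(b, 1, rowSums(b), "/")
}

#' Simulation parameters for a synthetic repertoire
#'
#' @param germline A [germline_reference()].
#' @param n_sequences Number of sequences to generate.
#' @param lambda Mean of the Poisson number of nucleotide substitution events
#'   per sequence (default 12 over the 294-nt bundled germlines, i.e. about
#'   4 percent per base, giving per-amino-acid mutation frequencies around
#'   10 percent as seen in baseline IgG repertoires).
#' @param position_weights Relative event rate per nucleotide position
#'   (non-negative, not all zero; default uniform). Hotspots are emulated by
#'   raising individual weights.
#' @param substitution_bias 4x4 replacement matrix, rows A/C/G/T summing to
#'   one with zero diagonal (default [default_substitution_bias()]).
#' @param seed RNG seed; the same parameters always regenerate the identical
#'   repertoire.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(germline, n_sequences, lambda = 12,
                       position_weights = NULL,
                       substitution_bias = default_substitution_bias(),
                       seed = 1) {
  stopifnot(inherits(germline, "germline_reference"), n_sequences >= 1,
            lambda >= 0)
  L <- nchar(germline$nt_seq)
  if (is.null(position_weights)) position_weights <- rep(1, L)
  if (length(position_weights) != L || any(position_weights < 0) ||
      all(position_weights == 0))
    stop("position_weights must be ", L, " non-negative values, not all zero")
  b <- substitution_bias
  if (!all(dim(b) == c(4, 4)) || any(diag(b) != 0) ||
      any(abs(rowSums(b) - 1) > 1e-8))
    stop("substitution_bias must be 4x4 with zero diagonal and unit row sums")
  dimnames(b) <- list(NT4, NT4)
  structure(list(germline = germline, n_sequences = as.integer(n_sequences),
                 lambda = lambda, position_weights = position_weights,
                 substitution_bias = b, seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a germline-anchored repertoire
#'
#' Each sequence receives `k ~ Poisson(lambda)` substitution events; event
#' positions are drawn by weight (with replacement -- a position hit twice is
#' mutated sequentially from its current base) and replacement bases from
#' the bias matrix. Deterministic under the seed in `params`.
#'
#' @param params A [sim_params()].
#' @return A [repertoire_set()] of IgG records tagged with the germline gene.
#' @export
simulate_repertoire <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  gl <- strsplit(params$germline$nt_seq, "")[[1]]
  L <- length(gl)
  n <- params$n_sequences
  nt <- matrix(gl, nrow = n, ncol = L, byrow = TRUE)
  k <- rpois(n, params$lambda)
  total <- sum(k)
  if (total > 0) {
    ev_seq <- rep.int(seq_len(n), k)
    ev_pos <- sample.int(L, total, replace = TRUE, prob = params$position_weights)
    remaining <- seq_len(total)
    while (length(remaining)) {
      key <- ev_seq[remaining] + (ev_pos[remaining] - 1) * n
      first <- !duplicated(key)
      idx <- remaining[first]
      cells <- cbind(ev_seq[idx], ev_pos[idx])
      cur <- nt[cells]
      new <- cur
      for (b in NT4) {
        at <- which(cur == b)
        if (length(at))
          new[at] <- sample(NT4, length(at), replace = TRUE,
                            prob = params$substitution_bias[b, ])
      }
      nt[cells] <- new
      remaining <- remaining[!first]
    }
  }
  seqs <- do.call(paste0, lapply(seq_len(L), function(j) nt[, j]))
  rec <- data.frame(sequence_id = sprintf("sim%07d", seq_len(n)),
                    subject_id = "sim",
                    isotype = "IgG",
                    nt_seq = seqs,
                    germline_gene = params$germline$gene_name)
  repertoire_set(rec, germline = params$germline$gene_name)
}

#' Expected amino-acid substitution frequencies under the simulator
#'
#' Ground-truth oracle for validating score recovery. In the single-hit
#' regime the expectation is closed-form: the chance that a sequence carries
#' amino acid `j` at codon position `i` is the summed rate of the single-
#' nucleotide events turning the germline codon into a codon of `j`
#' (per-position event rate `lambda * w_p / sum(w)` times the bias of the
#' replacement base). `method = "mc"` instead estimates frequencies from an
#' independent Monte-Carlo run at `mc_factor` times the parameterized size,
#' capturing multi-hit effects.
#'
#' @param params A [sim_params()].
#' @param method `"closed_form"` (default) or `"mc"`.
#' @param mc_factor Monte-Carlo oversampling factor (default 10).
#' @return Positions x 20 matrix of expected per-sequence substitution
#'   frequencies; the wild-type cell of each row is `NA`.
#' @export
true_aa_profile <- function(params, method = c("closed_form", "mc"),
                            mc_factor = 10) {
  method <- match.arg(method)
  gl <- params$germline
  L <- nchar(gl$aa_seq)
  if (method == "mc") {
    mc_params <- sim_params(gl, n_sequences = params$n_sequences * mc_factor,
                            lambda = params$lambda,
                            position_weights = params$position_weights,
                            substitution_bias = params$substitution_bias,
                            seed = (params$seed + 104729L) %% .Machine$integer.max)
    aln <- align_repertoire(simulate_repertoire(mc_params), gl)
    prof <- matrix(NA_real_, L, 20L, dimnames = list(seq_len(L), AA20))
    for (i in seq_len(L)) {
      res <- aln$aa[, i]
      ok <- res %in% AA20
      prof[i, ] <- tabulate(factor(res[ok], levels = AA20), 20L) / sum(ok)
    }
  } else {
    w <- params$position_weights / sum(params$position_weights)
    rate <- params$lambda * w
    codons <- germline_codons(gl)
    prof <- matrix(0, L, 20L, dimnames = list(seq_len(L), AA20))
    for (i in seq_len(L)) {
      cod <- strsplit(codons[i], "")[[1]]
      for (p in 1:3) {
        ntp <- 3L * (i - 1L) + p
        for (b in setdiff(NT4, cod[p])) {
          mut <- cod; mut[p] <- b
          aa <- codon_to_aa(paste(mut, collapse = ""))
          if (aa %in% AA20)
            prof[i, aa] <- prof[i, aa] +
              rate[ntp] * params$substitution_bias[cod[p], b]
        }
      }
    }
  }
  wt <- strsplit(gl$aa_seq, "")[[1]]
  prof[cbind(seq_len(L), match(wt, AA20))] <- NA_real_
  prof
}

#' Simulate paired germline/mutant peptide:MHC-II KD tables
#'
#' Fixture generator for the fold-change binning procedure. Framework
#' mutations are drawn from the PSSM's unmasked cells; each lives on one
#' 15-mer window of the germline. Germline KDs are log-normal per (peptide,
#' allele); mutant KDs plant a score-to-fold coupling,
#' `log2(fold) = slope * score + noise`, so that with positive slope the
#' high-scoring mutations concentrate in the `fold > 2` bin. With zero slope
#' and noise every fold is exactly 1.
#'
#' @param pssm A `pssm`.
#' @param germline Its [germline_reference()].
#' @param effect_model List with `slope` (log2-fold per score unit, default
#'   0.15), `noise_sd` (log2-fold noise, default 0.2), `kd_meanlog`,
#'   `kd_sdlog` (germline KD log-normal parameters, defaults log(800), 1).
#' @param alleles Allele names (default 38 synthetic DRB1-style labels).
#' @param n_mutations Number of distinct planted mutations (default 40).
#' @param seed RNG seed.
#' @return List with `germline` and `mutant` KD tables, the `pairing` map,
#'   and `mutation_scores` (`peptide`, `position`, `score`) for the planted
#'   mutations.
#' @export
simulate_kd_tables <- function(pssm, germline,
                               effect_model = list(slope = 0.15, noise_sd = 0.2,
                                                   kd_meanlog = log(800),
                                                   kd_sdlog = 1),
                               alleles = sprintf("DRB1*S%02d:01", 1:38),
                               n_mutations = 40, seed = 1) {
  stopifnot(inherits(pssm, "pssm"))
  set.seed(seed)
  em <- effect_model
  for (nm in c("slope", "noise_sd")) if (is.null(em[[nm]])) em[[nm]] <- 0
  if (is.null(em$kd_meanlog)) em$kd_meanlog <- log(800)
  if (is.null(em$kd_sdlog)) em$kd_sdlog <- 1
  L <- nchar(germline$aa_seq)
  cells <- which(!pssm$masked, arr.ind = TRUE)
  pick <- cells[sample.int(nrow(cells), min(n_mutations, nrow(cells))), ,
                drop = FALSE]
  pos <- pssm$positions[pick[, 1]]
  res <- AA20[pick[, 2]]
  score <- pssm$scores[pick]
  start <- pmin(pmax(pos - 7L, 1L), L - 14L)
  gl_pep <- substring(germline$aa_seq, start, start + 14L)
  mut_pep <- vapply(seq_along(pos), function(k) {
    p <- gl_pep[k]
    substr(p, pos[k] - start[k] + 1L, pos[k] - start[k] + 1L) <- res[k]
    p
  }, "")
  dup <- duplicated(mut_pep)
  pos <- pos[!dup]; res <- res[!dup]; score <- score[!dup]
  gl_pep <- gl_pep[!dup]; mut_pep <- mut_pep[!dup]
  nm <- length(mut_pep); na <- length(alleles)
  u_gl <- unique(gl_pep)
  gl_tab <- data.frame(peptide = rep(u_gl, each = na),
                       allele = rep(alleles, length(u_gl)),
                       kd_nM = exp(rnorm(length(u_gl) * na,
                                         em$kd_meanlog, em$kd_sdlog)))
  base_kd <- gl_tab$kd_nM[match(paste(rep(gl_pep, each = na), rep(alleles, nm)),
                                paste(gl_tab$peptide, gl_tab$allele))]
  log2fold <- em$slope * rep(score, each = na) +
    if (em$noise_sd > 0) rnorm(nm * na, 0, em$noise_sd) else 0
  mut_tab <- data.frame(peptide = rep(mut_pep, each = na),
                        allele = rep(alleles, nm),
                        kd_nM = base_kd * 2^log2fold)
  list(germline = gl_tab, mutant = mut_tab,
       pairing = data.frame(mutant_peptide = mut_pep, germline_peptide = gl_pep),
       mutation_scores = data.frame(peptide = mut_pep, position = pos,
                                    score = score))
}
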
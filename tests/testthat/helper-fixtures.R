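# Shared fixtures (memoized so expensive simulations run once per suite) and
# independent oracles used across the tests.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

demo_gl <- function() synthetic_germline("VH3-S1*01")
demo_gl_allele2 <- function() synthetic_germline("VH3-S1*02")
demo_gl_b <- function() synthetic_germline("VH3-S2*01")

# One moderate repertoire shared by most statistical tests.
shared_aln <- function() memo("shared_aln", {
  p <- sim_params(demo_gl(), n_sequences = 10000, lambda = 12, seed = 101)
  align_repertoire(simulate_repertoire(p), demo_gl())
})

shared_pssm <- function() memo("shared_pssm", {
  suppressWarnings(build_pssm(shared_aln()))
})

shared_sums <- function() memo("shared_sums", {
  repertoire_score_sums(shared_aln(), shared_pssm())
})

# Minimal hand-built count table for closed-form alpha/score checks.
make_count_table <- function(counts, totals, masked = NULL) {
  counts <- matrix(as.integer(counts), nrow = length(totals), ncol = 20,
                   dimnames = list(seq_along(totals), aa_alphabet()))
  if (is.null(masked)) masked <- matrix(FALSE, nrow(counts), 20)
  dimnames(masked) <- dimnames(counts)
  structure(list(germline = "TOY", positions = seq_along(totals),
                 region = rep("FR1", length(totals)),
                 wt = rep("A", length(totals)),
                 counts = counts, totals = as.integer(totals), masked = masked,
                 pseudocounted = matrix(FALSE, nrow(counts), 20),
                 n_sequences = max(totals), filter = list()),
            class = "count_table")
}

# ---- independent oracles ----------------------------------------------------

# Numeric root-finder for the centering constant: solves mean S(alpha) = 0
# over the unmasked frequencies, independently of the closed form.
alpha_root_oracle <- function(f) {
  mean_s <- function(log_alpha) mean(log(exp(log_alpha) * f) / log(1.26))
  exp(uniroot(mean_s, c(-50, 50), tol = 1e-12)$root)
}

# Brute-force global-alignment oracle: enumerate every alignment of a and b
# and score it (match +1, mismatch -1, a gap of length L costs
# gap_open + L * gap_extend). Exponential; only for very short sequences.
brute_force_align_score <- function(a, b, gap_open = 5, gap_extend = 1) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  score_cols <- function(ca, cb) {
    s <- 0
    for (k in seq_along(ca)) {
      if (ca[k] != "-" && cb[k] != "-") s <- s + if (ca[k] == cb[k]) 1 else -1
    }
    for (row in list(ca, cb)) {
      r <- rle(row == "-")
      gaps <- r$lengths[r$values]
      if (length(gaps)) s <- s - sum(gap_open + gap_extend * gaps)
    }
    s
  }
  best <- -Inf
  rec <- function(i, j, ca, cb) {
    if (i > length(ac) && j > length(bc)) {
      best <<- max(best, score_cols(ca, cb))
      return(invisible(NULL))
    }
    if (i <= length(ac) && j <= length(bc))
      rec(i + 1, j + 1, c(ca, ac[i]), c(cb, bc[j]))
    if (i <= length(ac)) rec(i + 1, j, c(ca, ac[i]), c(cb, "-"))
    if (j <= length(bc)) rec(i, j + 1, c(ca, "-"), c(cb, bc[j]))
  }
  rec(1, 1, character(), character())
  best
}

# Exhaustive codon-table oracle for minimum nucleotide distances: plain loops
# over every codon of the target residue, comparing position by position.
brute_force_min_nt <- function(codon, target_aa) {
  gc <- Biostrings::GENETIC_CODE
  best <- 3L
  for (cand in names(gc)) {
    if (gc[[cand]] != target_aa) next
    d <- 0L
    for (p in 1:3) if (substr(codon, p, p) != substr(cand, p, p)) d <- d + 1L
    best <- min(best, d)
  }
  best
}
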
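test_that("per-position mutation frequencies count substitutions only", {
  gl <- demo_gl()
  aln0 <- align_repertoire(rep(gl$nt_seq, 10), gl)
  cm <- build_column_map(aln0)
  f0 <- per_position_frequency(aln0, cm)
  expect_true(all(f0$per_position$frequency == 0))

  # 3 of 10 sequences mutated at amino-acid position 5 -> 0.30 there
  v5a <- gl$nt_seq; substr(v5a, 14, 14) <- "C"
  aln <- align_repertoire(c(rep(v5a, 3), rep(gl$nt_seq, 7)), gl)
  f <- per_position_frequency(aln, build_column_map(aln))
  expect_equal(f$per_position$frequency[f$per_position$position == 5], 0.3)
  expect_equal(sum(f$per_position$frequency > 0), 1)
})

test_that("simulated repertoires reproduce the generator's mutation profile", {
  p <- sim_params(demo_gl(), 10000, lambda = 12, seed = 101)
  aln <- shared_aln()
  f <- per_position_frequency(aln, build_column_map(aln))
  prof <- true_aa_profile(p)
  expected <- rowSums(prof, na.rm = TRUE)[f$per_position$position]
  sigma <- sqrt(expected * (1 - expected) / nrow(aln$aa))
  # per-position recovery within generous binomial bounds (plus a small
  # allowance for multi-hit effects the closed form ignores)
  expect_true(all(abs(f$per_position$frequency - expected) < 5 * sigma + 0.005))
  expect_lt(abs(mean(f$per_position$frequency) - mean(expected)), 0.005)
})

test_that("identity summary bins strictly above 98 percent", {
  gl <- demo_gl()
  five <- gl$nt_seq
  for (i in c(3, 30, 60, 90, 120))
    substr(five, i, i) <- if (substr(five, i, i) == "A") "C" else "A"
  six <- five
  substr(six, 150, 150) <- if (substr(six, 150, 150) == "A") "C" else "A"
  stopifnot(sum(strsplit(five, "")[[1]] != strsplit(gl$nt_seq, "")[[1]]) == 5,
            sum(strsplit(six, "")[[1]] != strsplit(gl$nt_seq, "")[[1]]) == 6)
  aln <- align_repertoire(c(gl$nt_seq, five, six), gl)
  ids <- identity_summary(aln)
  # 289/294 = 98.30% is inside the bin; 288/294 = 97.96% is not
  expect_equal(ids$pct_over_98_identity, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(ids$pct_unmutated, 100 * 1 / 3, tolerance = 1e-9)
  expect_lte(ids$pct_unmutated, ids$pct_over_98_identity)
})

test_that("dN/dS counts per-codon events against the germline", {
  gl <- demo_gl()
  codons <- repframe:::germline_codons(gl)
  # codon 2 is GTC (V): GTA is synonymous, GAC (D) nonsynonymous
  stopifnot(codons[2] == "GTC")
  syn <- gl$nt_seq; substr(syn, 6, 6) <- "A"
  nonsyn <- gl$nt_seq; substr(nonsyn, 5, 5) <- "A"
  expect_equal(dn_ds(align_repertoire(c(syn, syn), gl))$ratio, 0)
  both <- align_repertoire(c(rep(syn, 10), rep(nonsyn, 10)), gl)
  expect_equal(dn_ds(both), list(dn = 10L, ds = 10L, ratio = 1))
  # record order does not matter
  shuffled <- align_repertoire(c(rep(c(nonsyn, syn), 10)), gl)
  expect_equal(dn_ds(shuffled)$ratio, 1)
  # no synonymous events -> NA with counts preserved
  res <- dn_ds(align_repertoire(c(nonsyn, nonsyn), gl))
  expect_true(is.na(res$ratio))
  expect_equal(res$dn, 2L)
})

test_that("neutral simulation matches the codon-structure expectation", {
  gl <- demo_gl()
  p <- sim_params(gl, 20000, lambda = 2, seed = 202,
                  substitution_bias = default_substitution_bias(ti_tv = 1))
  aln <- align_repertoire(simulate_repertoire(p), gl)
  obs <- dn_ds(aln)$ratio
  # enumeration oracle: all single-nt changes of the germline, uniform bias
  glc <- strsplit(gl$nt_seq, "")[[1]]
  n_events <- 0L; s_events <- 0L
  for (i in seq_along(glc)) {
    cod_i <- (i + 2) %/% 3
    cod <- repframe:::germline_codons(gl)[cod_i]
    for (b in setdiff(c("A", "C", "G", "T"), glc[i])) {
      mut <- cod
      substr(mut, ((i - 1) %% 3) + 1, ((i - 1) %% 3) + 1) <- b
      if (Biostrings::GENETIC_CODE[[mut]] == Biostrings::GENETIC_CODE[[cod]])
        s_events <- s_events + 1L
      else n_events <- n_events + 1L
    }
  }
  expect_lt(abs(obs - n_events / s_events) / (n_events / s_events), 0.1)
})

test_that("PSSM correlations behave at the identity and sign extremes", {
  p <- shared_pssm()
  expect_equal(as.numeric(pssm_correlation(p, p)), 1)
  neg <- p
  neg$scores <- -p$scores
  expect_equal(as.numeric(pssm_correlation(p, neg)), -1)
})

test_that("independent halves of one repertoire give near-identical PSSMs", {
  aln <- shared_aln()
  half1 <- repframe:::aln_subset(aln, 1:5000)
  half2 <- repframe:::aln_subset(aln, 5001:10000)
  p1 <- build_pssm(half1, min_seqs = 0)
  p2 <- build_pssm(half2, min_seqs = 0)
  r <- as.numeric(pssm_correlation(p1, p2))
  expect_gt(r, 0.9)
  # the shared-codon and 1-nt restrictions still correlate strongly
  # restricted to 1-nt cells the pseudocount floor no longer contributes,
  # so the bar is a little lower at this depth
  r1 <- as.numeric(pssm_correlation(p1, p2, one_nt_only = TRUE,
                                    germline1 = demo_gl(), germline2 = demo_gl()))
  expect_gt(r1, 0.8)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  aln <- shared_aln()
  thirds <- lapply(list(1:3000, 3001:6000, 6001:9000),
                   function(ix) build_pssm(repframe:::aln_subset(aln, ix),
                                           min_seqs = 0))
  names(thirds) <- c("a", "b", "c")
  cmat <- pssm_correlation_matrix(thirds)
  expect_equal(diag(cmat$r), c(a = 1, b = 1, c = 1))
  expect_equal(cmat$r, t(cmat$r))
  expect_true(all(cmat$r >= -1 & cmat$r <= 1))
})

test_that("UPGMA clustering matches a hand-computed average-linkage oracle", {
  # toy distances d(AB) = 0.2, d(AC) = 0.6, d(BC) = 0.8:
  # A,B merge at 0.2; C joins at mean(0.6, 0.8) = 0.7
  r <- matrix(c(1, 0.8, 0.4,
                0.8, 1, 0.2,
                0.4, 0.2, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cm <- structure(list(labels = c("A", "B", "C"), r = r,
                       shared_codon_restricted = FALSE),
                  class = "comparison_matrix")
  cl <- cluster_pssms(cm)
  expect_equal(cl$hclust$height, c(0.2, 0.7), tolerance = 1e-12)
  tree <- ape::read.tree(text = cl$newick)
  expect_setequal(tree$tip.label, c("A", "B", "C"))

  # two identical PSSMs merge first, at height zero
  p <- shared_pssm()
  neg <- p; neg$scores <- -p$scores
  cl2 <- cluster_pssms(list(x = p, y = p, z = neg))
  expect_equal(min(cl2$hclust$height), 0)
  first <- cl2$hclust$merge[1, ]
  expect_setequal(cl2$hclust$labels[-first], c("x", "y"))

  expect_error(cluster_pssms(list(p)), "at least 2")
})

test_that("replicate PSSMs cluster by germline of origin", {
  mk <- function(gl, seed) {
    p <- sim_params(gl, 3000, lambda = 12, seed = seed)
    build_pssm(align_repertoire(simulate_repertoire(p), gl), min_seqs = 0)
  }
  pssms <- list(g1_r1 = mk(demo_gl(), 11), g1_r2 = mk(demo_gl(), 12),
                g2_r1 = mk(demo_gl_b(), 13), g2_r2 = mk(demo_gl_b(), 14))
  cl <- cluster_pssms(pssms)
  coph <- ape::cophenetic.phylo(cl$tree)
  expect_lt(coph["g1_r1", "g1_r2"], coph["g1_r1", "g2_r1"])
  expect_lt(coph["g2_r1", "g2_r2"], coph["g2_r1", "g1_r1"])
})

test_that("subsampling displacement shrinks with depth and is reproducible", {
  aln <- shared_aln()
  rep1 <- subsample_convergence(aln, sizes = c(500, 5000), reps = 2, seed = 7)
  expect_true(all(rep1$median_abs_ds >= 0))
  expect_gte(rep1$median_abs_ds[rep1$size == 500],
             rep1$median_abs_ds[rep1$size == 5000])
  expect_gte(rep1$q975_abs_ds[rep1$size == 500],
             rep1$q975_abs_ds[rep1$size == 5000])

  # the full set displaces nothing
  full <- subsample_convergence(aln, sizes = nrow(aln$aa), reps = 1, seed = 7)
  expect_equal(full$median_abs_ds, 0)
  expect_equal(full$q975_abs_ds, 0)

  rep2 <- subsample_convergence(aln, sizes = c(500, 5000), reps = 2, seed = 7)
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))
  expect_error(subsample_convergence(aln, sizes = 1e6, reps = 1), "exceed")
})
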
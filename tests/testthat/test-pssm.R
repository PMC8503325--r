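test_that("counts tally observations with gap-aware totals", {
  gl <- demo_gl()
  seqs <- rep(gl$nt_seq, 10)
  # 3 sequences carry V5A (codon 5 GTA -> GCA)
  v5a <- gl$nt_seq
  substr(v5a, 14, 14) <- "C"
  seqs[1:3] <- v5a
  aln <- align_repertoire(seqs, gl)
  cm <- build_column_map(aln)
  ct <- tally_counts(aln, cm)

  i5 <- match(5, ct$positions)
  expect_equal(ct$counts[i5, "A"], 3)
  expect_equal(ct$counts[i5, "V"], 7)
  expect_equal(ct$totals[i5], 10)
  expect_equal(sum(ct$counts[i5, ]), ct$totals[i5])

  # all-germline copies: counts concentrated on WT, totals = n everywhere
  aln0 <- align_repertoire(rep(gl$nt_seq, 10), gl)
  ct0 <- tally_counts(aln0, build_column_map(aln0))
  expect_true(all(ct0$counts[cbind(seq_along(ct0$wt), match(ct0$wt, aa_alphabet()))] == 10))
  expect_true(all(ct0$totals == 10))

  # one sequence gapped at position 7 (codon deleted): total drops to 9
  del7 <- paste0(substr(gl$nt_seq, 1, 18), substr(gl$nt_seq, 22, 294))
  alng <- align_repertoire(c(rep(gl$nt_seq, 9), del7), gl)
  ctg <- tally_counts(alng, build_column_map(alng))
  expect_equal(ctg$totals[match(7, ctg$positions)], 9)
  expect_equal(ctg$totals[match(8, ctg$positions)], 10)
})

test_that("wild-type and allelic residues are masked, idempotently", {
  gl <- demo_gl()
  aln <- align_repertoire(rep(gl$nt_seq, 5), gl)
  ct <- tally_counts(aln, build_column_map(aln))

  # single allele: exactly the WT residue masked at each position
  m1 <- mask_wt_and_alleles(ct, gl)
  expect_true(all(rowSums(m1$masked) == 1))
  expect_true(all(m1$masked[cbind(seq_along(m1$wt), match(m1$wt, aa_alphabet()))]))

  # allele *02 differs by D75M: both D and M masked at position 75
  m2 <- mask_wt_and_alleles(ct, gl, list(demo_gl_allele2()))
  i75 <- match(75, m2$positions)
  expect_true(m2$masked[i75, "D"] && m2$masked[i75, "M"])
  expect_equal(sum(m2$masked[i75, ]), 2)
  expect_identical(mask_wt_and_alleles(m2, gl, list(demo_gl_allele2())), m2)

  # totals are untouched by masking
  expect_identical(m2$totals, ct$totals)

  # an allele of a different length is rejected
  short <- demo_gl_allele2()
  short$aa_seq <- substr(short$aa_seq, 1, 97)
  expect_error(mask_wt_and_alleles(ct, gl, list(short)), "length")
})

test_that("pseudocounting raises unmasked zeros to one and nothing else", {
  ct <- make_count_table(counts = 0, totals = c(10, 10))
  ct$counts[1, "C"] <- 5
  ct$masked[1, "A"] <- TRUE
  ps <- apply_pseudocounts(ct)
  expect_equal(ps$counts[1, "C"], 5)          # real counts unchanged
  expect_equal(ps$counts[1, "D"], 1)          # unmasked zero -> 1
  expect_equal(ps$counts[1, "A"], 0)          # masked zero stays outside
  expect_true(ps$pseudocounted[1, "D"])
  expect_false(ps$pseudocounted[1, "C"])
})

test_that("alpha has the closed form of an inverse geometric mean", {
  # uniform frequencies f = 0.05 -> alpha = 20, every score 0
  ct <- make_count_table(counts = 5, totals = rep(100, 2))
  ct <- apply_pseudocounts(ct)
  expect_equal(solve_alpha(ct), 20, tolerance = 1e-12)
  p <- score_matrix(ct)
  expect_true(all(abs(p$scores[!p$masked]) < 1e-9))

  # two entries f = 0.1 and 0.001 -> geometric mean 0.01, alpha = 100
  ct2 <- make_count_table(counts = 0, totals = c(1000, 1000),
                          masked = matrix(TRUE, 2, 20))
  ct2$masked[1, "A"] <- FALSE; ct2$masked[2, "A"] <- FALSE
  ct2$counts[1, "A"] <- 100; ct2$counts[2, "A"] <- 1
  ct2 <- apply_pseudocounts(ct2)
  expect_equal(solve_alpha(ct2), 100, tolerance = 1e-9)
  expect_equal(solve_alpha(ct2), alpha_root_oracle(c(0.1, 0.001)),
               tolerance = 1e-6)

  # f = 0.1 and 0.01 -> alpha ~ 31.62, scores ~ +/- 4.98
  ct3 <- ct2
  ct3$counts[2, "A"] <- 10
  expect_equal(solve_alpha(ct3), sqrt(1000), tolerance = 1e-9)
  expect_equal(solve_alpha(ct3), alpha_root_oracle(c(0.1, 0.01)),
               tolerance = 1e-6)
  p3 <- score_matrix(ct3)
  expect_equal(sort(p3$scores[!p3$masked]), c(-4.9815, 4.9815), tolerance = 1e-3)

  ct_empty <- make_count_table(counts = 1, totals = 10,
                               masked = matrix(TRUE, 1, 20))
  ct_empty$pseudocounted <- matrix(FALSE, 1, 20)
  expect_error(solve_alpha(ct_empty), "no unmasked")
})

test_that("scores follow S = log_1.26(alpha * N / T)", {
  ct <- make_count_table(counts = 0, totals = c(1000, 1000),
                         masked = matrix(TRUE, 2, 20))
  ct$masked[1, "A"] <- FALSE
  ct$counts[1, "A"] <- 100
  ct <- apply_pseudocounts(ct)
  # N = 100, T = 1000, alpha = 100 -> log_1.26(10)
  p <- score_matrix(ct, alpha = 100)
  expect_equal(p$scores[1, "A"], log(10) / log(1.26), tolerance = 1e-9)
  expect_equal(p$scores[1, "A"], 9.963, tolerance = 1e-3)
  # f exactly 1/alpha -> score 0
  p0 <- score_matrix(ct, alpha = 10)
  expect_equal(p0$scores[1, "A"], 0, tolerance = 1e-12)
  # pseudocounted N = 1, T = 10000, alpha = 1000 -> log_1.26(0.1)
  ct2 <- make_count_table(counts = 0, totals = c(10000, 10000),
                          masked = matrix(TRUE, 2, 20))
  ct2$masked[1, "A"] <- FALSE
  ct2 <- apply_pseudocounts(ct2)
  p2 <- score_matrix(ct2, alpha = 1000)
  expect_equal(p2$scores[1, "A"], -9.963, tolerance = 1e-3)
})

test_that("PSSM invariants: mean-zero, monotonicity, scale law, floor", {
  set.seed(77)
  for (rep in 1:5) {
    P <- sample(3:8, 1)
    totals <- rep(sample(500:5000, 1), P)
    counts <- matrix(rpois(P * 20, lambda = runif(1, 0.5, 30)), P, 20)
    ct <- make_count_table(counts, totals)
    ct$masked[cbind(seq_len(P), sample(20, P, replace = TRUE))] <- TRUE
    ct <- apply_pseudocounts(ct)
    p <- score_matrix(ct)

    # (1) centering
    expect_lt(abs(mean(p$scores[!p$masked])), 1e-6)

    # (2) monotone in N at fixed T and alpha
    ord <- order(ct$counts[1, ])
    s <- p$scores[1, ord]; n <- ct$counts[1, ord]; ok <- !is.na(s)
    expect_true(all(diff(s[ok])[diff(n[ok]) > 0] > 0))

    # (3) multiplying every N and T by k leaves scores unchanged
    ct_k <- ct
    ct_k$counts <- ct$counts * 7L
    ct_k$totals <- ct$totals * 7L
    p_k <- score_matrix(ct_k, alpha = solve_alpha(ct_k))
    expect_equal(p_k$scores, p$scores, tolerance = 1e-9)

    # (5) the position minimum sits on a pseudocounted cell when one exists
    for (i in seq_len(P)) {
      if (any(ct$pseudocounted[i, ])) {
        expect_equal(min(p$scores[i, !p$masked[i, ]]),
                     p$scores[i, which(ct$pseudocounted[i, ])[1]])
      }
    }
  }
})

test_that("the full pipeline warns below the recommended depth", {
  gl <- demo_gl()
  expect_warning(build_pssm(align_repertoire(rep(gl$nt_seq, 3), gl)),
                 "below the recommended")
})
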
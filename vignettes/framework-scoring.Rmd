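---
title: "Scoring antibody framework mutations from baseline repertoires"
author: "repframe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring antibody framework mutations from baseline repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repframe)
```

## The problem

Affinity maturation leaves baseline human antibody repertoires with highly
reproducible substitution preferences at framework (FR) positions of the
heavy-chain variable domain. Because the framework scaffolds the
antigen-binding loops, those preferences carry information about what the
immune system tolerates — and repeatedly selects — at each position:
stability, expression, low immunogenicity. `repframe` turns deeply sequenced
IgG repertoires, binned by inferred germline V gene, into position-specific
scoring matrices (PSSMs) of framework substitutions, and uses them to ask how
"repertoire-like" the framework mutations of any query antibody (for
instance, a therapeutic candidate) are.

Only heavy-chain V segments are modeled, and only FR1–FR3: CDRs are under
antigen-specific selection and are excluded, as are the D- and J-encoded
segments (CDR3/FR4), which are too variable to cover well.

## The score model

For germline gene $g$, let $N_{ij}$ be the number of repertoire sequences
carrying amino acid $j$ at FR position $i$, and $T_i = \sum_{j=A}^{Y} N_{ij}$
the number of gap-free sequences at that position. The score of substitution
$j$ at position $i$ is

$$S_{ij} \;=\; \log_{1.26}\!\left(\frac{\alpha\, N_{ij}}{T_i}\right),$$

with the base 1.26 following the log-odds convention of classical Dayhoff
matrices. Three preprocessing rules precede scoring:

* **Column filtering.** Alignment columns occupied by strictly fewer than 10%
  of sequences (more than 90% gaps, i.e. rare insertions) are dropped;
  retained columns map one-to-one onto germline positions.
* **Wild-type and allele masking.** At every position the germline residue,
  and any residue that is germline in *another allele of the same gene*, is
  masked out of scoring. Population-level allelic variation would otherwise
  masquerade as a spuriously common "mutation" (the bundled synthetic gene
  pair, whose alleles differ by D75M, illustrates the effect). Masking does
  not change $T_i$: frequencies remain true per-sequence frequencies, which
  keeps the observed counts interpretable even though the germline residue
  itself is never scored.
* **Pseudocounts.** Unmasked zero counts become one, so every cell has a
  finite score; the pseudocounted cells form the per-position lower bound of
  the matrix.

### The centering constant

$\alpha$ is chosen per germline so that the mean score over all unmasked FR
cells is exactly zero — a randomly chosen framework substitution is neutral
by construction, common substitutions score positive, rare ones negative.
Writing $f_{ij} = N_{ij}/T_i$,

$$\overline{S} = \frac{\log\alpha + \overline{\log f}}{\log 1.26} = 0
\quad\Longleftrightarrow\quad
\alpha = \exp\!\left(-\overline{\log f}\right),$$

the reciprocal of the geometric mean of the observed frequencies.
`solve_alpha()` uses this closed form rather than iterating; the test suite
verifies it against a numeric root-finder. Two conventions are deliberate
and worth knowing: the mean is taken over *all* unmasked cells, including
pseudocounted ones (excluding them would recenter the matrix on the observed
cells only and shift every score upward), and the denominator $T_i$ includes
wild-type observations even though wild-type cells are masked.

## Antibody-level FR scores

Framework mutations are assumed additive and independent. For a query with
$m$ FR mutations whose scores are $S_{ijk}$,

$$\mathrm{FR} \;=\;
\begin{cases}
1 & m = 0\\[2pt]
\dfrac{\sum_{k=1}^{m} S_{ijk}}{c_0\, m + c_1\, m^2} & m > 0,
\end{cases}$$

where $c_0, c_1$ are fitted per germline by ordinary least squares (no
intercept) of repertoire score sums on $(m, m^2)$, over a simple random
sample of repertoire antibodies — 1,000 with replacement by default,
excluding $m = 0$ antibodies, which contribute no constraint. The
denominator estimates the typical score sum of a repertoire antibody with
the same mutation load, so repertoire antibodies average an FR score of one
and an antibody with unusually rare framework mutations falls below one.
Zero-mutation antibodies are assigned FR = 1 by definition (the ratio is
otherwise undefined).

Two open choices are exposed as flags rather than hard-coded: the fit can
be run on per-$m$ mean score sums instead of raw antibodies
(`per_m_means = TRUE`; the default fits raw antibodies, the most literal
reading of least squares over a sample), and query mutations that land on a
*masked allelic* residue are excluded from both $m$ and the sum — they are
allelic, not somatic.

## Codon distance classes

Somatic hypermutation is dominated by single-nucleotide events, so
substitutions reachable from the germline codon in one nucleotide change are
strongly enriched over those needing two or three. `min_nt_from_codon()`
computes the minimum Hamming distance from a codon to any sense codon of a
target residue (stop codons are excluded as targets, and no pathway through
intermediate codons is modeled — distances are direct);
`min_nt_aa_level()` minimizes over the source residue's codons when the
germline codon is unknown. The codon-level basis is preferred whenever the
germline nucleotide sequence is available, because different codons of one
residue can need different substitution counts.
`class_score_summary()` partitions a PSSM by these distances; on any
repertoire generated by single-nucleotide events the class means order
1-nt > 2-nt > 3-nt, which the test suite asserts via one-tailed Welch tests.

## Supporting analyses

* `per_position_frequency()`, `identity_summary()`, `dn_ds()` summarize
  maturation load. dN/dS counts **one event per codon**: a codon whose
  translation differs from germline is one nonsynonymous event; a codon
  identical in translation but not in nucleotides is one synonymous event.
  The per-codon rule (rather than per-nucleotide) is pinned by an
  enumeration oracle in the tests.
* `pssm_correlation()` compares matrices over the intersection of unmasked
  cells, optionally restricted to positions with a shared germline codon or
  to 1-nt-accessible cells; disjoint same-repertoire subsamples give the
  basal-noise ceiling. `cluster_pssms()` runs UPGMA (average linkage) on
  $1 - r$ and writes Newick.
* `subsample_convergence()` rebuilds the matrix on subsamples drawn without
  replacement and reports the median and 97.5th percentile (the upper end
  of a 95% band) of absolute score displacement against the full matrix —
  the practical tool for choosing a sequencing depth; shallow repertoires
  warn in `build_pssm()` below 100,000 sequences by default.
* `bin_by_fold_change()` / `average_and_test()` implement peptide:MHC-II
  affinity fold-change binning for 15-mer scans: mutant peptides whose
  germline counterpart binds with high affinity ($K_D < 1{,}000$ nM,
  strict) fall into fold-change bins $<0.5$, $[0.5, 2]$ (closed on both
  ends), $>2$; scores are averaged per DRB1 allele and bin before Welch
  t-tests with Benjamini–Hochberg correction, so a peptide binding several
  alleles contributes once per allele. Affinity prediction itself is out of
  scope — any TSV of (peptide, allele, kd_nM) is accepted. Mutant and
  germline windows are paired by identical start position on the aligned
  germline; a peptide containing several mutations contributes the mean of
  their scores (switchable to per-mutation expansion).

## The synthetic repertoire generator

Every statistical claim in the package is testable without external data
through `simulate_repertoire()`: sequences descend from a germline by
$k \sim \mathrm{Poisson}(\lambda)$ independent single-nucleotide
substitutions, positions drawn by per-position weights, replacement bases by
a transition-biased matrix (2:1 by default). Defaults are fixed once:
$\lambda = 12$ events per 294-nt sequence (~4% per base), which produces
per-amino-acid-position mutation frequencies around 10% — the load regime of
baseline IgG repertoires — with uniform position weights. The bundled
germline references are synthetic (random sense codons behind a fixed
leader, frozen as constants) and resemble no database gene.

`true_aa_profile()` is the generator's ground truth: in the single-hit
regime the expected substitution frequency per cell is a closed-form sum
over the codon's nine single-nucleotide neighbors; a Monte-Carlo mode covers
multi-hit loads. The end-to-end recovery test — simulate, tally, mask,
pseudocount, solve $\alpha$, score, correlate with the profile-derived
scores — exceeds $r = 0.95$ over well-observed cells at 50,000 sequences.

The generator deliberately models **no selection, no clonal structure, no
isotype dynamics and no AID hotspot motifs**. Passing tests therefore
demonstrate that the machinery recovers a known mutational mechanism, not
that real repertoires have any particular score distribution: absolute
score magnitudes from real data (which mix mutation bias with functional
selection) are outside what the simulator can certify.

## Numerical choices and degenerate inputs

* Occupancy threshold is strict (`< 0.10` drops; exactly 10% is retained).
* Germline assignment breaks identity ties lexicographically by gene name
  and reports the tie; best identity below 60% is "unassigned".
* Pairwise alignment (match +1, mismatch −1, gap of length $L$ costs
  $5 + L$) anchors every sequence to the common germline instead of a
  progressive MSA of the whole repertoire — identical column semantics at
  linear cost. Insertions relative to the germline are tallied, and any
  insertion that would survive the occupancy filter triggers a warning
  (supply a pre-aligned matrix to retain such columns).
* The quadratic FR denominator is checked for positivity over the fitted
  load range at fit time; scoring at a load where it is non-positive is an
  error, not a silent sign flip.
* Rank-deficient normalization fits (a single distinct $m$) error with an
  instruction to enlarge the sample; zero synonymous events make dN/dS `NA`
  with counts preserved; empty codon-distance classes report $n = 0$ and
  `NA` means.

## Problem sizes

The shipped tests run the pipeline at 10,000 simulated sequences for
centering and FR-score calibration, 20,000 for rate-recovery checks, and
50,000 for score recovery; subsampling convergence is demonstrated between
500 and 5,000 sequences against a 10,000-sequence reference. These sizes
are where the simulator's statistics are comfortably stable; deeper
repertoires only tighten them.

## Limitations

Scores are heavy-chain, framework-only, and gene-level (no per-allele
matrices — alleles are masked instead). The FR score assumes additivity and
ignores epistasis between framework mutations. Light chains, CDR scoring,
lineage structure and binding-affinity prediction are out of scope.
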
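---
title: "Transcriptome-derived microsatellites: mining, QC and differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-derived microsatellites: mining, QC and differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrtools)
```

`ssrtools` implements the bioinformatic stages of developing and
quality-controlling microsatellite markers mined from assembled
transcriptome contigs. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## 1. Repeat mining

### Model

A microsatellite locus is a *maximal perfect tandem repeat*: `k`
consecutive exact copies of a primitive motif of period `p ∈ {2, 3, 4}`,
not extendable by a full copy on either side. Partial trailing copies are
excluded; the reported tract length is always `k × p`. Any non-ACGT
character (`N`, IUPAC ambiguity codes) terminates a run.

Motifs are grouped into cyclic-rotation classes and labelled by the
lexicographically smallest rotation (`CAG → AGC`). Two choices here are
deliberate:

* **No reverse-complement collapsing.** Transcript sequence is stranded;
  `AC` and `GT` stay distinct so the report reflects the observed strand.
  There are therefore 6 dinucleotide, 20 trinucleotide and 60
  tetranucleotide classes.
* **Primitivity.** `ACAC` is two copies of `AC`; tracts are only ever
  reported under their shortest period. `canonical_motif()` rejects
  degenerate motifs naming the shorter period.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `min_repeats` | 8 | minimum whole motif copies, regardless of period (16 bp for di-, 24 bp for tri-, 32 bp for tetranucleotides). A single copy-count threshold is the convention for EST-SSR screens; it is deliberately conservative so that primers target long, reliably polymorphic tracts. |
| `periods` | 2–4 | mononucleotide runs are not mined: homopolymers in transcript data are dominated by sequencing artefacts and poly-A tails, and the compound mono components seen in genotyping panels arise at allele scoring, not mining. |
| `flank_len` | 200 | flank bases extracted each side for primer design, clipped at contig edges. The value is a toolkit choice: enough sequence for typical primer-design windows without dragging in whole contigs. |
| `compound_gap` | 10 | two reported tracts separated by at most this many bases are both flagged `compound`. The flag is informational only — compound loci tend to have messy electropherograms — and 10 bp reflects the adjacency seen in published compound motifs. |

When a tract ends in a partial copy, several rotations of the same class
start within the first period of the run; the miner reports the leftmost
frame with the maximal copy count, exactly once. The test suite pins this
semantics to an independent brute-force oracle (enumerate every position
and motif, count copies, keep maximal runs, collapse same-class
overlaps).

## 2. Genotype tables and summaries

Genotypes are unordered diploid allele-size pairs (fragment lengths in
bp); missing is a distinct state, never "allele 0". GenePop is the
interchange format (2- or 3-digit codes; population labels taken from
the first individual of each `Pop` block, so a write/read round-trip
preserves the grouping up to relabeling).

Per-locus summaries are computed over **all individuals pooled**,
mirroring how published panel tables are reported: allele count, observed
heterozygosity `H_o` (heterozygotes / typed individuals), gene diversity
`H_e = 1 − Σ p²` from pooled frequencies, and percent missing. Pooling
means population structure legitimately depresses `H_o` below `H_e`
(Wahlund effect) — which is why the HWE tests below run per population,
never pooled. `H_e` is uncorrected by default; the small-sample factor
`2n/(2n−1)` sits behind `bias_correct = TRUE` because published panel
tables rarely state whether it was applied.

## 3. Hardy–Weinberg QC and null-allele diagnostics

### Chi-square HWE test

Per locus and population, expected genotype counts are `n pᵢ²`
(homozygotes) and `2 n pᵢ pⱼ` (heterozygotes) from observed allele
frequencies; the statistic sums `(O − E)²/E` over all `k(k+1)/2` cells
with `df = k(k−1)/2`. Choices:

* chi-square, not an exact or MCMC test — matching the screening practice
  the package supports, and cheap over a loci × populations grid;
* no continuity correction and **no cell pooling** — published screens
  rarely state a pooling rule, so instead a `low_expected` flag is set
  when any expected cell < 1 or more than 20% of cells < 5;
* statuses: `significant` (p < α), `non_significant`, `monomorphic`
  (k = 1 in that population), `untestable` (no data). The grid renders
  populations alphabetically.
* per-population multiple-testing correction is not applied by default:
  the grid is a diagnostic picture, not an inference procedure.

### Null-allele diagnostic

Null alleles produce a specific joint signature: null heterozygotes are
scored as homozygotes (deficit in `H_o`) and null homozygotes fail
entirely (missing calls). `deficit_vs_missingness()` computes the
tie-aware Spearman correlation (Pearson correlation of midranks) between
`H_e − H_o` and percent missing across loci. The p-value uses the t
approximation `t = r_s √((n−2)/(1−r_s²))`; full permutation enumeration
is available (`p_method = "exact"`, n ≤ 10). On the bundled checkerspot
panel the printed, rounded table values give `r_s = 0.851` — slightly
above the value published from unrounded data (0.81), as expected when
ranks are computed on rounded numbers.

`missingness_anova()` is classical one-way fixed-effects ANOVA of the
**raw** percent-missing values by multiplex group (an arcsine or logit
transform is defensible at n = 10 observations but the raw analysis
reproduces published practice). Degenerate inputs are defined explicitly:
all values equal → F = 0, p = 1; between-group differences with zero
within-group variance → F = ∞, p = 0.

## 4. Pairwise Fst

`pairwise_fst()` implements the Weir & Cockerham (1984) moment estimator
θ per population pair (r = 2 samples), per allele per locus, from the
variance components *a* (between populations), *b* (between individuals
within populations) and *c* (within individuals), combined
**ratio-of-sums** (`Σa / Σ(a+b+c)`) across alleles and loci — the
standard multi-locus rule, which weights loci by information rather than
averaging noisy per-locus ratios. Further choices:

* θ rather than an AMOVA formulation: for two populations with
  codominant unphased data the two coincide in expectation, and θ is
  fully specified from genotype tables alone;
* negative estimates are retained (they are part of the estimator's
  sampling distribution near Fst = 0), not clamped;
* missing calls are dropped per locus; loci with data in only one member
  of a pair are dropped for that pair (pairwise-complete); a pair with no
  shared polymorphic data yields `NA`, never a silent 0.

The test suite checks θ against an independently coded implementation
that builds the same components from raw ANOVA sums of squares
(agreement to 1e-10), and checks parameter recovery against the
simulator's generative Fst.

## 5. Mantel concordance test

`mantel_test()` correlates the off-diagonal pairs of two labelled
distance matrices and builds the null by simultaneously permuting rows
and columns of the second matrix. Design choices:

* **Permutation, not bootstrap.** Descriptions of this test sometimes say
  "bootstrap replicates"; resampling pairs independently would break the
  exchangeability structure the Mantel null requires, so label
  permutation is what is implemented (and documented prominently).
* One-sided `greater` default — the concordance hypothesis — with the
  add-one rule `p = (1 + #{r* ≥ r})/(1 + N)`, so p is never 0 and has
  resolution `1/(N+1)`.
* Matrices are aligned **by label**: the plain-text matrix format invites
  silent row-order mismatches, and aligning by position would turn those
  into wrong answers rather than errors.
* `NA` pairs are dropped pairwise with a warning.

## 6. The simulators: what a green test establishes

`simulate_contigs()` draws background sequence i.i.d. from the base
composition, **rejecting** any draw containing a spontaneous run at or
above the mining threshold, then plants the requested tracts and breaks
both boundaries so each planted tract is exactly maximal. The truth
table is therefore exact by construction, which is what makes
recall = precision = 1 a meaningful acceptance bar. Not emulated: real
transcriptome base composition, interrupted/imperfect repeats, assembly
errors, polyA tails. A green mining test establishes scanner
correctness, not performance on dirty assemblies.

`simulate_genotypes()` is a Balding–Nichols island model: ancestral
frequencies per locus from a flat Dirichlet; population frequencies from
`Dirichlet(p (1−F)/F)`, so the generative differentiation parameter is
directly the expected Fst (at `F = 0` populations share the ancestral
frequencies exactly — accepted as the explicit no-structure limit);
genotypes drawn under within-population HWE. The null-allele overlay
follows the standard dominance model: each transmitted allele copy is
null independently with probability ν, null/null → missing,
null/visible → visible homozygote; hence expected extra missingness ν²
and an `H_o` deficit growing with ν. Baseline missingness is applied
independently afterwards. Defaults elsewhere in the tests (50
individuals/population, 20 loci, 5 alleles, Fst 0.10) are the regime the
acceptance criteria state. Not emulated: stepwise mutation, linkage,
selection on linked genes — precisely the forces that make real EST-SSRs
deviate from neutrality, so a green calibration test establishes
estimator correctness under the island model, not robustness to those
forces.

All randomness flows from one explicit spec seed through a scoped RNG
(`with_seed()`), leaving the caller's global generator untouched; equal
seeds give byte-identical FASTA/GenePop output.

### Calibration worlds

Two acceptance-style calibrations deserve a note on their stated worlds:

* HWE type-I error is measured on equifrequent k-allele HWE samples
  (k = 2 and 5, n = 100) — the canonical "population with k alleles".
  The true level of the chi-square test there is ≈ 0.052 (k = 2) and
  ≈ 0.046 (k = 5; slightly conservative because 15 genotype cells at
  n = 100 leave small expected counts), both inside the ±2 Monte-Carlo-SE
  acceptance band around 0.05.
* Mantel type-I is measured on independent random symmetric matrices
  (n = 15 labels, 999 permutations), where the permutation null is exact
  by construction; the band again reflects Monte-Carlo error only.

## 7. Known limitations

* The chi-square HWE test is approximate for rare alleles; the
  `low_expected` flag marks affected cells but no exact test is offered.
* MICRO-CHECKER-style null-allele *frequency estimation* is out of scope;
  the package diagnoses presence, not rate.
* GenePop parsing targets the classic dialect (title, loci, `Pop`
  blocks, 2/3-digit codes); extended dialects are not supported.
* Primer design itself (Primer3), read assembly, imperfect-repeat models
  and AFLP scoring are upstream/downstream of this toolkit.
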
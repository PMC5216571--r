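---
title: "Methods: expression level dominance, dosage compensation and the planted-category benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression level dominance, dosage compensation and the planted-category benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eldr)
```

## The data model

`eldr` analyzes bulk RNA-seq of three genotypes: a paternal diploid, a
maternal diploid, and their triploid hybrid carrying one paternal and two
maternal genome sets. The pipeline's entry point is a gene × sample integer
count matrix with per-gene transcript lengths and a sample-to-group map;
read mapping and assembly are upstream concerns. Counts are normalized to
RPKM = 10⁹·C/(N·L) (C reads on the gene, N total mapped reads in the
library, L transcript length in bp), and a gene's expression per genotype
is the arithmetic mean of its replicate RPKM values. The hybrid mean is
the *actual triploid expression level* (AT-ELV).

By default N is the column sum of the supplied matrix. When the matrix
covers only a subset of the transcriptome (filtered gene sets, simulated
data), the true totals should be passed explicitly: RPKM is a relative
measure, and a column-sum denominator both understates depth and couples
strong expression changes in one group into apparent changes everywhere
else. The simulator therefore reports its true per-library totals, and the
benchmark uses them.

## Differential expression between two genotypes

The per-contrast tests are two-library exact tests, so replicate counts
are pooled by summation within each group before testing (replicate
variance modelling — dispersion estimation, shrinkage — is deliberately
out of scope; the simulator quantifies what this costs, see below). Two
engines are provided:

* **Random-sampling model** (default): conditional on the total
  t = c₁ + c₂, c₁ is Binomial(t, n₁/(n₁+n₂)) under the null of equal
  relative expression; the two-sided p sums the point probabilities of all
  outcomes no more likely than the observed one. This is the exact,
  small-count-safe form of the MA-plot random-sampling test; the normal
  approximation of the original formulation is intentionally not
  implemented.
* **Fisher's exact test** on [[c₁, n₁−c₁], [c₂, n₂−c₂]]
  (point-probability method).

The two are near-equivalent at sequencing-scale n, which is why both are
offered behind one interface. p-values are Benjamini–Hochberg adjusted
across tested genes; a gene is called up/down when q < 0.001 **and**
|M| > 1 (both strict), with `use_fdr = FALSE` available to threshold raw
p-values instead. M is the log₂ RPKM ratio of the pooled counts: ±Inf
when exactly one side is zero (such genes can still be called), and the
mean intensity A is recorded as missing then. Genes with zero pooled
counts on both sides are flagged untested and called `ns`.

## The dosage model

With parental means χ_pat and χ_mat, the additive (no-compensation)
expectation is PT-ELV = ½χ_pat + χ_mat and the diploid-state expectation
is PD-ELV = ½χ_pat + ½χ_mat; PT − PD = χ_mat/2 ≥ 0 is exactly the extra
maternal dose. The genome doses are arguments, so reciprocal crosses can
be modelled; defaults are 1 paternal : 2 maternal. `dosage_comparison()`
sets M = log₂(AT-ELV/prediction) and calls |M| > 1 in threshold mode —
the default, because a prediction has no replicate structure to support a
test statistic. A statistical mode builds a pseudo-library for the
prediction as the same linear combination of the pooled parental counts
(rounded to the nearest integer); it is provided for completeness and
warns that predicted counts are pseudo-observations.

## The 12-category classifier

Genes are first routed by the zero-handling rules, in order:

1. **Silenced**: AT-ELV = 0 while both parents exceed the floor
   (default 10 RPKM).
2. **Novel**: both parents 0 while AT-ELV exceeds the floor.
3. **Excluded**: any remaining zero group mean. No pseudocount is added
   anywhere; the ratio classification is restricted to genes expressed in
   all three genotypes.

The floor is defined on the RPKM scale (a raw-count variant of the same
rule circulates in the literature); the RPKM form is implemented and the
floor is configurable.

For strictly positive triples, three pairwise calls are formed —
P (paternal vs maternal), Hb (hybrid vs paternal), Hg (hybrid vs
maternal) — where two levels are *equal* iff |log₂ ratio| ≤ τ
(non-strict, default τ = 1) and *higher*/*lower* otherwise. The decision
table, per parental branch and in order:

| P = higher | P = lower | P = equal |
|---|---|---|
| Hb higher → V | Hg higher → VI | both higher → IV |
| Hg lower → I | Hb lower → II | both lower → III |
| Hb equal ∧ Hg higher → VII | Hb equal ∧ Hg lower → VIII | otherwise → NoChange |
| Hg equal ∧ Hb lower → IX | Hg equal ∧ Hb higher → X | |
| Hb lower ∧ Hg higher → XI | Hb higher ∧ Hg lower → XII | |
| both equal → Ambiguous | both equal → Ambiguous | |
| otherwise → Unresolved | otherwise → Unresolved | |

Three choices here were genuinely open:

* **Equality is non-strict at τ.** Threshold conventions differ on whether
  the boundary counts as a difference; taking equality at
  |log₂ ratio| ≤ 1 reproduces all 45 published growth-gene labels, including the borderline parental ratio of
  *bambia* (0.986 → equal) and the hybrid/maternal ratio of *igfbp5a*
  (1.075 → higher).
* **Ambiguous** (hybrid within τ of both parents while the parents differ,
  reachable when τ < log₂ ratio ≤ 2τ) gets its own label rather than being
  forced into a dominance category; an optional tie-break assigns ELD
  toward the parent with the smaller |log₂ ratio|. The published table
  contains no such case, so no behaviour could be copied.
* **Unresolved** marks logically inconsistent call triples. They cannot
  arise from one coherent expression triple (property-tested), but they
  can in statistical mode, where three independent tests need not be
  transitive; they are reported, never silently merged.

The classifier is total, scale-invariant, and mirrors under exchange of
the parental roles via {I↔II, V↔VI, VII↔X, VIII↔IX, XI↔XII} with III, IV,
NoChange and Ambiguous fixed — all property-tested over random triples.

## Enrichment and reporting

`category_enrichment()` tests over-representation of a category grouping
in a gene subset with the one-sided hypergeometric test on the
(subset vs rest) × (in grouping vs not) table; a variant using the whole
set as the comparator margin and a two-sided alternative are available by
flag, since either construction is defensible for these margins. The odds ratio
uses a 0.5 continuity correction only when a cell is zero.
`proportion_report()` reports grouping percentages at full precision
(rounded to one decimal only for display) and can carry genes known only
by count as a no-change remainder via its `denominator` argument — the
published growth-gene percentages use a denominator of 57 while only the
45 differentially classified genes are printed.

## qPCR arithmetic

`ddct_fold_change()` implements 2^−ΔΔCt with
ΔΔCt = (Ct_target − Ct_ref)_test − (Ct_target − Ct_ref)_calibrator.
`qpcr_fold_changes()` averages Ct within technical replicates of each
(biological replicate, condition) first, computes one fold change per
biological replicate, and summarizes mean and SD across replicates — the
conventional reading of "average threshold cycle", documented here because
the method name alone does not fix the order of averaging.

## The planted-category simulator

`generate_dataset()` emulates the study design: 3 genotypes × 3 replicate
libraries, 10⁶ mapped reads each, transcript lengths uniform on
400–4000 bp, negative-binomial counts with variance μ + φμ² (φ = 0.05
default, φ = 0 → Poisson) — the standard RNA-seq noise model for
overdispersed counts. Per gene, a category is drawn
(defaults: 5% in each of the twelve categories, 34% no-change, 3% each
silenced and novel), a baseline maternal RPKM is drawn log-normal with
median 50 and sdlog 0.6 — a detectable-transcriptome baseline chosen so
that planted geometry, not detection limits, dominates the benchmark —
and the three expected levels follow the category geometry with planted
effect 2^3 = 8-fold: dominant/equal levels match the relevant parent,
mid-parent genes sit at PD-ELV, transgressive genes sit 8-fold beyond the
extreme parent, and silenced/novel genes are planted at baseline + 3×floor
so their state is unambiguous at the 10-RPKM detection floor. The hybrid
expected level is then multiplied by the dosage factor (default 2/3,
i.e. compensation from the additive to the diploid state; 1 = no
compensation). With an 8-fold planted effect and τ = 1, the 2/3 scaling
(|log₂| ≈ 0.585) provably preserves every planted category, so truth
labels stay recoverable. Expected counts are μ = RPKM·N·L/10⁹.

What the simulator does *not* emulate: GC/length bias, mapping ambiguity
between homoeologs, correlated replicates, composition effects, or any
relationship between expression level and dispersion. Passing the
recovery benchmark therefore demonstrates that the pipeline's inference
is correct under its own assumptions, not that those assumptions hold for
any particular real dataset. In particular, the two-library pooling
strategy ignores biological replicate variance; at the benchmark's
dispersion the classifier still recovers ≥ 93% of planted labels, but the
exact-test p-values themselves are anti-conservative relative to a
replicate-aware model and should be read accordingly.

## Problem sizes and determinism

The test suite exercises the enumeration oracles exhaustively for totals
up to 50 (binomial) and small-to-moderate Fisher margins up to 60;
classifier properties run over 10⁴ random triples; the recovery benchmark
runs the full 2,000-gene design over seeds 1–5 and completes in seconds.
All simulation entry points take an explicit seed and are deterministic
given it; threshold-mode pipeline reruns are byte-identical, which the
manifest (configuration echo, input checksum, per-stage row counts)
makes checkable.

## Known limitations

* Genome-scale published tallies (thousands of differentially expressed
  genes) require the study's raw reads, which are not deposited; the
  package reproduces the in-paper 45-gene surface and the mechanisms, not
  those magnitudes.
* No allele-resolved analysis: the categories describe whole-gene levels
  of the three genotypes, not which homoeolog carries the change.
* No TPM/TMM/median-of-ratios alternatives: the analysis design is
  RPKM-only, and normalization choice is upstream of everything this
  package adds.
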
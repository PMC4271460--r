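---
title: "Benchmarking differential alternative splicing detection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking differential alternative splicing detection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dasbench)
```

# What this package models

Differential alternative splicing (DAS) is a change, between two
conditions, in the *relative* usage of a gene's isoforms — not in its
overall expression. Benchmarking DAS callers requires data where the truth
is known, which in practice means simulation. `dasbench` simulates at the
level at which count-based DAS statistics actually operate: **counting
units**, the disjoint exonic bins and exon–exon junctions obtained by
flattening all transcripts of a gene at every splice boundary. Skipping
read-level simulation and alignment keeps a full benchmark grid at
desk scale while preserving the statistical structure that drives DAS
detection — negative-binomial biological variability of gene totals and
condition-dependent isoform proportions.

## Gene flattening and splice events

A gene model is a set of transcripts, each an ordered list of 1-based
inclusive exon intervals on one chromosome and strand. Flattening
(`flatten_gene()`) cuts the exonic union at every exon start and end
observed in any transcript, so no bin interior contains a splice boundary;
each distinct intron contributes one junction unit. Effective lengths —
the weights used when distributing a transcript's reads over its units —
are the bin width in nucleotides for exonic bins and `read_length - 1` for
junctions (the number of read start positions spanning the junction; the
standard convention, with the default read length of 100 nt chosen to
match common paired-end protocols).

Pairwise event extraction (`extract_events()`) compares the exonic
coverage of two transcripts over their shared span and classifies each
maximal differing region: an internal exon of one transcript inside the
other's intron with shared flanking introns is a skipped exon (SE); an
intron of one transcript fully exonic in the other is intron retention
(IR); a single differing exon boundary with the other intron boundary
shared is an alternative 5' or 3' splice site, decided strand-aware by
whether the donor or acceptor side differs; two reciprocal internal exons
separated by a region intronic in both transcripts are mutually exclusive
exons (MXE); everything else — multi-exon skips, combined boundary shifts —
is `complex`. Three deliberate conventions:

* **Transcription start/end differences are not splice events.** Coverage
  is compared only over the span both transcripts reach, and differing
  regions touching the shared-span edges are ignored. Alternative
  first/last exons reflect alternative transcription, not splicing, and
  including them would blur the event-type partition.
* **Genes with more than two transcripts** are classified from all
  pairwise comparisons and called "simple" only when every informative
  pair agrees on one identical event. This matches the restriction of
  per-type evaluation to two-transcript single-event genes.
* **A3SS and A5SS are merged** into one `A3A5SS` class for the per-type
  partition: from the detector's point of view the two are the same
  problem. MXE is detected but, being rare and structurally two-sided, is
  not part of the three-class partition (`A3A5SS` / `IR` / `SE`) either.

These conventions affect borderline genes (e.g. UTR-only variants), which
is why counts of "two-transcript single-event" genes on a real annotation
can shift slightly under a different event-calling convention.

## The synthetic annotation generator

`synth_annotation()` builds non-overlapping genes on one synthetic
chromosome, each constructed to realize a requested class and verified by
`classify_gene()` before being returned (a generation error, not a silent
mislabel, if the round trip fails). Class counts are allocated
deterministically — `floor(fraction × n)` plus largest-remainder — so a
400-gene annotation with four 0.25 fractions contains exactly 100 genes
per class. Default lengths (exons 50–300 nt, introns 80–200 nt,
intergenic gap 500 nt) emulate compact plant-like genes, where introns are
short and intron retention dominates; they are structural placeholders,
not fitted values. The generator emulates *structure* only: no sequence,
no GC or positional bias, no overlapping genes, no shared exons between
genes. Tests passing on generated annotation therefore validate the
counting and statistical machinery, not robustness to the messiness of
real annotation (fragmented models, non-canonical attributes), which
enters only through the GFF3/GTF parser.

# The simulator

Simulation is a two-step hierarchy per gene × sample:

1. **Gene total:** `M ~ NB(mean = μ · d, Var = μd + α(μd)²)`, with `μ` the
   baseline-depth mean, `d` the depth factor (1.0 ≡ the baseline depth;
   0.6 and 0.25 are the reduced-depth settings), and `α` the dispersion of
   the sample's condition. `α = 0` falls back to Poisson. Under the `Same`
   pattern both conditions share one `α` per gene; under `Diff` each
   condition has its own.
2. **Partition:** `M` is multinomially split over transcripts by the
   condition's isoform proportion vector θ, then each transcript's count
   multinomially over that transcript's units with effective-length
   weights. Unit counts add over transcripts sharing a unit, so gene
   totals are conserved exactly — an invariant the tests check.

**PALT** (percentage of the alternative isoform) is the single knob for
differential splicing: a true-AS gene's designated alternative transcript
has abundance `palt_control` (default 0.2) in condition 1 and
`palt_treatment` (0.4/0.6/0.8 for low/medium/high signal) in condition 2.
Two under-determined choices are made in the simplest exchangeable way and
are configurable: the remaining `1 − PALT` is split *equally* among the
standard isoforms, and null multi-isoform genes draw one proportion vector
from a symmetric Dirichlet(1) used identically in both conditions — which
makes condition labels exchangeable for null genes, the property the
calibration tests rely on.

NB parameters can be estimated from a real gene × sample count matrix by
per-gene method of moments (`estimate_nb()`): `μ = m`,
`α = max(0, (s² − m)/m²)`, with the negative-dispersion clamp keeping the
estimator defined at the 2–3 replicates typical of calibration data;
`pooled` mode centers each condition and estimates one α per gene. Without
a calibration matrix, `default_nb_params()` draws synthetic defaults:
log-normal μ (median 200 reads, σ_log = 1.5) and α ~ U(0.05, 0.5), spans
chosen to cover weakly-to-strongly overdispersed bulk RNA-seq genes. The
method-of-moments estimator's typical (median) relative error for α at
100 replicates per condition is about 10–15%; a single estimate exceeds
25% error roughly one time in ten, which is why the package's recovery
checks bound the median over repeated estimates rather than one draw.

# Reference detectors

The detectors implement the *families* of statistics used by published
count-based DAS tools, in their simplest defensible form; they are
reference implementations for exercising the harness, not re-implementations
of any specific package.

* **Unit-fraction statistic.** Per unit `i` and condition `j`,
  `p̂_ij` is the mean over replicates of the unit's fraction of the gene
  total in that sample and `v̂_ij` the across-replicate variance;
  `T = (1/U) Σ_i (p̂_i1 − p̂_i2)² / (v̂_i1 + v̂_i2 + ε)`. The floor
  `ε = 1e-8` keeps `T` finite for degenerate zero-variance units while
  being far below any real variance scale. Samples with gene total 0 are
  dropped; fewer than two usable replicates in a condition flags the gene
  `NA` rather than scoring it.
* **Permutation p-values.** Condition labels are permuted jointly across
  all genes. When the design admits at most `n_perm` distinct label
  splits, all are enumerated and `p` is the exact tail fraction (the
  observed labeling included); otherwise `n_perm` sampled permutations
  with the add-one convention `p = (1 + #{T* ≥ T}) / (n_perm + 1)`.
  Default `n_perm = 1000`. A structural consequence worth knowing: the
  statistic is invariant to swapping the two condition labels, so every
  split ties with its complement and a balanced `k vs k` design yields at
  most `C(2k, k)/2` distinct values — at 3 vs 3 the p-value floor is 0.1,
  and nothing can pass an FDR 0.05 cutoff. This is a property of
  permutation DAS tests generally, visible in published benchmarks as
  permutation-based methods reporting nothing significant at three
  replicates; at 5 vs 5 (126 effective splits) calibration is restored,
  and the package's calibration checks are run at both designs.
* **√JSD statistic.** The square root of the Jensen–Shannon divergence
  (base-2 entropy, so JSD ∈ [0, 1] and √JSD is a metric) between the two
  conditions' mean unit-fraction vectors, with the same permutation
  scheme.
* **ψ bootstrap test.** Per sample, `ψ = inclusion/(inclusion + exclusion)`
  over an event's inclusion/exclusion units, each side first divided by
  its summed effective length (on by default — junction-only exclusion
  sides would otherwise be structurally down-weighted against multi-bin
  inclusion sides; switchable off). The score is the bootstrap probability
  that the condition means differ by more than `c = 0.1`, a conventional
  minimum-biological-effect cutoff.
* **Gene-level Bonferroni**, `min(1, k · min p)`, for combining unit-level
  p-values.

# Evaluation harness

Rankings are `1 − P_adj` where adjusted p-values exist (Benjamini–Hochberg
for the internal detectors; Bonferroni also provided) and the raw
statistic otherwise. ROC curves sweep distinct score values descending;
tied targets enter as one step, i.e. a diagonal segment — the unbiased
convention. Targets missing from a method's output are ranked last
(score −∞), mirroring how benchmarks handle methods that report subsets.

The restricted AUC integrates the curve by trapezoid over FPR ∈ [0,
`fpr_max`] (default 0.2, the regime where DAS callers actually operate),
interpolating at the right edge. Because a raw partial AUC caps at
`fpr_max`, the default report standardizes it (McClish):
`0.5 · (1 + (pAUC − pAUC_min)/(pAUC_max − pAUC_min))` with
`pAUC_max = fpr_max`, `pAUC_min = fpr_max²/2`, so a random ranking scores
≈ 0.5 and a perfect one exactly 1 — the scale on which published benchmark
AUCs near 0.5 for near-random methods are readable. The raw value is
always attached alongside, so either convention can be compared. Both the
curve construction and the partial AUC are verified against brute-force
threshold enumeration on all small instances, and the full AUC against an
independent ROC implementation.

Rank concordance between methods is Spearman's ρ (average ranks for ties)
over the intersection of reported targets; overlap tables count shared
significant calls.

# Problem sizes, determinism, limitations

The shipped checks use 1000-gene annotations (200 true AS / 800 null for
power; 0 true AS for calibration), 3–8 replicates per condition and 1000
permutations — sizes at which every figure of merit recomputes in seconds
and Monte-Carlo error is small relative to the tolerances asserted. All
randomness flows from explicit integer seeds through a single
seed-restoring RNG wrapper; derived per-gene and per-stage seeds keep any
one component's draws independent of another's. Known limitations: no
read-level effects (fragment-length, GC, positional or sequencing-error
models), no mapping ambiguity, no differential expression confounding
(gene-level μ is equal across conditions by default), no overlapping
genes, and the reference detectors deliberately omit the model-specific
machinery (GLMs, Bayesian priors, transcript assembly) of the tools they
echo.
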
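---
title: "Classifying local and systemic nutrient-resupply responses in split-root RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying local and systemic nutrient-resupply responses in split-root RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitSulfur)
```

## The experimental design and what the package computes

A split-root experiment divides one plant's root system between two
compartments. After a period of sulfur starvation, sulfate is returned to
one compartment (`SPSR_R`) while the other stays deprived (`SPS0_R`);
whole-root resupply (`SR_R`) and untreated controls (`CK_R`) anchor the
comparison, and the shoots of the same plants (`SP_Sh`, `SR_Sh`) report
the above-ground side of the signalling. Because the two root halves share
one shoot, a gene that recovers in the *still-deprived* half can only have
received a shoot-relayed (systemic) signal, while recovery confined to the
resupplied half reflects local perception.

`splitSulfur` takes a gene-level fragment-count matrix for the nine sample
groups and produces, per tissue and per deficiency direction, a partition
of the deficiency-responsive genes into recovery classes: in roots
*local* (set codes A/E), *systemic* (B/F), *both* (C/G), *none* (D/H) and
*unrecovered*; in shoots *hetero-responsive* vs *homogeneous-only*
(A/B up, C/D down) and *unrecovered*.

## The differential-expression model

The classifier consumes nothing but per-contrast DEG sets, so the DE step
is deliberately self-contained and fully specified.

**Normalisation.** Median-of-ratios size factors over the samples of the
contrast, computed on genes with all-positive counts and rescaled to
geometric mean 1; if no such gene exists the factors fall back to
column-sum ratios.

**Dispersion.** A method-of-moments estimate per gene,
`phi_raw = max(0, (s2 - m) / m^2)`, where `m` is the pooled normalised
mean and `s2` the pooled within-group variance, shrunk towards the
across-gene mean: `phi_hat = w * phi_bar + (1 - w) * phi_raw`. At three
replicates per group the gene-wise moment estimate is mostly sampling
noise, and the zero-clamping correlates small `phi_raw` with inflated
test statistics. Two calibration choices follow from this:

* `phi_bar` is the **untrimmed** mean of `phi_raw`. The distribution of
  `phi_raw` across genes is strongly right-skewed at small n, so a
  trimmed mean systematically underestimates the centre and makes every
  test anticonservative.
* the default weight is `w = 0.8`, leaning heavily on the pooled value.
  On 5,000-gene all-background simulations (dispersion 0.1, 3
  replicates) this holds the empirical fraction of `p < 0.05` at
  0.041–0.050 across seeds, where lighter shrinkage (for instance
  `w = 0.3`) sits at 0.07–0.08. Both knobs are arguments of
  `estimate_dispersion()` for users who prefer gene-wise behaviour.

**Test.** `log2FC = log2((mean_A + 0.5) / (mean_B + 0.5))` — the 0.5
pseudocount keeps fold changes finite for all-zero groups — with the
delta-method standard error given in the README and a two-sided normal
p-value. Genes with zero counts in every sample of the contrast are not
detected transcripts for that comparison: they are excluded from the BH
denominator and reported with `p = fdr = 1`. DEG status is the strict
conjunction `|FC| >= 2 & p < 0.05 & FDR < 0.01`; all three thresholds are
configurable via `deg_thresholds()`.

This Wald test stands where published analyses of this design typically
place DESeq2 or edgeR. It is isolated behind the per-contrast record
table, so a different engine can be substituted without touching the
classifier.

## The classification set algebra

"Recovered" means a *significant opposite-direction call* in the resupply
contrast — strict set intersection, not a numeric drift toward baseline.
This makes class membership threshold-sensitive by construction (a gene
hovering near the fold-change cut-off can move between classes D and A/B
under resampling), which is why the package reports every set size
alongside materialised gene lists rather than percentages alone.

The whole-root recovery gate is applied first: genes significant in a
split-half contrast but not in `SR_R/S0_R` are `unrecovered`, never
classified further. Within a (tissue, direction) branch the four class
sets partition the recovered set exactly — an invariant asserted in the
test suite across randomised inputs — and exchanging the `SPSR_R` and
`SPS0_R` inputs swaps local and systemic labels exactly.

Root and shoot universes are handled independently; the overlap of the
two tissues' deficiency DEG sets is reported separately as plain
intersections (`tissue_common` in the run report).

Percentages are rendered with decimal half-up rounding at a caller-chosen
precision (1 or 2 decimals in practice); the underlying value is kept
unrounded, and every reported fraction is recomputable from its integer
numerator and denominator.

## FPKM and QC

FPKM uses the per-sample column sum of the supplied count matrix as the
"million mapped fragments" total — the only total available once the
input is a count table; quantifiers that work from alignments would use
the mapped-fragment count instead, so absolute FPKM values can differ by
a few percent from alignment-based reports, while all within-sample
structure is unaffected. Replicate QC is pairwise Pearson correlation of
`log10(FPKM + 1)` within each group; the pseudocount 1 stabilises the
variance of low expressors. Constant vectors have no defined correlation
and are reported as missing values, counted in the QC summary. A full
PCA adds no decision content here and is deliberately out of scope.

## Enrichment

Term over-representation is the one-sided upper-tail hypergeometric
probability; depletion is never tested. BH adjustment runs within each
annotation category (BP/MF/CC/pathway) by default, mirroring the
convention of separate GO and pathway analyses, with a switch for a
single global adjustment. The annotation file defines the background
universe — no ontology-graph propagation is applied, terms are tested
exactly as annotated — so results are reproducible per input but will
differ from services that propagate annotations up the GO graph. Ties in
top-N selection break lexicographically by term id to keep reports
deterministic.

## What the simulator emulates — and what it does not

`simulate_counts()` draws negative-binomial counts with
`variance = mu + phi mu^2` (Poisson at `phi = 0`), matching the test's
model. Per-gene baseline means are log-uniform over
`base_mean_log_range` (default `10^0.5`–`10^3.5`, spanning low and high
expressors without heavy tails); library-size factors are log-normal
with CV `libsize_cv` (default 0.1), renormalised to geometric mean 1 so
the global scale stays identifiable; gene lengths are uniform over
200–10,000 bp. Planted classes multiply the baseline by group-specific
factors of `2^±Delta` exactly as the class definitions prescribe
(`expected_mean_pattern()` is the single source of those patterns).

Default class proportions reproduce the motivating study's root-tissue
cardinalities (128/8/105/172 local/systemic/both/none up-recovered genes,
2,306 up-unrecovered, the 28/7/85/1044/2866 down mirrors, and 30,595
background genes out of 37,344); the default effect size `Delta = 3` and
dispersion `phi = 0.1` are the package's benchmark conditions. The
rounding remainder of class allocation goes to the background class —
deterministic and conservative.

One planted class per gene drives both tissues: shoots reuse the root
machinery with `SR_Sh`/`SP_Sh` in the homogeneous/heterogeneous roles,
mapping local/systemic/both to *hetero-responsive*, none to
*homogeneous-only* and unrecovered to itself. This is a deliberate
simplification — it makes shoot and root DEG sets fully overlapping,
which real tissues are not.

Equally deliberate omissions: no read-level simulation, no batch effects
beyond library size, no gene–gene correlation, no mean–dispersion trend,
and identical dispersion for every gene. Passing the recovery benchmarks
therefore demonstrates that the pipeline's logic is correct under its own
model assumptions, not that the statistical power estimates transfer to
real rice data, whose dispersions and effect sizes are unknown (the raw
study data are not publicly deposited).

## Problem sizes and numerical choices

The test suite and acceptance script use 5,000-gene null simulations for
size calibration, a 10,000-gene planted simulation (3 replicates,
baselines >= 100) for class-recovery benchmarks — at these settings the
confusion-matrix diagonal for local/systemic/both exceeds 0.99 and under
0.5% of background genes acquire any label — and 20 randomised 250-gene
runs for the partition invariants; these sizes give stable Monte-Carlo
estimates while keeping a full run in minutes on a laptop. Determinism
contracts: the same design and seed reproduce byte-identical report JSON;
all randomness flows through the single design seed.

The pipeline config is a single YAML file (the natural single-file config
format for an R package, read with `yaml`), with `simulate:` or
`inputs:` sections, an optional contrast roster and thresholds;
`inst/scripts/splitroot-pipeline.R` wraps `run_pipeline()` for shell use
with exit codes 0/1/2 (ok / user error / internal error).

## Known limitations

* The moment-based Wald test has no GLM machinery: no covariates, no
  exact small-count test, no independent filtering. It is calibrated for
  the design it serves (two groups, 2–4 replicates).
* The strict significant-opposite-call definition of recovery means
  class sizes shrink as thresholds tighten; compare runs only at fixed
  thresholds.
* With the study's own group sizes (3 replicates) the systemic class is
  intrinsically the hardest: it requires a *non*-call in one contrast
  and a call in another, so its recall degrades fastest as `Delta`
  shrinks or `phi` grows.
* FPKM totals are column sums, not mapped-fragment totals; see above.
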
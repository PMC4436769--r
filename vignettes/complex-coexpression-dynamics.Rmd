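---
title: "Quantifying co-expression dynamics of protein complexes"
author: "coexdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying co-expression dynamics of protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexdyn)
```

## The question

Subunits of a protein complex tend to be co-expressed, so the pairwise
correlation structure of a complex's genes is a usable proxy for how
coherently the complex is assembled and regulated. `coexdyn` asks whether
that internal structure differs between a disease ("case") group and a
control group, and how the difference evolves over a time course. The
motivating setting is a two-group transgenic-mouse brain microarray time
course (an anti-NGF neurodegeneration model such as AD11 versus matched
controls, sampled at months 1, 3, 6 and 15, with 15 animals per group per
timepoint), with complexes taken from a CORUM-style catalog; the machinery
is generic for any two-group, multi-timepoint expression design.

## The model and its two statistics

For a complex with $n$ measured genes, every (group, timepoint) cell of the
design yields an upper-triangular matrix of the $N = n(n-1)/2$ pairwise
Pearson correlations between gene expression profiles, computed over that
cell's samples only. Case and control matrices at the same timepoint, $A$
and $B$, are compared two ways.

**Average correlation shift.** The entries $A_{ij}$ and $B_{ij}$ refer to the
same gene pair, so they are treated as matched pairs and the shift in the
mean correlation is tested with a paired t statistic,

$$ t = \frac{\sum_{i<j}(A_{ij}-B_{ij})}
  {\sqrt{\tfrac{N\sum_{i<j}(A_{ij}-B_{ij})^2-\left(\sum_{i<j}(A_{ij}-B_{ij})\right)^2}{N-1}}}, $$

algebraically the textbook paired t (mean difference over its standard
error) with $N-1$ degrees of freedom. At each timepoint the comparison is
encoded as $+1$ (significantly higher average correlation in the case
group at two-sided $p < \alpha$, default $\alpha = 0.05$), $-1$
(significantly lower) or $0$; the per-complex tuple of codes in timepoint
order — the *quadruplet* for a four-timepoint design — localizes when in
the time course a complex is perturbed.

**Structural distance.** Two matrices can have equal averages yet very
different wiring. The second statistic is the normalized Euclidean
distance

$$ d = \sqrt{\frac{\sum_{i<j}(A_{ij}-B_{ij})^2}{N}}, $$

which is sensitive to entrywise re-organization. $d$ has no theoretical
maximum, so significance comes from a permutation-style null: for each
complex size $n$ and timepoint, `build_null()` draws 1000 random gene sets
of size $n$ from the measured gene universe, computes their case–control
distances, and summarizes them by mean $\langle x\rangle$ and standard
deviation $S$. An observed distance becomes $z = (d - \langle x\rangle)/S$,
declared significant one-sidedly at $z > 1.9$: a negative $z$ means the
complex is *more* similar across groups than a random gene set and is never
significant.

**Single-gene attribution.** The difference matrix $A - B$ localizes a
shift to individual genes: `rank_gene_decorrelation()` averages, per gene,
all difference entries involving it, and ranks genes ascending, so a
subunit that is strongly anti-correlated with the rest of its complex in
the case group only (an "anti-member", apparently dissociated from the
complex network) ranks first.

## Preprocessing

Microarrays carry several probes per gene. `score_probes()` runs a one-way
two-class ANOVA (case versus control, all timepoints pooled) per probe;
`select_best_probes()` keeps, per gene, the probe with the smallest p-value
(largest F, then lexicographically smallest probe id on ties — the order is
deterministic and invariant to row or column shuffles). Pooling across
timepoints is the simplest reading of "best discrimination between the two
classes" and gives the selection one consistent criterion; no absolute p
cutoff is applied, because the gene universe is subsequently restricted to
complex members anyway. Probes with zero within-group variance get $p = 1$
(flat control probes are common on real arrays and should lose, not error).
`map_complexes()` intersects each catalog entry with the measured genes and
keeps complexes with at least `min_size = 3` genes — below that a
correlation "structure" is a single pair. Reporting additionally restricts
to size > 3 (`report_min_size = 4`); keeping the analysis and reporting
filters distinct mirrors how such studies report only the larger complexes
while analyzing all of them.

Expression values are assumed to be already-normalized log ratios; no
normalization stage is included, and missing values are rejected at read
time because Pearson over incomplete pairs would silently change $N$.

## The synthetic-data generator

`simulate_dataset()` exists so every downstream stage is testable without
external data. Each planted complex is drawn, per (group, timepoint) cell,
from a zero-mean multivariate normal with an *equicorrelation* block: a
single target correlation $\rho$ per cell, which is exactly the quantity
the two statistics measure (an average level and a uniform shift). An
optional anti-member extension sets one gene's correlation to $-\rho_{anti}$
against all others, reproducing the single-dissociated-subunit pattern; the
implied matrix is checked numerically for positive semi-definiteness and
rejected otherwise (equicorrelation alone requires $\rho > -1/(n-1)$).
Background genes are independent Gaussian noise. Because all metrics are
correlation-based and location/scale free, Gaussian unit-variance marginals
lose no generality; dye effects, spatial artifacts and probe-sequence
behavior of real two-color arrays are deliberately out of scope, so passing
tests demonstrate statistical correctness of the machinery, not robustness
to array-specific artifacts.

Defaults mirror the motivating design: four timepoints, 15 samples per
(group, timepoint) cell, 500 background genes. `make_probe_level()` expands
a gene-level dataset into one true probe plus heavy-noise decoy probes per
gene, giving probe selection a planted right answer; an optional
`group_shift` adds a case-mean offset to chosen genes, since a pure
correlation structure carries no two-class mean signal for the ANOVA to
find. An anti-conservativeness caveat drives one generator convention: the
paired t treats the $N$ pairs as independent although pairs sharing a gene
are not, which is the published procedure and is implemented as such. On
equicorrelation-0 nulls the empirical type-I rate is close to nominal
(the dependence vanishes with the correlations), and the generator
therefore uses $\rho = 0$ as its null condition, both for type-I
calibration and at the non-differential timepoints of planted-effect
scenarios; at a shared nonzero $\rho$ the rate is visibly inflated
(roughly 2–3× nominal at $\rho = 0.1$), which users should keep in mind
when interpreting quadruplets of strongly co-expressed complexes.

## Numerical and design choices

- **Canonical order.** Genes within a complex are sorted lexicographically
  and upper-triangle entries stored in column-major pair order
  (1,2), (1,3), (2,3), …; every matrix, difference matrix and output table
  uses it, making runs bit-reproducible and matrices comparable entrywise.
- **z-score sign.** The z-score is the plain standardized residual
  $(d - \langle x\rangle)/S$; significance is one-sided above 1.9. Negative
  z-scores are reported (they say the complex moved *less* than random)
  but can never be significant.
- **Degenerate paired differences.** All-zero differences give $p = 1$
  (no change); identical nonzero differences have zero spread but a real
  shift and are treated as maximally significant, with a warning either
  way. The zero-spread test uses a relative tolerance
  ($N\,\mathrm{var} < 10^{-12}\sum D^2$) so constant differences are caught
  through floating-point dust.
- **Zero-variance genes.** A flat expression profile makes Pearson
  undefined; the affected complex is skipped with a logged reason rather
  than imputed. Random null draws that hit such genes are redrawn.
- **Null universe and seeding.** Random complexes are drawn from the full
  measured gene universe (the least biased reading of "randomly selected
  genes"); one null per (size, timepoint) serves all complexes of that
  size, with sub-seeds derived deterministically from the master seed so
  the whole pipeline is byte-identical under one seed.
- **Degenerate nulls.** If the null distances have zero spread (case and
  control literally identical), the pipeline reports z as NA — never
  significant — instead of aborting; `z_score()` itself refuses $S = 0$.

## Problem sizes used in the shipped checks

The test-suite simulations are sized to be decisive yet quick, as the
package's own choice of desk-scale experiments: formula oracles on 1000
random matrix pairs; null calibration with a 1000-draw null against 1000
held-out random complexes (size 8, 15 samples per cell); type-I rates over
500 null complexes of size 5; planted-effect recovery (case $\rho = 0.6$
versus control $\rho = 0.1$ at the first timepoint, size-8 complexes,
15 samples per cell) over 100 replicates, where the expected quadruplet is
recovered in well over 80% of replicates and the planted anti-member ranks
first in essentially all of them.

## Applying the pipeline to real array data

The on-disk route is four TSVs — expression matrix, sample metadata, probe
map, complex catalog (CORUM or two-column dialect) — through
`pipeline_config(paths = ...)` and `run_pipeline()`, or the `coexdyn`
command-line wrapper. For the motivating mouse study the expression data
are public (GEO Series GSE63617: 16,515 probes, 120 arrays) and CORUM is
freely downloadable; neither is bundled, because catalog releases and
identifier namespaces drift and the catalog must be an explicit, versioned
input. Reported real-data figures (e.g. which complexes pass $z > 1.9$ and
when) depend on the catalog release used, so cross-study comparisons should
be made cell-wise on the exported tables, not row-wise against a printed
table.

## Limitations

- The paired t over gene pairs ignores their dependence (see above); its
  codes are best read as a calibrated screen, not exact hypothesis tests.
- Pearson correlation captures linear co-expression only, and with 15
  samples per cell individual correlations carry substantial sampling
  noise; the statistics aggregate over pairs precisely to compensate.
- No multiple-testing correction is applied across complexes, matching the
  original procedure; with ~80 complexes and 4 timepoints a handful of
  nominally significant codes are expected by chance.
- The generator's equicorrelation blocks cannot represent arbitrary
  correlation topologies (hub structure, cliques); they span exactly the
  alternatives the two statistics are designed to detect.
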
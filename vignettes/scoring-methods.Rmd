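---
title: "Scoring de novo transcriptome assemblies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring de novo transcriptome assemblies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transeval)
```

## The problem

De novo transcriptome assemblers are evaluated with heterogeneous quality
metrics: re-mapping rates in percent, misassembly counts in the thousands,
likelihood-based scores that are large negative numbers, completeness
fractions. No single metric is decisive, their scales are incomparable, and
for some of them *smaller* is better. `transeval` turns a table of such raw
metric values — one value per (dataset, assembler, metric) — into
comparable scores, ranks the assemblers, and clusters their per-dataset
performance profiles.

## The scoring model

For each dataset $d_i$ and metric $m_j$, the raw values
$\mathbf{v}^{i,j} = (r^{i,j}_1, \dots, r^{i,j}_K)$ of the $K$ assemblers
are min–max normalized into $(0,1)$:

$$ n^{i,j}_k \;=\; \frac{r^{i,j}_k - \min \mathbf{v}^{i,j}}
                        {\max \mathbf{v}^{i,j} - \min \mathbf{v}^{i,j}} $$

for higher-is-better metrics, and the complement
$(\max \mathbf{v} - r_k)/(\max \mathbf{v} - \min \mathbf{v})$ for
lower-is-better metrics (misassemblies, mismatches per transcript,
duplication ratio, percentage of uncovered bases, ambiguous bases, missing
BUSCOs), so that 1 always marks the best assembler on that metric and 0 the
worst. The normalization is invariant to positive affine transformations of
the raw values — equivalently, z-scoring first and then rescaling into
$(0,1)$ gives identical output — which is what makes percent scales,
counts, and negative likelihood scores commensurable.

The **metric score** of assembler $a_k$ on dataset $d_i$ is the plain sum

$$ \mathrm{MS}(d_i, a_k) \;=\; \sum_j n^{i,j}_k , $$

with maximum equal to the number of applicable metrics, and the **overall
metric score** sums MS over datasets,

$$ \mathrm{OMS}(a_k) \;=\; \sum_i \mathrm{MS}(d_i, a_k), $$

except that datasets sharing a *replicate group* contribute the arithmetic
mean of their MS values once. The replicate rule exists because a set of
near-identical libraries (e.g. three time points of one infection
experiment, sequenced the same way) would otherwise count its systematic
assembly behavior several times.

Metrics are deliberately unweighted: weighting correlated metrics is an
arbitrary decision that the sum avoids; strongly redundant metrics should
instead be pruned from the registry.

### Applicability

The TransRate optimal score and the percentage of uncovered bases can only
be computed from paired-end reads. Applicability is therefore modeled as a
predicate on the dataset's library layout rather than as a hard-coded
dataset list: a single-end dataset is automatically scored on 18 of the 20
canonical metrics and its maximum MS shrinks to 18. User registries can
mark their own metrics `paired_end_only`.

### Where the metric directions come from

The registry ships a fixed direction per metric. The six inverted metrics
were fixed by recomputing both orientations of the min–max transform for
every row of the bundled reference evaluation (`table2_fixture()`) and
keeping the orientation that matches the published normalized values; the
test suite re-runs that reconstruction. Directions are user-overridable
through a registry file for metrics whose polarity is genuinely contested.

## Numerical choices and degenerate inputs

* **Degenerate metrics** (all assemblers identical, max = min): the ratio
  is undefined and the metric carries no ranking information. All
  assemblers receive the neutral value 0.5 (configurable to any value,
  e.g. 0), with a warning. Dropping the metric instead would silently
  change `max_possible` between datasets.
* **Missing cells** (one assembler lacks a value others have): the cell is
  excluded from the min/max so it cannot distort the scale. At summation
  time it contributes 0 under the default `"zero"` policy — an assembler
  that failed to produce a metric is treated as worst on it. The `"omit"`
  policy yields the same sum (omitting a term from a sum is adding zero)
  but records `max_possible` as the count of metrics actually present,
  which makes the shortfall explicit in reports.
* **Rounding**: all arithmetic is done in full double precision; 2-decimal
  rounding happens only at report-rendering time. The bundled reference
  fixture stores raw values at their printed precision, so recomputed
  normalized cells match the published ones only within a tolerance that
  combines output rounding (±0.005 per side) with propagation of the raw
  quantization through the min–max ratio (quantum divided by the metric's
  range); the tests compute that bound per metric.
* **Ties in ranking** are broken lexicographically by assembler id, making
  the ranking a deterministic total order.
* **Replicate means over incomplete groups** use the members whose MS is
  available.

## Clustering

The heatmap of MS profiles orders assemblers by agglomerative hierarchical
clustering of their per-dataset MS vectors. Distance and linkage are not
canonical choices anywhere; Euclidean distance with average linkage is
used as a conventional default, both configurable. Clustering is
display-only: it never feeds back into MS or OMS. When replicate groups
are present the clustering still uses the full per-dataset MS matrix
(before replicate averaging), since averaging columns only rescales
within-group distances without adding information.

## Derived metrics computed from primary data

Four metric families are computed by the package itself rather than
ingested from evaluator output:

* **Assembly statistics** — contig counts, contigs ≥ 1,000 nt, total
  length, ambiguous (`N`) bases, N50. N50 is the length at which the
  cumulative sum of descending contig lengths first reaches half the
  total.
* **ExN50** — the N50 restricted to the most highly expressed transcripts
  accounting for a fraction (0.9 by convention: Ex90N50) of the total
  normalized expression. Expression is renormalized to proportions
  internally, so the statistic is invariant to the unit the abundance
  estimator reports (TPM versus estimated counts — deliberately left
  unpinned). Expression ties are broken by length (descending) then id
  (ascending) for determinism; the transcript that crosses the threshold
  is included.
* **Full-length protein-coding transcripts** — from a 12-column tabular
  protein alignment: segments of one (transcript, protein) pair are merged
  by subject-coordinate interval union (1-based inclusive, reversed
  coordinates swapped); coverage is union length over protein length,
  capped at 1; per protein the maximum over transcripts is taken —
  segments of *different* transcripts are never merged — and proteins
  with coverage strictly above 0.9 are counted. The interval union is a
  simplification of colinearity-aware chaining used by some toolkits: it
  ignores segment order and query-side consistency, which can only
  overestimate coverage, and it is exact whenever the alignments are
  colinear. Both the threshold and its strictness are configurable; an
  e-value pre-filter (1e-20) is available and applied by default only in
  the command-line `fulllength` step.
* **BUSCO summaries** — the four completeness categories are reduced to
  `complete = single_copy + duplicated` (so isoform-rich assemblies are
  not penalized for duplicated orthologs) and `missing`. When a
  short-summary file carries only the percentage line, S, D, and F counts
  are recovered by rounding and the missing count is derived as the
  remainder so the category partition holds exactly.

## The synthetic-data generators

Every pipeline stage is testable without external downloads because the
generators plant their ground truth:

* `gen_metric_matrix()` emulates the structure the scoring model assumes —
  a latent strictly ordered assembler quality observed through
  direction-heterogeneous metrics. Each (dataset, metric) pair draws its
  own scale and offset, and the observation is a monotone transform of
  quality plus Gaussian noise. The default emulates the scale of a full
  benchmark study: 10 assemblers, 9 datasets, 20 metrics, qualities evenly
  spaced on $[0.1, 1]$ with noise sd 0.05 (small relative to the 0.1
  quality gap, i.e. metrics that are informative but not noiseless). With
  `noise_sd = 0` the planted ranking must be recovered exactly and the
  best assembler attains the maximal MS everywhere; these are regression
  tests, not tuning targets.
* `gen_transcripts()` plants an expression prefix of equal-length
  transcripts whose share crosses the ExN50 fraction, so the expected
  statistic equals the planted length by construction.
* `gen_alignments()` realizes an exact covered region `[1, K]` per protein
  as overlapping segments, so realized coverage is `K / length` exactly
  and the full-length count is known. Protein lengths default to
  multiples of 10 so round-number coverages (e.g. exactly 0.9) sit
  precisely on the strict-threshold boundary.
* `gen_fasta()` plants contig lengths and `N` positions for the assembly
  statistics.

What the generators do *not* emulate: correlated metrics (real evaluator
metrics are strongly correlated), heavy-tailed or discrete metric noise,
assembler-by-dataset interactions (a tool that excels only on small
genomes), and real sequence content. Passing the planted-recovery tests
therefore shows the aggregation arithmetic is correct, not that 20 real
metrics identify the best assembler on real data.

Seeding: each generator derives a private RNG stream from its `seed`
argument via `withr::with_seed()`, so generators compose in any order,
never disturb the caller's RNG, and are pure functions of
(parameters, seed).

## Problem sizes

The bundled reference evaluation is 10 assemblers × 20 metrics on one
dataset (200 cells). Property suites run on randomized instances of up to
10 assemblers × 9 datasets × 20 metrics and on small (≤ 4 × 3) instances
compared against brute-force oracles at 1e-12; these sizes exercise every
code path while keeping the whole suite interactive.

## Known limitations

* The framework ingests nine of its canonical metrics from external
  evaluators (mapping, rnaQUAST, TransRate, DETONATE scores); it does not
  re-implement them, and garbage raw values are normalized as faithfully
  as good ones — `validate_matrix()` checks structure, not plausibility.
* Min–max normalization is sensitive to a single outlier assembler, which
  compresses everyone else's scores toward the other end (visible in the
  bundled fixture's misassembly row, where one extreme value pushes all
  other assemblers to ≥ 0.97).
* No significance testing of rank differences: an OMS gap of 0.1 is
  reported as an ordering, not as evidence.
* The interval-union coverage can overestimate relative to
  colinearity-aware segment chaining when a transcript hits a protein in
  conflicting, non-colinear segments.
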
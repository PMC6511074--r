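# transeval

Normalized scoring, ranking, and clustering of de novo transcriptome
assemblies — for anyone who has run several assemblers (Trinity, SPAdes,
Trans-ABySS, ...) on one or more RNA-Seq datasets and needs a defensible
way to pick a winner from a pile of incommensurable quality metrics.

## What it computes

External evaluators emit metrics on wildly different scales: re-mapping
rates in percent, misassembly counts, duplication ratios, negative
likelihood-based scores, BUSCO completeness counts. For each dataset
*d<sub>i</sub>* and metric *m<sub>j</sub>*, `transeval` min–max normalizes
the vector of raw values across assemblers into (0,1),

> n<sub>k</sub> = (r<sub>k</sub> − min **v**) / (max **v** − min **v**),

inverting the six lower-is-better metrics (misassemblies, mismatches per
transcript, duplication ratio, uncovered bases, ambiguous bases, missing
BUSCOs) so 1 always marks the best assembler. Per dataset, the **metric
score** MS(d<sub>i</sub>, a<sub>k</sub>) = Σ<sub>j</sub> n<sub>k</sub> sums
the normalized scores (maximum = number of applicable metrics: 20 for
paired-end data, 18 for single-end, where two TransRate metrics are
unavailable). The **overall metric score** OMS(a<sub>k</sub>) sums MS over
datasets, with datasets in a replicate group contributing their mean MS
once. Assemblers are ranked by OMS and hierarchically clustered on their
MS profiles for the summary heatmap.

The package also computes the derived metrics such evaluations consume,
directly from primary data:

* contig statistics: counts, contigs ≥ 1,000 nt, ambiguous bases, N50;
* **Ex90N50** — N50 restricted to the most highly expressed transcripts
  covering 90 % of total normalized expression;
* full-length protein-coding transcript counts from 12-column tabular
  protein alignments (per-transcript interval-union coverage > 90 %);
* BUSCO completeness summaries (complete = single-copy + duplicated).

Synthetic-data generators with planted ground truth (quality orderings,
ExN50 prefixes, coverage profiles, FASTA statistics) make every stage
testable offline.

## Worked example

The package bundles a complete reference evaluation — ten assemblers by
twenty metrics on a strand-specific paired-end human RNA-Seq library —
as `table2_fixture()`:

```r
library(transeval)

fx  <- table2_fixture()
res <- score_assemblies(fx$raw, fx$datasets)
res
#> Assembly scoring over 1 dataset(s) and 10 assembler(s)
#>
#> Ranking by overall metric score:
#> # A tibble: 10 × 3
#>     rank assembler          oms
#>    <int> <chr>            <dbl>
#>  1     1 Trans-ABySS      14.2
#>  2     2 Trinity          12.4
#>  3     3 SPAdes-rna       12.0
#>  4     4 SOAPdenovo-Trans 11.9
#>  5     5 SPAdes-sc        11.5
#>  6     6 Bridger          11.2
#>  7     7 Shannon          10.3
#>  8     8 IDBA-Tran         8.63
#>  9     9 BinPacker         6.60
#> 10    10 Oases             6.32
```

With a single dataset, OMS equals MS. Trans-ABySS tops this library with
an MS of 14.2 of a possible 20 — it wins or nearly wins reference
coverage, 95 %-assembled isoforms, full-length transcripts, and both
DETONATE F1 metrics — while Trinity's 12.4/20 reflects strong completeness
scores pulled down by a high duplication ratio. `res$normalized` holds the
per-cell (0,1) scores, `res$ms` the per-dataset sums with `max_possible`,
and `plot_ms_heatmap(res$ms, res$oms)` draws the cluster-ordered heatmap.

The same pipeline runs from the shell via the bundled script
(`inst/scripts/transeval`), whose subcommands `score`, `normalize`,
`stats`, `exn50`, `fulllength`, `busco`, and `simulate` emit and consume
long-format TSV rows (`dataset assembler metric value`), so derived
metrics can be computed per assembly, concatenated, and scored in two
steps.

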
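Package: transeval
Title: Normalized Scoring and Ranking of De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates and ranks de novo transcriptome assemblers from
    heterogeneous quality metrics. Raw per-assembler metric values (mapping
    rates, rnaQUAST statistics, TransRate and DETONATE scores, BUSCO
    completeness, and others) are min-max normalized into (0,1) scores with
    metric-specific directionality, summed into per-dataset metric scores
    (MS) and replicate-aware overall metric scores (OMS), and the assemblers
    are ranked and hierarchically clustered on their MS profiles. Also
    computes, from primary data, the derived metrics such pipelines consume:
    contig statistics (N50, ambiguous bases, length thresholds),
    expression-informed ExN50, full-length protein-coding transcript counts
    from tabular protein alignments, and BUSCO completeness summaries.
    Includes synthetic-data generators with planted ground truth for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    ggplot2,
    jsonlite,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
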
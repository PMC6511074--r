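#' Score assemblies end to end
#'
#' Runs the full scoring pipeline on a raw metric matrix: validation,
#' per-(dataset, metric) min-max normalization with metric directionality,
#' per-dataset metric scores (MS), replicate-aware overall metric scores
#' (OMS), ranking, and (optionally) hierarchical clustering of the
#' assembler MS profiles.
#'
#' Validation problems of type `unknown_metric` or `unknown_dataset` are
#' fatal; all other findings (non-applicable cells, non-normalizable or
#' degenerate metrics, missing cells) are collected as warnings into the
#' result and do not fail the run.
#'
#' @param raw Long-format raw metric matrix (see [read_metric_matrix()]).
#' @param datasets Dataset sheet tibble (see [read_dataset_sheet()]).
#' @param registry Metric registry; defaults to [builtin_registry()].
#' @param missing Missing-cell policy for [metric_scores()].
#' @param degenerate Degenerate-normalization value for
#'   [normalize_vector()].
#' @param cluster Cluster MS profiles when at least two assemblers are
#'   present (default `TRUE`).
#' @param distance,linkage Clustering parameters for [cluster_profiles()].
#' @return An object of class `transeval_result`: a list with `normalized`,
#'   `ms`, `oms`, `ranking`, `clustering` (or `NULL`), `warnings`
#'   (character), plus the inputs `registry` and `datasets`.
#' @export
score_assemblies <- function(raw, datasets, registry = builtin_registry(),
                             missing = c("zero", "omit"), degenerate = 0.5,
                             cluster = TRUE, distance = "euclidean",
                             linkage = "average") {
  missing <- match.arg(missing)
  raw <- tibble::as_tibble(raw)
  if (nrow(raw) == 0) {
    stop("empty metric matrix", call. = FALSE)
  }
  datasets <- validate_datasets(datasets)
  report <- validate_matrix(raw, registry, datasets)
  fatal <- report$problems[report$problems$type %in%
                             c("unknown_metric", "unknown_dataset"), ]
  if (nrow(fatal) > 0) {
    stop("metric matrix failed validation:\n  ",
         paste(fatal$message, collapse = "\n  "), call. = FALSE)
  }
  warnings_log <- report$problems$message

  normalized <- withCallingHandlers(
    normalize_matrix(raw, registry, datasets, degenerate = degenerate),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  ms <- metric_scores(normalized, registry, datasets, missing = missing)
  oms <- overall_metric_score(ms, datasets)
  ranking <- rank_assemblers(oms)
  clustering <- NULL
  if (cluster && length(unique(ms$assembler)) >= 2) {
    clustering <- tryCatch(
      cluster_profiles(ms, distance = distance, linkage = linkage),
      error = function(e) {
        warnings_log <<- c(warnings_log,
                           paste("clustering skipped:", conditionMessage(e)))
        NULL
      })
  }
  structure(list(normalized = normalized, ms = ms, oms = oms,
                 ranking = ranking, clustering = clustering,
                 warnings = warnings_log, registry = registry,
                 datasets = datasets),
            class = "transeval_result")
}

#' @export
print.transeval_result <- function(x, ...) {
  cat("Assembly scoring over", length(unique(x$ms$dataset)), "dataset(s) and",
      length(unique(x$ms$assembler)), "assembler(s)\n\n")
  cat("Ranking by overall metric score:\n")
  print(x$ranking, n = Inf)
  if (length(x$warnings) > 0) {
    cat("\n", length(x$warnings), " warning(s); see $warnings\n", sep = "")
  }
  invisible(x)
}

#' Write / read a scoring report
#'
#' `write_score_report()` serializes a [score_assemblies()] result into an
#' output directory: `normalized_matrix.tsv` (wide; one row per
#' dataset-metric, one column per assembler), `ms.tsv`, `oms.tsv`,
#' `ranking.tsv`, and `report.json` bundling all tables plus the ranking
#' and accumulated warnings at full floating precision. TSV numbers are
#' written at full precision too, so re-reading reproduces MS and OMS
#' bit-identically (`read_score_report()`).
#'
#' @param result A `transeval_result` from [score_assemblies()].
#' @param dir Output directory (created if needed).
#' @param heatmap Also render `ms_heatmap.svg` via [plot_ms_heatmap()].
#' @return `dir`, invisibly.
#' @export
write_score_report <- function(result, dir, heatmap = FALSE) {
  stopifnot(inherits(result, "transeval_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # doubles go out at 17 significant digits so TSV rereads are bit-exact
  exact <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else col
    })
    df
  }
  wide <- tidyr::pivot_wider(result$normalized, names_from = "assembler",
                             values_from = "score")
  readr::write_tsv(exact(wide), file.path(dir, "normalized_matrix.tsv"))
  readr::write_tsv(exact(result$ms), file.path(dir, "ms.tsv"))
  readr::write_tsv(exact(result$oms), file.path(dir, "oms.tsv"))
  readr::write_tsv(exact(result$ranking), file.path(dir, "ranking.tsv"))
  bundle <- list(
    normalized = result$normalized,
    ms = result$ms,
    oms = result$oms,
    ranking = result$ranking,
    warnings = result$warnings
  )
  # digits = I(17): shortest-exact is not available, 17 significant digits
  # guarantee doubles survive the JSON round trip bit-identically
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       dataframe = "columns", digits = I(17), na = "null")
  if (heatmap) {
    p <- plot_ms_heatmap(result$ms, result$oms,
                         cluster = !is.null(result$clustering))
    ggplot2::ggsave(file.path(dir, "ms_heatmap.svg"), p,
                    width = 7, height = 5)
  }
  invisible(dir)
}

#' @rdname write_score_report
#' @return `read_score_report()` returns a list with tibbles `normalized`,
#'   `ms`, `oms`, `ranking` and the `warnings` character vector, rebuilt
#'   from `report.json`.
#' @export
read_score_report <- function(dir) {
  bundle <- jsonlite::read_json(file.path(dir, "report.json"),
                                simplifyVector = TRUE)
  list(normalized = tibble::as_tibble(bundle$normalized),
       ms = tibble::as_tibble(bundle$ms),
       oms = tibble::as_tibble(bundle$oms),
       ranking = tibble::as_tibble(bundle$ranking),
       warnings = as.character(bundle$warnings))
}

#' Emit derived-metric rows in metric-matrix format
#'
#' Wraps a computed derived-metric value as one long-format row
#' (`dataset assembler metric value`) append-compatible with
#' [read_metric_matrix()], enabling the two-step pipeline: compute derived
#' metrics per assembly, concatenate the rows, then score.
#'
#' @param dataset,assembler Ids the value belongs to.
#' @param metric Registry metric id.
#' @param value The computed value.
#' @return A one-row tibble.
#' @export
metric_row <- function(dataset, assembler, metric, value) {
  tibble::tibble(dataset = dataset, assembler = assembler, metric = metric,
                 value = as.numeric(value))
}
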
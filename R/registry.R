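#' The canonical 20-metric registry
#'
#' Returns the built-in registry of the 20 assembly-evaluation metrics the
#' scoring pipeline is designed around: the HISAT2 re-mapping rate, seven
#' rnaQUAST statistics, the expression-informed Ex90N50, the number of
#' full-length protein-coding transcripts, five TransRate metrics, four
#' DETONATE scores, and the two BUSCO completeness summaries.
#'
#' Each metric carries a `direction`: for `higher_better` metrics larger raw
#' values indicate better assemblies, while `lower_better` metrics
#' (misassemblies, mismatches per transcript, duplication ratio, percentage
#' of uncovered bases, ambiguous bases, missing BUSCOs) are inverted during
#' normalization. The TransRate optimal score and the percentage of uncovered
#' bases can only be computed from paired-end libraries and are marked
#' `paired_end_only`; all other metrics apply to every dataset.
#'
#' @return A tibble with columns `metric_id`, `label`, `source_tool`,
#'   `direction`, `applicability`, and `ordinal` (canonical ordering 1..20).
#' @seealso [applicable_metrics()], [read_registry()]
#' @export
#' @examples
#' reg <- builtin_registry()
#' table(reg$direction)
builtin_registry <- function() {
  tibble::tribble(
    ~metric_id, ~label, ~source_tool, ~direction, ~applicability, ~ordinal,
    "overall_mapping_rate", "Overall mapping rate", "HISAT2", "higher_better", "all", 1L,
    "transcripts_ge_1000", "Transcripts >= 1,000 nt", "rnaQUAST", "higher_better", "all", 2L,
    "misassemblies", "Misassemblies", "rnaQUAST", "lower_better", "all", 3L,
    "mismatches_per_transcript", "Mismatches per transcript", "rnaQUAST", "lower_better", "all", 4L,
    "avg_alignment_length", "Average alignment length", "rnaQUAST", "higher_better", "all", 5L,
    "isoforms_95pct", "95%-assembled isoforms", "rnaQUAST", "higher_better", "all", 6L,
    "duplication_ratio", "Duplication ratio", "rnaQUAST", "lower_better", "all", 7L,
    "ex90n50", "Ex90N50", "Trinity/Salmon", "higher_better", "all", 8L,
    "full_length_transcripts", "Full-length transcripts", "Trinity/Blastx", "higher_better", "all", 9L,
    "reference_coverage", "Reference coverage", "TransRate", "higher_better", "all", 10L,
    "mean_orf_percentage", "Mean ORF percentage", "TransRate", "higher_better", "all", 11L,
    "transrate_optimal_score", "Optimal score", "TransRate", "higher_better", "paired_end_only", 12L,
    "pct_bases_uncovered", "Percentage bases uncovered", "TransRate", "lower_better", "paired_end_only", 13L,
    "ambiguous_bases", "Number of ambiguous bases", "TransRate", "lower_better", "all", 14L,
    "nucleotide_f1", "Nucleotide F1", "DETONATE", "higher_better", "all", 15L,
    "contig_f1", "Contig F1", "DETONATE", "higher_better", "all", 16L,
    "kc_score", "KC score", "DETONATE", "higher_better", "all", 17L,
    "rsem_eval", "RSEM-EVAL", "DETONATE", "higher_better", "all", 18L,
    "complete_buscos", "Complete BUSCOs", "BUSCO", "higher_better", "all", 19L,
    "missing_buscos", "Missing BUSCOs", "BUSCO", "lower_better", "all", 20L
  )
}

registry_directions <- c("higher_better", "lower_better")
registry_applicabilities <- c("all", "paired_end_only")
dataset_layouts <- c("single_end", "paired_end")

#' Validate a metric registry
#'
#' Checks the structural invariants of a registry table: required columns,
#' unique metric ids, and valid `direction`/`applicability` levels.
#'
#' @param registry A data frame as returned by [builtin_registry()] or
#'   [read_registry()].
#' @return The registry, invisibly, as a tibble (for chaining). Errors on any
#'   violated invariant.
#' @export
validate_registry <- function(registry) {
  required <- c("metric_id", "label", "source_tool", "direction",
                "applicability", "ordinal")
  missing_cols <- setdiff(required, names(registry))
  if (length(missing_cols) > 0) {
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  registry <- tibble::as_tibble(registry)
  if (anyDuplicated(registry$metric_id)) {
    dup <- unique(registry$metric_id[duplicated(registry$metric_id)])
    stop("duplicate metric_id in registry: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!all(registry$direction %in% registry_directions)) {
    stop("registry direction must be one of: ",
         paste(registry_directions, collapse = ", "), call. = FALSE)
  }
  if (!all(registry$applicability %in% registry_applicabilities)) {
    stop("registry applicability must be one of: ",
         paste(registry_applicabilities, collapse = ", "), call. = FALSE)
  }
  invisible(registry)
}

#' Metrics applicable to a dataset
#'
#' Metrics marked `paired_end_only` (the TransRate optimal score and the
#' percentage of uncovered bases in the canonical registry) are only
#' reported for paired-end libraries, so a single-end dataset is scored on
#' 18 rather than 20 metrics and its maximum achievable metric score shrinks
#' accordingly.
#'
#' @param dataset Either a dataset layout string (`"single_end"` or
#'   `"paired_end"`) or a one-row data frame / list with a `layout` field,
#'   e.g. one row of a dataset sheet from [read_dataset_sheet()].
#' @param registry A metric registry; defaults to [builtin_registry()].
#' @return Character vector of applicable `metric_id`s in ordinal order.
#' @export
#' @examples
#' length(applicable_metrics("paired_end")) # 20
#' length(applicable_metrics("single_end")) # 18
applicable_metrics <- function(dataset, registry = builtin_registry()) {
  layout <- dataset_layout(dataset)
  if (nrow(registry) == 0) {
    return(character(0))
  }
  validate_registry(registry)
  registry <- dplyr::arrange(registry, .data$ordinal)
  keep <- registry$applicability == "all" |
    (registry$applicability == "paired_end_only" & layout == "paired_end")
  registry$metric_id[keep]
}

dataset_layout <- function(dataset) {
  layout <- if (is.character(dataset) && length(dataset) == 1 &&
                dataset %in% dataset_layouts) {
    dataset
  } else if (!is.null(dataset$layout)) {
    dataset$layout[[1]]
  } else {
    stop("`dataset` must be a layout string or have a `layout` field",
         call. = FALSE)
  }
  match.arg(layout, dataset_layouts)
}

#' Read or write a metric registry file
#'
#' A registry file is either a TSV with header
#' `metric_id label source_tool direction applicability ordinal`, or a YAML
#' file whose top level is a list of entries with the same keys. The format
#' is chosen by file extension (`.yml`/`.yaml` versus anything else).
#'
#' @param path Path to the registry file.
#' @return A validated registry tibble, ordered by `ordinal`.
#' @export
read_registry <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
    registry <- dplyr::bind_rows(lapply(entries, tibble::as_tibble))
  } else {
    registry <- readr::read_tsv(path, col_types = readr::cols(
      metric_id = readr::col_character(),
      label = readr::col_character(),
      source_tool = readr::col_character(),
      direction = readr::col_character(),
      applicability = readr::col_character(),
      ordinal = readr::col_integer()
    ))
  }
  registry$ordinal <- as.integer(registry$ordinal)
  validate_registry(registry)
  dplyr::arrange(tibble::as_tibble(registry), .data$ordinal)
}

#' @rdname read_registry
#' @param registry A registry tibble to serialize.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- lapply(seq_len(nrow(registry)), function(i) as.list(registry[i, ]))
    yaml::write_yaml(entries, path)
  } else {
    readr::write_tsv(registry, path)
  }
  invisible(path)
}

#' Read a dataset sheet
#'
#' A dataset sheet is a TSV with header
#' `dataset_id layout strand_specific replicate_group` describing each
#' RNA-Seq dataset that was assembled: its library layout (`single_end` or
#' `paired_end`), strand specificity, and an optional replicate-group label.
#' Datasets sharing a replicate group (for example several time points of
#' the same infection experiment) contribute the mean of their per-dataset
#' metric scores to the overall metric score instead of each counting once,
#' so near-identical experiments are not over-weighted.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per dataset; `replicate_group` is `NA` for
#'   ungrouped datasets.
#' @export
read_dataset_sheet <- function(path) {
  ds <- readr::read_tsv(path, col_types = readr::cols(
    dataset_id = readr::col_character(),
    layout = readr::col_character(),
    strand_specific = readr::col_logical(),
    replicate_group = readr::col_character()
  ))
  ds$replicate_group[!is.na(ds$replicate_group) & ds$replicate_group == ""] <- NA_character_
  validate_datasets(ds)
}

#' @rdname read_dataset_sheet
#' @param datasets A dataset tibble to serialize.
#' @export
write_dataset_sheet <- function(datasets, path) {
  validate_datasets(datasets)
  readr::write_tsv(datasets, path)
  invisible(path)
}

#' Validate a dataset sheet
#'
#' Checks unique dataset ids and valid layouts, and warns on replicate
#' groups containing a single dataset (a group is only meaningful with two
#' or more members).
#'
#' @param datasets A data frame with columns `dataset_id`, `layout`, and
#'   optionally `strand_specific` and `replicate_group`.
#' @return The dataset tibble (invisibly unchanged apart from class).
#' @export
validate_datasets <- function(datasets) {
  datasets <- tibble::as_tibble(datasets)
  if (!all(c("dataset_id", "layout") %in% names(datasets))) {
    stop("dataset sheet needs `dataset_id` and `layout` columns", call. = FALSE)
  }
  if (anyDuplicated(datasets$dataset_id)) {
    stop("duplicate dataset_id in dataset sheet", call. = FALSE)
  }
  if (!all(datasets$layout %in% dataset_layouts)) {
    stop("dataset layout must be one of: ",
         paste(dataset_layouts, collapse = ", "), call. = FALSE)
  }
  if (!"replicate_group" %in% names(datasets)) {
    datasets$replicate_group <- NA_character_
  }
  grp <- table(datasets$replicate_group[!is.na(datasets$replicate_group)])
  singletons <- names(grp)[grp < 2]
  if (length(singletons) > 0) {
    warning("replicate group(s) with a single member: ",
            paste(singletons, collapse = ", "), call. = FALSE)
  }
  datasets
}
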
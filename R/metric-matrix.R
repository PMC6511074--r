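# Raw metric matrices travel as long-format tibbles with columns
# dataset / assembler / metric / value; a missing cell is an NA value.

#' Read a long-format raw metric matrix
#'
#' The canonical interchange format is a TSV with header
#' `dataset assembler metric value`, one row per (dataset, assembler,
#' metric) cell. Values are real numbers; `NA` or an empty field marks a
#' missing cell (an assembler for which a tool produced no value) and is
#' reported with a warning. Duplicate cells are an error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `dataset`, `assembler`, `metric` (character)
#'   and `value` (double, `NA` = missing).
#' @export
read_metric_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("dataset", "assembler", "metric", "value"))) {
    stop("metric matrix header must be: dataset assembler metric value",
         call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    dataset = readr::col_character(),
    assembler = readr::col_character(),
    metric = readr::col_character(),
    value = readr::col_character()
  ))
  if (!identical(names(raw), c("dataset", "assembler", "metric", "value"))) {
    stop("metric matrix header must be: dataset assembler metric value",
         call. = FALSE)
  }
  missing_mask <- is.na(raw$value) | raw$value %in% c("", "NA", "na", "NaN")
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- !missing_mask & is.na(value)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("unparsable value %s at (%s, %s, %s)", dQuote(raw$value[i]),
                 raw$dataset[i], raw$assembler[i], raw$metric[i]),
         call. = FALSE)
  }
  raw$value <- value
  if (any(missing_mask)) {
    warning(sum(missing_mask), " missing cell(s) in ", path, call. = FALSE)
  }
  check_unique_cells(raw)
  raw
}

#' @rdname read_metric_matrix
#' @param matrix A long-format metric matrix tibble to serialize.
#' @export
write_metric_matrix <- function(matrix, path) {
  readr::write_tsv(matrix, path)
  invisible(path)
}

check_unique_cells <- function(matrix) {
  key <- paste(matrix$dataset, matrix$assembler, matrix$metric, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(sprintf("duplicate cell for (%s, %s, %s)", matrix$dataset[i],
                 matrix$assembler[i], matrix$metric[i]), call. = FALSE)
  }
  invisible(matrix)
}

#' Validate a raw metric matrix against a registry and dataset sheet
#'
#' Produces a report (never an error, never a mutation) listing:
#' unknown metric ids, unknown dataset ids, values present for metrics not
#' applicable to their dataset's layout, and (dataset, metric) pairs with
#' fewer than two non-missing values, which cannot be min-max normalized.
#' Per-dataset coverage counts (cells present versus the full
#' assemblers-by-applicable-metrics grid) are attached.
#'
#' @param matrix Long-format raw metric matrix.
#' @param registry Metric registry; defaults to [builtin_registry()].
#' @param datasets Dataset sheet tibble (see [read_dataset_sheet()]).
#' @return An object of class `transeval_validation`: a list with `problems`
#'   (tibble: `type`, `dataset`, `assembler`, `metric`, `message`),
#'   `coverage` (tibble per dataset), and `clean` (logical).
#' @export
validate_matrix <- function(matrix, registry = builtin_registry(), datasets) {
  matrix <- tibble::as_tibble(matrix)
  datasets <- validate_datasets(datasets)
  check_unique_cells(matrix)
  problems <- list()
  note <- function(type, dataset = NA, assembler = NA, metric = NA, message) {
    tibble::tibble(type = type, dataset = as.character(dataset),
                   assembler = as.character(assembler),
                   metric = as.character(metric), message = message)
  }

  unknown_m <- setdiff(unique(matrix$metric), registry$metric_id)
  for (m in unknown_m) {
    problems <- c(problems, list(note("unknown_metric", metric = m,
      message = sprintf("metric '%s' is not in the registry", m))))
  }
  unknown_d <- setdiff(unique(matrix$dataset), datasets$dataset_id)
  for (d in unknown_d) {
    problems <- c(problems, list(note("unknown_dataset", dataset = d,
      message = sprintf("dataset '%s' is not in the dataset sheet", d))))
  }

  known <- matrix[matrix$metric %in% registry$metric_id &
                    matrix$dataset %in% datasets$dataset_id, ]
  for (d in unique(known$dataset)) {
    app <- applicable_metrics(datasets[datasets$dataset_id == d, ], registry)
    sub <- known[known$dataset == d, ]
    inapp <- sub[!sub$metric %in% app & !is.na(sub$value), ]
    for (i in seq_len(nrow(inapp))) {
      problems <- c(problems, list(note("not_applicable", dataset = d,
        assembler = inapp$assembler[i], metric = inapp$metric[i],
        message = sprintf("metric '%s' is not applicable to %s dataset '%s'",
                          inapp$metric[i],
                          datasets$layout[datasets$dataset_id == d], d))))
    }
    per_metric <- dplyr::summarise(
      dplyr::group_by(sub[sub$metric %in% app, ], .data$metric),
      n_values = sum(!is.na(.data$value)), .groups = "drop")
    weak <- per_metric$metric[per_metric$n_values < 2]
    for (m in weak) {
      problems <- c(problems, list(note("non_normalizable", dataset = d,
        metric = m,
        message = sprintf(
          "metric '%s' has <2 non-missing values in dataset '%s'", m, d))))
    }
  }

  coverage <- dplyr::bind_rows(lapply(datasets$dataset_id, function(d) {
    app <- applicable_metrics(datasets[datasets$dataset_id == d, ], registry)
    sub <- known[known$dataset == d, ]
    tibble::tibble(
      dataset = d,
      n_assemblers = length(unique(sub$assembler)),
      n_applicable_metrics = length(app),
      n_cells_expected = length(unique(sub$assembler)) * length(app),
      n_cells_present = sum(!is.na(sub$value) & sub$metric %in% app)
    )
  }))

  problems <- if (length(problems) == 0) {
    tibble::tibble(type = character(), dataset = character(),
                   assembler = character(), metric = character(),
                   message = character())
  } else {
    dplyr::bind_rows(problems)
  }
  structure(list(problems = problems, coverage = coverage,
                 clean = nrow(problems) == 0),
            class = "transeval_validation")
}

#' @export
print.transeval_validation <- function(x, ...) {
  if (x$clean) {
    cat("Metric matrix validation: clean\n")
  } else {
    cat("Metric matrix validation:", nrow(x$problems), "problem(s)\n")
    print(x$problems, n = Inf)
  }
  cat("\nPer-dataset coverage:\n")
  print(x$coverage)
  invisible(x)
}
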
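#' Min-max normalize one metric vector across assemblers
#'
#' Rescales the raw values of a single metric, observed for several
#' assemblers on one dataset, to the interval (0, 1):
#' `(v - min) / (max - min)` for `higher_better` metrics and
#' `(max - v) / (max - min)` for `lower_better` metrics, so that 1 always
#' marks the best assembler and 0 the worst. The result is identical to a
#' z-score transformation followed by rescaling into (0, 1), and is
#' invariant to any positive affine transformation of the input.
#'
#' Missing values are excluded from the min/max and propagate as `NA`. If
#' all non-missing values coincide (max equals min) the metric carries no
#' ranking information and every non-missing entry receives the neutral
#' value `degenerate` (0.5 by default) with a warning.
#'
#' @param values Numeric vector of raw metric values; `NA` = missing.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param degenerate Value assigned to all entries when max equals min.
#' @return Numeric vector of the same length with non-missing entries in
#'   \[0, 1\].
#' @export
#' @examples
#' normalize_vector(c(77.0, 49.1, 95.7, 34.3), "higher_better")
#' normalize_vector(c(3378, 216127, 279), "lower_better")
normalize_vector <- function(values,
                             direction = c("higher_better", "lower_better"),
                             degenerate = 0.5) {
  direction <- match.arg(direction)
  if (!is.numeric(values)) {
    stop("`values` must be numeric", call. = FALSE)
  }
  obs <- values[!is.na(values)]
  if (length(obs) == 0) {
    stop("cannot normalize an all-missing metric vector", call. = FALSE)
  }
  lo <- min(obs)
  hi <- max(obs)
  if (hi == lo) {
    warning("degenerate metric vector (max == min); assigning ", degenerate,
            " to all assemblers", call. = FALSE)
    out <- ifelse(is.na(values), NA_real_, degenerate)
    return(out)
  }
  out <- if (direction == "higher_better") {
    (values - lo) / (hi - lo)
  } else {
    (hi - values) / (hi - lo)
  }
  out
}

#' Normalize a raw metric matrix
#'
#' Applies [normalize_vector()] independently to every (dataset, metric)
#' vector of raw values across assemblers, using each metric's registered
#' direction and restricting each dataset to its applicable metrics (so a
#' single-end dataset never yields rows for paired-end-only metrics).
#'
#' Cells for metrics absent from the registry are an error; cells for
#' non-applicable metrics are dropped with a warning. A (dataset, metric)
#' vector with no non-missing values raises an error naming the pair.
#'
#' @param raw Long-format raw metric matrix (`dataset`, `assembler`,
#'   `metric`, `value`).
#' @param registry Metric registry; defaults to [builtin_registry()].
#' @param datasets Dataset sheet tibble.
#' @param degenerate Passed to [normalize_vector()].
#' @return A long-format tibble `dataset`, `assembler`, `metric`, `score`
#'   with non-missing scores in \[0, 1\].
#' @export
normalize_matrix <- function(raw, registry = builtin_registry(), datasets,
                             degenerate = 0.5) {
  raw <- tibble::as_tibble(raw)
  datasets <- validate_datasets(datasets)
  validate_registry(registry)
  check_unique_cells(raw)
  if (nrow(raw) == 0 || length(unique(raw$assembler)) == 0) {
    stop("empty metric matrix: nothing to normalize", call. = FALSE)
  }
  unknown <- setdiff(unique(raw$metric), registry$metric_id)
  if (length(unknown) > 0) {
    stop("metric(s) not in registry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unknown_d <- setdiff(unique(raw$dataset), datasets$dataset_id)
  if (length(unknown_d) > 0) {
    stop("dataset(s) not in dataset sheet: ",
         paste(unknown_d, collapse = ", "), call. = FALSE)
  }

  pieces <- lapply(unique(raw$dataset), function(d) {
    app <- applicable_metrics(datasets[datasets$dataset_id == d, ], registry)
    sub <- raw[raw$dataset == d, ]
    dropped <- setdiff(unique(sub$metric), app)
    if (length(dropped) > 0) {
      warning(sprintf("dropping non-applicable metric(s) for dataset '%s': %s",
                      d, paste(dropped, collapse = ", ")), call. = FALSE)
      sub <- sub[sub$metric %in% app, ]
    }
    dplyr::bind_rows(lapply(unique(sub$metric), function(m) {
      cells <- sub[sub$metric == m, ]
      dir <- registry$direction[registry$metric_id == m]
      score <- tryCatch(
        normalize_vector(cells$value, dir, degenerate = degenerate),
        error = function(e) {
          stop(sprintf("dataset '%s', metric '%s': %s", d, m,
                       conditionMessage(e)), call. = FALSE)
        })
      tibble::tibble(dataset = d, assembler = cells$assembler, metric = m,
                     score = unname(score))
    }))
  })
  dplyr::bind_rows(pieces)
}
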
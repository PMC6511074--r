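#' Per-dataset metric scores (MS)
#'
#' The metric score of an assembler on a dataset is the sum of its
#' (0,1)-normalized scores over all metrics applicable to that dataset, so
#' its maximum equals the number of applicable metrics (20 for a paired-end
#' dataset under the canonical registry, 18 for single-end). An MS of
#' 14.62 on a paired-end dataset is conventionally written 14.62/20.
#'
#' A cell that is missing for one assembler while present for others never
#' enters the min/max during normalization; at summation time it
#' contributes 0 under the default `missing = "zero"` policy (an assembler
#' that failed to produce a metric is treated as worst). Under
#' `missing = "omit"` the sum is numerically identical but the reported
#' `max_possible` for that assembler counts only the metrics actually
#' present, making the shortfall visible.
#'
#' @param norm Normalized matrix from [normalize_matrix()].
#' @param registry Metric registry; defaults to [builtin_registry()].
#' @param datasets Dataset sheet tibble.
#' @param missing Missing-cell policy, `"zero"` (default) or `"omit"`.
#' @return A tibble `dataset`, `assembler`, `ms`, `n_metrics` (non-missing
#'   cells summed), `max_possible`.
#' @export
metric_scores <- function(norm, registry = builtin_registry(), datasets,
                          missing = c("zero", "omit")) {
  missing <- match.arg(missing)
  norm <- tibble::as_tibble(norm)
  datasets <- validate_datasets(datasets)
  grid <- tidyr::expand_grid(dataset = unique(norm$dataset),
                             assembler = unique(norm$assembler))
  ms <- dplyr::summarise(
    dplyr::group_by(norm, .data$dataset, .data$assembler),
    ms = sum(.data$score, na.rm = TRUE),
    n_metrics = sum(!is.na(.data$score)),
    .groups = "drop")
  ms <- dplyr::left_join(grid, ms, by = c("dataset", "assembler"))
  ms$ms[is.na(ms$ms)] <- 0
  ms$n_metrics[is.na(ms$n_metrics)] <- 0L
  app_n <- vapply(ms$dataset, function(d) {
    length(applicable_metrics(datasets[datasets$dataset_id == d, ], registry))
  }, integer(1), USE.NAMES = FALSE)
  ms$max_possible <- if (missing == "zero") app_n else ms$n_metrics
  dplyr::arrange(ms, .data$dataset, .data$assembler)
}

#' @rdname metric_scores
#' @param dataset,assembler Ids selecting a single MS value.
#' @return `metric_score()` returns the single MS value as a number.
#' @export
metric_score <- function(norm, dataset, assembler,
                         registry = builtin_registry(), datasets,
                         missing = c("zero", "omit")) {
  ms <- metric_scores(norm, registry, datasets, missing)
  row <- ms[ms$dataset == dataset & ms$assembler == assembler, ]
  if (nrow(row) == 0) {
    stop(sprintf("no MS for (%s, %s): unknown dataset or assembler",
                 dataset, assembler), call. = FALSE)
  }
  row$ms
}

#' Overall metric score (OMS)
#'
#' Sums each assembler's per-dataset metric scores into a single overall
#' score. Datasets sharing a `replicate_group` in the dataset sheet
#' contribute the arithmetic mean of their MS values once, instead of each
#' counting separately, so a trio of near-identical replicate experiments
#' does not dominate the total. Incomplete groups use the members with an
#' available MS.
#'
#' @param ms MS tibble from [metric_scores()] (columns `dataset`,
#'   `assembler`, `ms`).
#' @param datasets Dataset sheet tibble with `replicate_group`; `NULL`
#'   treats every dataset as ungrouped.
#' @return A tibble `assembler`, `oms`, sorted by assembler id.
#' @export
overall_metric_score <- function(ms, datasets = NULL) {
  ms <- tibble::as_tibble(ms)
  if (is.null(datasets)) {
    datasets <- tibble::tibble(dataset_id = unique(ms$dataset),
                               layout = "paired_end",
                               replicate_group = NA_character_)
  }
  datasets <- validate_datasets(datasets)
  grp <- datasets$replicate_group[match(ms$dataset, datasets$dataset_id)]
  # each ungrouped dataset is its own contribution unit
  unit <- ifelse(is.na(grp), paste0(".dataset:", ms$dataset),
                 paste0(".group:", grp))
  contrib <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(assembler = ms$assembler, unit = unit,
                                   ms = ms$ms),
                    .data$assembler, .data$unit),
    contribution = mean(.data$ms), .groups = "drop")
  oms <- dplyr::summarise(dplyr::group_by(contrib, .data$assembler),
                          oms = sum(.data$contribution), .groups = "drop")
  dplyr::arrange(oms, .data$assembler)
}

#' Rank assemblers by overall metric score
#'
#' Orders assemblers by descending OMS; ties are broken lexicographically
#' by assembler id so the ranking is a deterministic total order.
#'
#' @param oms Either the tibble returned by [overall_metric_score()] or a
#'   named numeric vector of OMS values.
#' @return A tibble `rank`, `assembler`, `oms`.
#' @export
rank_assemblers <- function(oms) {
  if (is.numeric(oms) && !is.null(names(oms))) {
    oms <- tibble::tibble(assembler = names(oms), oms = unname(oms))
  }
  oms <- tibble::as_tibble(oms)
  if (nrow(oms) == 0) {
    stop("cannot rank an empty OMS table", call. = FALSE)
  }
  ranked <- dplyr::arrange(oms, dplyr::desc(.data$oms), .data$assembler)
  tibble::tibble(rank = seq_len(nrow(ranked)), assembler = ranked$assembler,
                 oms = ranked$oms)
}

#' Hierarchically cluster assembler MS profiles
#'
#' Treats each assembler's vector of per-dataset metric scores as a
#' profile and clusters the assemblers by agglomerative hierarchical
#' clustering (Euclidean distance and average linkage by default, both
#' configurable). The clustering is display-only: it orders the rows of
#' the MS heatmap and never influences MS or OMS values.
#'
#' @param ms MS tibble (`dataset`, `assembler`, `ms`), complete over the
#'   assemblers-by-datasets grid.
#' @param distance Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An object of class `transeval_clustering`: a list with `tree`
#'   (the `hclust` object), `order` (assembler ids in leaf order), and
#'   `profiles` (the assemblers-by-datasets MS matrix).
#' @export
cluster_profiles <- function(ms, distance = "euclidean", linkage = "average") {
  ms <- tibble::as_tibble(ms)
  wide <- tidyr::pivot_wider(ms[, c("dataset", "assembler", "ms")],
                             names_from = "dataset", values_from = "ms")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$assembler
  if (nrow(mat) < 2) {
    stop("clustering needs at least 2 assemblers", call. = FALSE)
  }
  if (anyNA(mat)) {
    stop("MS matrix is incomplete; clustering needs every (dataset, assembler) pair",
         call. = FALSE)
  }
  tree <- stats::hclust(stats::dist(mat, method = distance), method = linkage)
  structure(list(tree = tree, order = rownames(mat)[tree$order],
                 profiles = mat),
            class = "transeval_clustering")
}

#' @export
print.transeval_clustering <- function(x, ...) {
  cat("Assembler MS-profile clustering (", x$tree$dist.method, " distance, ",
      x$tree$method, " linkage)\n", sep = "")
  cat("Leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' MS heatmap with cluster-ordered assemblers
#'
#' Renders the per-dataset metric scores as an annotated heatmap: rows are
#' assemblers (in clustering leaf order, with OMS in brackets), columns
#' are datasets, and each cell shows the MS rounded to two decimals.
#'
#' @param ms MS tibble (`dataset`, `assembler`, `ms`).
#' @param oms Optional OMS tibble used to annotate row labels.
#' @param cluster Cluster rows with [cluster_profiles()] (default `TRUE`).
#' @param dataset_order Optional explicit column order.
#' @return A `ggplot` object.
#' @export
plot_ms_heatmap <- function(ms, oms = NULL, cluster = TRUE,
                            dataset_order = NULL) {
  ms <- tibble::as_tibble(ms)
  row_order <- if (cluster && length(unique(ms$assembler)) >= 2) {
    cluster_profiles(ms)$order
  } else {
    sort(unique(ms$assembler))
  }
  labels <- stats::setNames(row_order, row_order)
  if (!is.null(oms)) {
    lab_oms <- oms$oms[match(row_order, oms$assembler)]
    labels <- stats::setNames(
      sprintf("%s (%.1f)", row_order, lab_oms), row_order)
  }
  col_order <- if (is.null(dataset_order)) unique(ms$dataset) else dataset_order
  ms$assembler <- factor(ms$assembler, levels = rev(row_order))
  ms$dataset <- factor(ms$dataset, levels = col_order)
  ggplot2::ggplot(ms, ggplot2::aes(x = .data$dataset, y = .data$assembler,
                                   fill = .data$ms)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$ms)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#fff5eb", high = "#d94801",
                                 name = "MS") +
    ggplot2::scale_y_discrete(labels = labels) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
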
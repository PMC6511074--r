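#' Bundled reference fixture: a 10-assembler x 20-metric evaluation
#'
#' Returns the bundled raw metric matrix for a strand-specific paired-end
#' human bulk RNA-Seq library evaluated with the full 20-metric canonical
#' registry across ten de novo assemblers, together with the published
#' normalized values and summarized per-assembler metric scores for
#' regression testing. The raw values were transcribed from the published
#' evaluation at its printed precision (RSEM-EVAL scores are in units of
#' 1e9; ambiguous-base counts in millions), so recomputed normalized
#' scores match the printed ones only within a rounding-propagation
#' tolerance of a few hundredths.
#'
#' @return A list with:
#'   \describe{
#'     \item{raw}{long-format raw metric matrix (dataset `"hsa"`).}
#'     \item{datasets}{one-row dataset sheet (paired-end,
#'       strand-specific).}
#'     \item{normalized_printed}{long-format tibble of the printed
#'       normalized scores (column `value`).}
#'     \item{ms_printed}{named numeric vector of the printed per-assembler
#'       metric scores.}
#'   }
#' @export
table2_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "transeval",
                                 mustWork = TRUE)
  raw <- suppressWarnings(read_metric_matrix(ext("table2_raw.tsv")))
  normalized <- suppressWarnings(read_metric_matrix(ext("table2_normalized.tsv")))
  ms <- readr::read_tsv(ext("table2_ms.tsv"), col_types = readr::cols(
    dataset = readr::col_character(),
    assembler = readr::col_character(),
    ms = readr::col_double()
  ))
  datasets <- tibble::tibble(dataset_id = "hsa", layout = "paired_end",
                             strand_specific = TRUE,
                             replicate_group = NA_character_)
  list(raw = raw, datasets = datasets, normalized_printed = normalized,
       ms_printed = stats::setNames(ms$ms, ms$assembler))
}
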
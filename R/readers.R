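# Tabular readers for the primary-data inputs of the derived metrics.

#' Read a per-transcript expression table
#'
#' A TSV with header `transcript_id length expression`: transcript id,
#' transcript length in nucleotides, and a non-negative normalized
#' abundance (TPM-like; the unit cancels out in [exn50()]).
#'
#' @param path Path to the TSV file.
#' @return A tibble with the three columns, validated.
#' @export
read_expression_table <- function(path) {
  records <- readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    length = readr::col_double(),
    expression = readr::col_double()
  ))
  if (any(is.na(records$length)) || any(records$length < 1)) {
    stop("transcript lengths must be >= 1", call. = FALSE)
  }
  if (any(is.na(records$expression)) || any(records$expression < 0)) {
    stop("expression values must be >= 0", call. = FALSE)
  }
  records
}

#' Read a 12-column tabular protein alignment file
#'
#' Reads the standard headerless 12-column tabular format of translated
#' BLAST searches (`qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore`). Subject coordinates are amino-acid
#' positions and may arrive reversed; canonicalization happens downstream
#' in [protein_coverage()].
#'
#' @param path Path to the alignment file.
#' @return A tibble with the twelve standard columns.
#' @export
read_alignment_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  aln <- readr::read_tsv(path, col_names = cols, col_types = readr::cols(
    qseqid = readr::col_character(),
    sseqid = readr::col_character(),
    .default = readr::col_double()
  ))
  aln
}

#' Filter alignment rows by e-value and identity
#'
#' Convenience pre-filter for alignment tables. Off by default in the
#' programmatic API ([protein_coverage()] consumes whatever it is given);
#' the command-line `fulllength` step applies the e-value cutoff 1e-20 by
#' default, mirroring common translated-search practice.
#'
#' @param alignments Tibble from [read_alignment_table()].
#' @param max_evalue Keep rows with `evalue <= max_evalue` (`NULL` = no
#'   filter).
#' @param min_identity Keep rows with `pident >= min_identity` (`NULL` =
#'   no filter).
#' @return The filtered tibble.
#' @export
filter_alignments <- function(alignments, max_evalue = 1e-20,
                              min_identity = NULL) {
  if (!is.null(max_evalue)) {
    alignments <- alignments[alignments$evalue <= max_evalue, ]
  }
  if (!is.null(min_identity)) {
    alignments <- alignments[alignments$pident >= min_identity, ]
  }
  alignments
}

#' Read a protein-length table
#'
#' A TSV with header `subject_id length` giving each reference protein's
#' length in amino acids.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of protein lengths.
#' @export
read_protein_lengths <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    length = readr::col_double()
  ))
  if (any(is.na(tab$length)) || any(tab$length <= 0)) {
    stop("protein lengths must be positive", call. = FALSE)
  }
  stats::setNames(tab$length, tab$subject_id)
}
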
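#' N50 of a set of contig lengths
#'
#' The N50 is the length of the contig at which the cumulative length of
#' contigs, sorted from longest to shortest, first reaches half of the
#' total assembled length.
#'
#' @param lengths Vector of positive integer contig lengths.
#' @return The N50 length (a positive integer).
#' @export
#' @examples
#' n50(c(2, 2, 2, 3, 3, 4, 8, 8)) # 8
n50 <- function(lengths) {
  if (length(lengths) == 0) {
    stop("cannot compute N50 of an empty length set", call. = FALSE)
  }
  if (any(is.na(lengths)) || any(lengths < 1)) {
    stop("contig lengths must be positive", call. = FALSE)
  }
  sorted <- sort(as.numeric(lengths), decreasing = TRUE)
  idx <- which(cumsum(sorted) >= sum(sorted) / 2)[1]
  sorted[idx]
}

#' Expression-informed ExN50
#'
#' The plain N50 of a transcriptome assembly is easily dragged down by
#' large numbers of short, weakly expressed contigs. The ExN50 statistic
#' compensates by restricting the N50 computation to the most highly
#' expressed transcripts that together account for a given fraction of the
#' total normalized expression; the conventional choice is the Ex90N50 at
#' `fraction = 0.9`.
#'
#' Expression values are renormalized internally to proportions, so the
#' statistic is invariant to the expression unit (TPM, estimated counts,
#' ...). Transcripts are sorted by expression (descending); ties are broken
#' by length (descending) and then transcript id (ascending) for
#' determinism. The minimal prefix whose cumulative expression share
#' reaches `fraction` is retained, including the transcript that crosses
#' the threshold, and its lengths are passed to [n50()].
#'
#' @param records A data frame with columns `transcript_id`, `length`,
#'   `expression` (see [read_expression_table()]).
#' @param fraction Expression share in (0, 1\] delimiting the prefix.
#' @return The ExN50 length (a positive integer).
#' @export
exn50 <- function(records, fraction = 0.9) {
  records <- tibble::as_tibble(records)
  required <- c("transcript_id", "length", "expression")
  if (!all(required %in% names(records))) {
    stop("records need columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) {
    stop("cannot compute ExN50 of an empty transcript set", call. = FALSE)
  }
  if (any(records$length < 1) || any(records$expression < 0)) {
    stop("lengths must be >= 1 and expression >= 0", call. = FALSE)
  }
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  total <- sum(records$expression)
  if (total == 0) {
    stop("total expression is zero; ExN50 undefined", call. = FALSE)
  }
  ord <- order(-records$expression, -records$length, records$transcript_id)
  records <- records[ord, ]
  share <- cumsum(records$expression) / total
  # tolerate float round-off at the crossing point
  k <- which(share >= fraction - 1e-12)[1]
  n50(records$length[seq_len(k)])
}

#' @rdname exn50
#' @return `exn50_prefix()` returns the retained transcript records (the
#'   minimal expression-sorted prefix), useful for inspecting which
#'   transcripts drive the statistic.
#' @export
exn50_prefix <- function(records, fraction = 0.9) {
  records <- tibble::as_tibble(records)
  total <- sum(records$expression)
  ord <- order(-records$expression, -records$length, records$transcript_id)
  records <- records[ord, ]
  share <- cumsum(records$expression) / total
  k <- which(share >= fraction - 1e-12)[1]
  records[seq_len(k), ]
}

#' Protein coverage from grouped alignment segments
#'
#' Estimates, for each reference protein, how much of its length is
#' covered by a single assembled transcript. Alignment segments (e.g. from
#' a translated BLAST search in 12-column tabular format) are grouped per
#' (transcript, protein) pair; the segments of one pair — a transcript may
#' hit a protein in several discontinuous alignments — are merged by
#' taking the union of their subject-coordinate intervals (1-based
#' inclusive amino-acid positions, so \[1, 10\] covers 10 residues).
#' Coverage of a pair is the union length divided by the protein length,
#' capped at 1. Per protein, the maximum coverage over all transcripts is
#' reported; segments from different transcripts are never merged.
#'
#' Reversed coordinates (`subject_start > subject_end`) are canonicalized
#' by swapping. Proteins listed in `protein_lengths` but hit by no segment
#' get coverage 0.
#'
#' @param segments Data frame with columns `query_id`, `subject_id`,
#'   `subject_start`, `subject_end` (extra columns ignored), e.g. from
#'   [read_alignment_table()] after renaming, or directly with the
#'   12-column names `qseqid`/`sseqid`/`sstart`/`send`.
#' @param protein_lengths Named numeric vector (names = subject ids) or a
#'   data frame with columns `subject_id`, `length`.
#' @return Named numeric vector of per-protein coverages in \[0, 1\],
#'   one entry per protein in `protein_lengths`.
#' @export
protein_coverage <- function(segments, protein_lengths) {
  segments <- tibble::as_tibble(segments)
  # accept raw 12-column alignment naming
  alias <- c(qseqid = "query_id", sseqid = "subject_id",
             sstart = "subject_start", send = "subject_end")
  for (from in names(alias)) {
    if (from %in% names(segments) && !alias[[from]] %in% names(segments)) {
      names(segments)[names(segments) == from] <- alias[[from]]
    }
  }
  required <- c("query_id", "subject_id", "subject_start", "subject_end")
  if (!all(required %in% names(segments))) {
    stop("segments need columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (is.data.frame(protein_lengths)) {
    protein_lengths <- stats::setNames(protein_lengths$length,
                                       protein_lengths$subject_id)
  }
  if (any(protein_lengths <= 0)) {
    stop("protein lengths must be positive", call. = FALSE)
  }
  unknown <- setdiff(unique(segments$subject_id), names(protein_lengths))
  if (length(unknown) > 0) {
    stop("segments reference protein(s) with unknown length: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  s1 <- pmin(segments$subject_start, segments$subject_end)
  s2 <- pmax(segments$subject_start, segments$subject_end)
  if (any(s1 < 1)) {
    stop("subject coordinates must be >= 1", call. = FALSE)
  }
  cov <- stats::setNames(rep(0, length(protein_lengths)),
                         names(protein_lengths))
  if (nrow(segments) > 0) {
    key <- paste(segments$query_id, segments$subject_id, sep = "\r")
    per_pair <- vapply(split(seq_len(nrow(segments)), key), function(i) {
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(s1[i], s2[i]))))
    }, numeric(1))
    # split() orders groups by key; recover each group's subject id from it
    pair_subject <- vapply(strsplit(names(per_pair), "\r", fixed = TRUE),
                           `[`, character(1), 2)
    pair_cov <- pmin(per_pair / protein_lengths[pair_subject], 1)
    best <- tapply(pair_cov, pair_subject, max)
    cov[names(best)] <- best
  }
  cov
}

#' Count full-length reconstructed proteins
#'
#' Counts reference proteins whose length is covered by more than (or at
#' least) a threshold fraction by a single assembled transcript. The
#' conventional criterion for a "full-length" protein-coding transcript is
#' strict coverage above 0.9.
#'
#' @param coverages Numeric vector of per-protein coverages in \[0, 1\]
#'   (see [protein_coverage()]).
#' @param threshold Coverage threshold in (0, 1\].
#' @param strict If `TRUE` (default) require coverage strictly greater
#'   than the threshold; if `FALSE`, greater or equal.
#' @return Integer count.
#' @export
count_full_length <- function(coverages, threshold = 0.9, strict = TRUE) {
  if (length(coverages) == 0) {
    return(0L)
  }
  if (any(coverages < 0 | coverages > 1)) {
    stop("coverages must lie in [0, 1]", call. = FALSE)
  }
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  if (strict) sum(coverages > threshold) else sum(coverages >= threshold)
}

#' Basic assembly statistics
#'
#' Computes per-assembly contig statistics: number of contigs, number of
#' contigs of length >= 1,000 nt, total length, count of ambiguous bases
#' (`N`/`n`), and the N50. Characters outside `A`, `C`, `G`, `T`, `N`
#' (case-insensitive) trigger a warning and count toward the length but
#' not toward the ambiguous bases.
#'
#' @param sequences A named character vector of nucleotide sequences, a
#'   `Biostrings::DNAStringSet`, or the path to a FASTA file.
#' @return An object of class `assembly_stats`: a list with `n_contigs`,
#'   `n_ge_1000`, `total_length`, `ambiguous_bases`, `n50`.
#' @export
assembly_stats <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  if (methods::is(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0) {
    stop("empty assembly: no sequences", call. = FALSE)
  }
  seqs <- toupper(sequences)
  lens <- nchar(seqs)
  n_amb <- vapply(seqs, function(s) {
    nchar(gsub("[^N]", "", s))
  }, numeric(1), USE.NAMES = FALSE)
  odd <- vapply(seqs, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, numeric(1), USE.NAMES = FALSE)
  if (any(odd > 0)) {
    warning(sum(odd), " character(s) outside the A/C/G/T/N alphabet; ",
            "counted in length but not as ambiguous", call. = FALSE)
  }
  structure(list(
    n_contigs = length(seqs),
    n_ge_1000 = sum(lens >= 1000),
    total_length = sum(lens),
    ambiguous_bases = sum(n_amb),
    n50 = n50(lens)
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "Assembly: %d contigs (%d >= 1,000 nt), %d nt total, %d ambiguous bases, N50 = %d\n",
    x$n_contigs, x$n_ge_1000, x$total_length, x$ambiguous_bases, x$n50))
  invisible(x)
}

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] accepting
#' multi-line, mixed-case FASTA.
#'
#' @param path Path to a (possibly multi-line) FASTA file.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
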
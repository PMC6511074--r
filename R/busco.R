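#' BUSCO category counts
#'
#' Container for the four BUSCO completeness categories of one assembly:
#' complete single-copy (S), complete duplicated (D), fragmented (F), and
#' missing (M) orthologs, plus the total number of ortholog groups
#' searched. The categories partition the total.
#'
#' @param single_copy,duplicated,fragmented,missing,total Non-negative
#'   integer counts with `single_copy + duplicated + fragmented + missing
#'   == total`.
#' @return A `busco_counts` object (a named list).
#' @export
busco_counts <- function(single_copy, duplicated, fragmented, missing, total) {
  counts <- c(single_copy = single_copy, duplicated = duplicated,
              fragmented = fragmented, missing = missing, total = total)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("BUSCO counts must be non-negative integers", call. = FALSE)
  }
  if (single_copy + duplicated + fragmented + missing != total) {
    stop(sprintf(
      "BUSCO categories do not sum to the total: S+D+F+M = %d, total = %d",
      single_copy + duplicated + fragmented + missing, total), call. = FALSE)
  }
  structure(as.list(counts), class = "busco_counts")
}

#' @export
print.busco_counts <- function(x, ...) {
  cat(sprintf("BUSCO: S=%d, D=%d, F=%d, M=%d of n=%d\n", x$single_copy,
              x$duplicated, x$fragmented, x$missing, x$total))
  invisible(x)
}

#' Summarize BUSCO completeness
#'
#' Reduces the four BUSCO categories to the two quantities used for
#' scoring: the number of complete orthologs — single-copy plus duplicated,
#' so alternative transcripts of the same ortholog still count as complete —
#' and the number of missing orthologs.
#'
#' @param counts A [busco_counts()] object (or a list with the same
#'   fields, which is validated first).
#' @return A list with `complete` (= S + D) and `missing`.
#' @export
#' @examples
#' busco_complete(busco_counts(2000, 2004, 300, 1804, 6108))
busco_complete <- function(counts) {
  if (!inherits(counts, "busco_counts")) {
    counts <- busco_counts(counts$single_copy, counts$duplicated,
                           counts$fragmented, counts$missing, counts$total)
  }
  list(complete = counts$single_copy + counts$duplicated,
       missing = counts$missing)
}

#' Parse a BUSCO short-summary file
#'
#' Accepts the standard `short_summary*.txt` produced by BUSCO, in either
#' of its two redundant representations (both are parsed if present):
#' \itemize{
#'   \item the per-category count lines, e.g. `2000  Complete and
#'     single-copy BUSCOs (S)`;
#'   \item the one-line percentage summary, e.g.
#'     `C:65.5%[S:32.7%,D:32.8%],F:4.9%,M:29.6%,n:6108`.
#' }
#' Count lines take precedence. When only the percentage line is present,
#' S, D, and F counts are recovered by rounding `pct/100 * n`; the missing
#' count is then derived as `n - S - D - F` (rather than from the printed
#' M percentage) so the category partition holds exactly despite rounding.
#'
#' @param path Path to a short-summary text file, or a character vector of
#'   its lines.
#' @return A [busco_counts()] object.
#' @export
parse_busco_summary <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    path
  }
  grab_count <- function(pattern) {
    hit <- grep(pattern, lines, value = TRUE)
    if (length(hit) == 0) {
      return(NA_integer_)
    }
    as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1", hit[1]))
  }
  s <- grab_count("Complete and single-copy BUSCOs")
  d <- grab_count("Complete and duplicated BUSCOs")
  f <- grab_count("Fragmented BUSCOs")
  m <- grab_count("Missing BUSCOs")
  n <- grab_count("Total BUSCO groups searched|Total lineage BUSCOs searched")

  if (anyNA(c(s, d, f, m, n))) {
    one <- grep("C:.*\\[S:.*,D:.*\\],F:.*,M:.*,n:", lines, value = TRUE)
    if (length(one) == 0) {
      stop("not a recognizable BUSCO short summary", call. = FALSE)
    }
    one <- gsub("\\s", "", one[1])
    pct <- function(tag) {
      as.numeric(sub(sprintf(".*%s:([-0-9.]+)%%.*", tag), "\\1", one))
    }
    n <- as.integer(sub(".*n:(\\d+).*", "\\1", one))
    s <- as.integer(round(pct("S") / 100 * n))
    d <- as.integer(round(pct("D") / 100 * n))
    f <- as.integer(round(pct("F") / 100 * n))
    m <- n - s - d - f
  }
  busco_counts(s, d, f, m, n)
}
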
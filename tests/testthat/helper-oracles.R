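# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# N50 by literal definition: walk the descending lengths until half the
# total is accumulated.
oracle_n50 <- function(lengths) {
  lengths <- sort(lengths, decreasing = TRUE)
  acc <- 0
  for (l in lengths) {
    acc <- acc + l
    if (acc >= sum(lengths) / 2) {
      return(l)
    }
  }
}

# Interval-union coverage by looping over every amino-acid position.
oracle_coverage <- function(starts, ends, protein_length) {
  covered <- rep(FALSE, protein_length)
  for (i in seq_along(starts)) {
    a <- min(starts[i], ends[i])
    b <- max(starts[i], ends[i])
    covered[a:min(b, protein_length)] <- TRUE
  }
  sum(covered) / protein_length
}

# MS by direct evaluation of the defining formulas: per metric, min-max
# across assemblers (inverting lower_better), then a plain sum per
# assembler. `raw` is a metrics-by-assemblers matrix.
oracle_ms <- function(raw, directions) {
  scores <- matrix(NA_real_, nrow(raw), ncol(raw),
                   dimnames = dimnames(raw))
  for (j in seq_len(nrow(raw))) {
    v <- raw[j, ]
    n <- (v - min(v)) / (max(v) - min(v))
    if (directions[j] == "lower_better") {
      n <- 1 - n
    }
    scores[j, ] <- n
  }
  colSums(scores)
}

# Tolerance for comparing normalized scores recomputed from rounded
# printed raws against printed normalized values: base printed-output
# rounding (0.005 per side) plus propagation of the raw quantization
# through the min-max ratio (~quantum / range).
fixture_cell_tol <- function(raw_values) {
  decimals <- max(0, nchar(sub("^[^.]*\\.?", "", format(raw_values,
                                                        scientific = FALSE))))
  quantum <- 10^-decimals
  0.02 + quantum / (max(raw_values) - min(raw_values))
}

# A tiny complete dataset sheet for single-dataset tests.
one_dataset <- function(id = "ds1", layout = "paired_end") {
  tibble::tibble(dataset_id = id, layout = layout, strand_specific = FALSE,
                 replicate_group = NA_character_)
}

# Long-format matrix from a metrics-by-assemblers value matrix.
long_matrix <- function(raw, dataset = "ds1") {
  dplyr::bind_rows(lapply(rownames(raw), function(m) {
    tibble::tibble(dataset = dataset, assembler = colnames(raw), metric = m,
                   value = unname(raw[m, ]))
  }))
}
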
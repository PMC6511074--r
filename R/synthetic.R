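# Synthetic-data generators. Every generator is a pure function of its
# parameters and seed, and returns its ground truth alongside the data so
# downstream checks never have to re-derive the truth from the artifact.
#
# Seeding: each generator derives a private stream from the supplied seed
# with withr::with_seed(), so generators can be composed in any order
# without perturbing each other or the caller's RNG state.

#' Generate a raw metric matrix with a planted quality ordering
#'
#' Emulates the statistical structure the MS/OMS analysis assumes: each
#' assembler has a latent quality, observed through direction-heterogeneous
#' metrics as a monotone transform of quality plus Gaussian noise. Each
#' (dataset, metric) pair draws its own scale and offset, so raw values are
#' heterogeneous across metrics the way real evaluator outputs are;
#' `lower_better` metrics decrease with quality.
#'
#' With `noise_sd = 0` every metric ranks the assemblers identically, so
#' the recovered OMS ranking must equal the planted order and the best
#' assembler attains the maximum possible MS on every dataset.
#'
#' @param n_datasets Number of datasets to simulate.
#' @param quality Strictly decreasing vector of latent assembler qualities;
#'   its length sets the number of assemblers. Default: 10 assemblers with
#'   qualities from 1 down to 0.1.
#' @param noise_sd Standard deviation of the Gaussian observation noise on
#'   the quality scale.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param layouts Dataset layouts, recycled across datasets.
#' @param replicate_groups Optional character vector (length `n_datasets`,
#'   `NA` = ungrouped) assigning datasets to replicate groups.
#' @param registry Metric registry supplying metric ids and directions.
#' @return A list with `matrix` (long-format raw metric matrix), `datasets`
#'   (dataset sheet tibble), `order` (assembler ids, best first — the
#'   ground truth), and `quality` (named quality vector).
#' @export
gen_metric_matrix <- function(n_datasets = 9,
                              quality = seq(1, 0.1, length.out = 10),
                              noise_sd = 0.05, seed = 1,
                              layouts = "paired_end",
                              replicate_groups = NULL,
                              registry = builtin_registry()) {
  stopifnot(n_datasets >= 1, length(quality) >= 1)
  if (is.unsorted(rev(quality), strictly = TRUE)) {
    stop("`quality` must be strictly decreasing (best assembler first)",
         call. = FALSE)
  }
  validate_registry(registry)
  assemblers <- sprintf("asm%02d", seq_along(quality))
  dataset_ids <- sprintf("ds%02d", seq_len(n_datasets))
  layouts <- rep_len(layouts, n_datasets)
  if (is.null(replicate_groups)) {
    replicate_groups <- rep(NA_character_, n_datasets)
  }
  datasets <- tibble::tibble(dataset_id = dataset_ids, layout = layouts,
                             strand_specific = FALSE,
                             replicate_group = replicate_groups)
  matrix <- withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_datasets), function(i) {
      app <- applicable_metrics(datasets[i, ], registry)
      dplyr::bind_rows(lapply(app, function(m) {
        dir <- registry$direction[registry$metric_id == m]
        scale <- stats::runif(1, 0.5, 100)
        offset <- stats::runif(1, -10, 10)
        signal <- if (dir == "higher_better") quality else -quality
        value <- offset + scale * (signal + stats::rnorm(length(quality),
                                                         sd = noise_sd))
        tibble::tibble(dataset = dataset_ids[i], assembler = assemblers,
                       metric = m, value = value)
      }))
    }))
  })
  list(matrix = matrix, datasets = datasets, order = assemblers,
       quality = stats::setNames(quality, assemblers))
}

#' Generate a transcript expression set with known ExN50
#'
#' Constructs transcript records whose minimal high-expression prefix — and
#' therefore the ExN50 value — is known by construction rather than
#' recomputed.
#'
#' In the `"dominant"` design, `prefix_size` transcripts of identical
#' length `prefix_length` share `expression_share` of the total expression
#' equally, and the remaining transcripts split the rest equally but carry
#' randomized longer lengths; the minimal prefix reaching `fraction` is
#' exactly the planted prefix, so the expected ExN50 equals
#' `prefix_length`. In the `"uniform"` design all transcripts have equal
#' expression and equal length, so the ExN50 equals that common length for
#' any fraction.
#'
#' @param n Total number of transcripts.
#' @param design `"dominant"` or `"uniform"`.
#' @param expression_share Total expression share of the planted prefix
#'   (dominant design); must satisfy
#'   `fraction <= expression_share` and
#'   `expression_share * (prefix_size - 1) / prefix_size < fraction`.
#' @param prefix_size Number of transcripts in the planted prefix.
#' @param prefix_length Common length of the prefix transcripts.
#' @param fraction Expression fraction the prefix is planted for.
#' @param seed Integer seed.
#' @return A list with `records` (tibble `transcript_id`, `length`,
#'   `expression`), `expected_exn50`, and `prefix_ids`.
#' @export
gen_transcripts <- function(n = 10, design = c("dominant", "uniform"),
                            expression_share = 0.91, prefix_size = 1,
                            prefix_length = 500, fraction = 0.9, seed = 1) {
  design <- match.arg(design)
  stopifnot(n >= 1)
  ids <- sprintf("tx%04d", seq_len(n))
  if (design == "uniform") {
    records <- tibble::tibble(transcript_id = ids, length = prefix_length,
                              expression = 1)
    return(list(records = records, expected_exn50 = prefix_length,
                prefix_ids = ids))
  }
  stopifnot(prefix_size >= 1, prefix_size < n)
  if (expression_share < fraction ||
      expression_share * (prefix_size - 1) / prefix_size >= fraction) {
    stop("planted prefix would not be the minimal prefix for `fraction`",
         call. = FALSE)
  }
  records <- withr::with_seed(seed, {
    tail_n <- n - prefix_size
    tibble::tibble(
      transcript_id = ids,
      length = c(rep(prefix_length, prefix_size),
                 prefix_length * 10 + sample.int(5000, tail_n, replace = TRUE)),
      expression = c(rep(expression_share / prefix_size, prefix_size),
                     rep((1 - expression_share) / tail_n, tail_n)))
  })
  list(records = records, expected_exn50 = prefix_length,
       prefix_ids = ids[seq_len(prefix_size)])
}

#' Generate alignment tables with planted protein coverage
#'
#' Builds a 12-column tabular alignment set in which each reference
#' protein is hit by exactly one synthetic transcript whose segments union
#' to a prescribed coverage. The covered region `[1, K]` with
#' `K = round(coverage * length)` is emitted as `n_segments` overlapping
#' sub-intervals, so segment grouping and interval union are exercised
#' while the realized coverage `K / length` is known exactly.
#'
#' @param n_proteins Number of reference proteins.
#' @param coverages Target coverage per protein in \[0, 1\], recycled to
#'   `n_proteins`. A coverage of 0 emits no segments for that protein.
#' @param n_segments Number of overlapping segments per covered protein.
#' @param protein_length Protein lengths in amino acids, recycled;
#'   multiples of 10 keep round-number coverages exact.
#' @param threshold,strict Full-length criterion used for the planted
#'   count (defaults: strict > 0.9).
#' @param seed Integer seed (randomizes segment overlaps only).
#' @return A list with `alignments` (12-column tibble), `protein_lengths`
#'   (named vector), `coverages` (named realized coverages — the ground
#'   truth), and `n_full_length` (planted count under the criterion).
#' @export
gen_alignments <- function(n_proteins = 100, coverages = 0.95,
                           n_segments = 2, protein_length = 300,
                           threshold = 0.9, strict = TRUE, seed = 1) {
  stopifnot(n_proteins >= 1, all(coverages >= 0 & coverages <= 1))
  proteins <- sprintf("prot%04d", seq_len(n_proteins))
  lens <- rep_len(protein_length, n_proteins)
  coverages <- rep_len(coverages, n_proteins)
  covered <- round(coverages * lens)
  realized <- covered / lens
  alignments <- withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_proteins), function(i) {
      k <- covered[i]
      if (k == 0) {
        return(NULL)
      }
      # cut [1, k] into n_segments pieces, then widen each start backwards
      # by a random overlap so the union stays exactly [1, k]
      bounds <- unique(round(seq(0, k, length.out = n_segments + 1)))
      starts <- utils::head(bounds, -1) + 1
      ends <- bounds[-1]
      overlap <- pmin(starts - 1, sample.int(10, length(starts), replace = TRUE))
      starts <- pmax(1, starts - overlap)
      tibble::tibble(
        qseqid = sprintf("contig%04d", i), sseqid = proteins[i],
        pident = 98, length = ends - starts + 1, mismatch = 0, gapopen = 0,
        qstart = (starts - 1) * 3 + 1, qend = ends * 3,
        sstart = starts, send = ends,
        evalue = 1e-50, bitscore = (ends - starts + 1) * 2)
    }))
  })
  n_full <- count_full_length(realized, threshold = threshold,
                              strict = strict)
  list(alignments = alignments,
       protein_lengths = stats::setNames(lens, proteins),
       coverages = stats::setNames(realized, proteins),
       n_full_length = n_full)
}

#' Generate a synthetic assembly FASTA with planted statistics
#'
#' Emits random contigs of prescribed lengths with a prescribed number of
#' ambiguous bases (`N`) planted at random positions in each contig, and
#' returns the exact expected [assembly_stats()] alongside.
#'
#' @param lengths Contig lengths.
#' @param n_ambiguous Number of `N` bases per contig, recycled.
#' @param seed Integer seed.
#' @return A list with `sequences` (named character vector), the expected
#'   `stats` (an `assembly_stats` object), and nothing else.
#' @export
gen_fasta <- function(lengths = c(500, 1500, 1000, 200), n_ambiguous = 0,
                      seed = 1) {
  stopifnot(all(lengths >= 1))
  n_ambiguous <- rep_len(n_ambiguous, length(lengths))
  stopifnot(all(n_ambiguous <= lengths))
  sequences <- withr::with_seed(seed, {
    vapply(seq_along(lengths), function(i) {
      s <- sample(c("A", "C", "G", "T"), lengths[i], replace = TRUE)
      if (n_ambiguous[i] > 0) {
        s[sample.int(lengths[i], n_ambiguous[i])] <- "N"
      }
      paste(s, collapse = "")
    }, character(1))
  })
  names(sequences) <- sprintf("contig%04d", seq_along(sequences))
  stats <- structure(list(
    n_contigs = length(lengths),
    n_ge_1000 = sum(lengths >= 1000),
    total_length = sum(lengths),
    ambiguous_bases = sum(n_ambiguous),
    n50 = n50(lengths)
  ), class = "assembly_stats")
  list(sequences = sequences, stats = stats)
}

#' Write a named character vector as FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
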
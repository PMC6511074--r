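# The published worked example: overall mapping rates of ten assemblers on
# the E. coli dataset, and the printed normalized vector.
eco_omr <- c(77.0, 49.1, 95.7, 56.6, 87.4, 71.1, 34.3, 76.7, 88.0, 89.0)
eco_omr_printed <- c(0.7, 0.24, 1.0, 0.36, 0.86, 0.6, 0.0, 0.69, 0.88, 0.89)

test_that("normalize_vector reproduces the published worked example", {
  got <- normalize_vector(eco_omr, "higher_better")
  expect_true(all(abs(got - eco_omr_printed) <= 0.02))
  expect_equal(min(got), 0)
  expect_equal(max(got), 1)
})

test_that("lower-is-better normalization matches the published misassembly row", {
  raws <- c(3378, 216127, 2743, 279, 7329, 5603, 302, 2837, 2022, 5126)
  printed <- c(0.99, 0.00, 0.99, 1.00, 0.97, 0.98, 1.00, 0.99, 0.99, 0.98)
  got <- normalize_vector(raws, "lower_better")
  expect_true(all(abs(got - printed) <= 0.02))
  # algebraic identity between the two orientations
  expect_equal(got, 1 - normalize_vector(raws, "higher_better"))
})

test_that("normalize_vector handles degenerate and missing input", {
  expect_warning(out <- normalize_vector(c(5, 5, 5), "higher_better"),
                 "degenerate")
  expect_equal(out, c(0.5, 0.5, 0.5))
  expect_warning(out <- normalize_vector(c(5, 5, 5), "lower_better",
                                         degenerate = 0),
                 "degenerate")
  expect_equal(out, c(0, 0, 0))
  # missing values pass through and stay out of min/max
  got <- normalize_vector(c(10, NA, 20, 30), "higher_better")
  expect_equal(got, c(0, NA, 0.5, 1))
  expect_error(normalize_vector(c(NA_real_, NA_real_), "higher_better"),
               "all-missing")
})

test_that("normalization is invariant to positive affine maps and z-scoring", {
  withr::local_seed(421)
  for (i in 1:20) {
    v <- stats::rnorm(sample(3:12, 1), sd = stats::runif(1, 0.1, 50))
    a <- stats::runif(1, 0.01, 100)
    b <- stats::runif(1, -100, 100)
    base <- normalize_vector(v, "higher_better")
    expect_equal(normalize_vector(a * v + b, "higher_better"), base,
                 tolerance = 1e-10)
    z <- (v - mean(v)) / stats::sd(v)
    expect_equal(normalize_vector(z, "higher_better"), base,
                 tolerance = 1e-10)
  }
})

test_that("normalize_matrix reproduces the full printed fixture table", {
  fx <- table2_fixture()
  norm <- normalize_matrix(fx$raw, builtin_registry(), fx$datasets)
  expect_equal(nrow(norm), 200)
  expect_true(all(norm$score >= 0 & norm$score <= 1))
  joined <- dplyr::inner_join(
    norm, fx$normalized_printed,
    by = c("dataset", "assembler", "metric"))
  expect_equal(nrow(joined), 200)
  for (m in unique(joined$metric)) {
    sub <- joined[joined$metric == m, ]
    tol <- fixture_cell_tol(fx$raw$value[fx$raw$metric == m])
    expect_lt(max(abs(sub$score - sub$value)), tol, label = m)
  }
  # each (dataset, metric) vector touches both 0 and 1
  per_metric <- dplyr::summarise(
    dplyr::group_by(norm, .data$dataset, .data$metric),
    lo = min(.data$score), hi = max(.data$score), .groups = "drop")
  expect_true(all(per_metric$lo == 0))
  expect_true(all(per_metric$hi == 1))
})

test_that("normalize_matrix respects applicability and permutation symmetry", {
  fx <- table2_fixture()
  single <- fx$datasets
  single$layout <- "single_end"
  expect_warning(norm <- normalize_matrix(fx$raw, builtin_registry(), single),
                 "non-applicable")
  expect_length(unique(norm$metric), 18)
  expect_false("transrate_optimal_score" %in% norm$metric)

  # permuting assembler rows permutes the output identically
  norm0 <- normalize_matrix(fx$raw, builtin_registry(), fx$datasets)
  perm <- withr::with_seed(7, fx$raw[sample.int(nrow(fx$raw)), ])
  normp <- normalize_matrix(perm, builtin_registry(), fx$datasets)
  expect_equal(dplyr::arrange(normp, .data$metric, .data$assembler),
               dplyr::arrange(norm0, .data$metric, .data$assembler))

  expect_error(normalize_matrix(fx$raw[0, ], builtin_registry(), fx$datasets),
               "empty")
})

test_that("metric scores match the published per-assembler sums", {
  fx <- table2_fixture()
  norm <- normalize_matrix(fx$raw, builtin_registry(), fx$datasets)
  ms <- metric_scores(norm, builtin_registry(), fx$datasets)
  expect_equal(unique(ms$max_possible), 20L)
  got <- stats::setNames(ms$ms, ms$assembler)[names(fx$ms_printed)]
  expect_true(all(abs(got - fx$ms_printed) <= 0.06))
  expect_equal(metric_score(norm, "hsa", "Trinity",
                            datasets = fx$datasets),
               12.38, tolerance = 0.06 / 12.38)
  expect_error(metric_score(norm, "hsa", "NotATool", datasets = fx$datasets),
               "unknown")
})

test_that("MS agrees with brute-force evaluation and hand-computed cases", {
  # hand-computed 3 assemblers x 2 metrics: each assembler sums a
  # complementary 0/0.5/1 pair
  raw <- rbind(m_up = c(10, 20, 30), m_down = c(1, 2, 3))
  colnames(raw) <- c("a1", "a2", "a3")
  reg <- tibble::tibble(
    metric_id = c("m_up", "m_down"), label = c("up", "down"),
    source_tool = "synthetic",
    direction = c("higher_better", "lower_better"),
    applicability = "all", ordinal = 1:2)
  norm <- normalize_matrix(long_matrix(raw), reg, one_dataset())
  ms <- metric_scores(norm, reg, one_dataset())
  expect_equal(ms$ms, c(1, 1, 1))

  # randomized small instances against the direct-formula oracle
  withr::local_seed(99)
  for (i in 1:25) {
    n_a <- sample(2:4, 1)
    n_m <- sample(1:3, 1)
    raw <- matrix(stats::rnorm(n_a * n_m, sd = 10), nrow = n_m,
                  dimnames = list(paste0("m", seq_len(n_m)),
                                  paste0("a", seq_len(n_a))))
    dirs <- sample(c("higher_better", "lower_better"), n_m, replace = TRUE)
    reg <- tibble::tibble(metric_id = rownames(raw), label = rownames(raw),
                          source_tool = "synthetic", direction = dirs,
                          applicability = "all", ordinal = seq_len(n_m))
    norm <- normalize_matrix(long_matrix(raw), reg, one_dataset())
    ms <- metric_scores(norm, reg, one_dataset())
    expected <- oracle_ms(raw, dirs)
    expect_equal(stats::setNames(ms$ms, ms$assembler), expected,
                 tolerance = 1e-12)
  }
})

test_that("MS is bounded and self-monotone", {
  withr::local_seed(2024)
  reg <- builtin_registry()
  for (i in 1:10) {
    sim <- gen_metric_matrix(n_datasets = 1, noise_sd = 0.3, seed = i)
    norm <- normalize_matrix(sim$matrix, reg, sim$datasets)
    ms <- metric_scores(norm, reg, sim$datasets)
    expect_true(all(ms$ms >= 0 & ms$ms <= ms$max_possible))

    # raise one assembler's raw value on a higher_better metric: its own
    # MS never decreases
    target <- sample(unique(sim$matrix$assembler), 1)
    m <- "overall_mapping_rate"
    bumped <- sim$matrix
    sel <- bumped$assembler == target & bumped$metric == m
    bumped$value[sel] <- bumped$value[sel] + stats::runif(1, 0, 50)
    ms2 <- metric_scores(normalize_matrix(bumped, reg, sim$datasets), reg,
                         sim$datasets)
    expect_gte(ms2$ms[ms2$assembler == target] + 1e-12,
               ms$ms[ms$assembler == target])
  }
})

test_that("an all-best assembler attains MS equal to the metric count", {
  sim <- gen_metric_matrix(n_datasets = 2, noise_sd = 0, seed = 5)
  norm <- normalize_matrix(sim$matrix, builtin_registry(), sim$datasets)
  ms <- metric_scores(norm, builtin_registry(), sim$datasets)
  best <- sim$order[1]
  worst <- sim$order[length(sim$order)]
  expect_equal(ms$ms[ms$assembler == best], ms$max_possible[ms$assembler == best])
  expect_equal(ms$ms[ms$assembler == worst], c(0, 0))
})

test_that("missing cells follow the zero/omit policy", {
  raw <- rbind(m1 = c(10, 20, 30), m2 = c(5, NA, 15))
  colnames(raw) <- c("a1", "a2", "a3")
  reg <- tibble::tibble(metric_id = c("m1", "m2"), label = c("m1", "m2"),
                        source_tool = "synthetic",
                        direction = "higher_better", applicability = "all",
                        ordinal = 1:2)
  norm <- normalize_matrix(long_matrix(raw), reg, one_dataset())
  # the missing cell stayed out of min/max: a1 and a3 still hit 0 and 1
  expect_equal(norm$score[norm$metric == "m2" & norm$assembler == "a1"], 0)
  expect_equal(norm$score[norm$metric == "m2" & norm$assembler == "a3"], 1)
  zero <- metric_scores(norm, reg, one_dataset(), missing = "zero")
  omit <- metric_scores(norm, reg, one_dataset(), missing = "omit")
  expect_equal(zero$ms, omit$ms) # the sum is the same either way
  expect_equal(zero$max_possible[zero$assembler == "a2"], 2L)
  expect_equal(omit$max_possible[omit$assembler == "a2"], 1L)
})

test_that("OMS averages replicate groups and sums the rest", {
  # the published replicate trio: mean of 14.35, 14.11, 13.87 is 14.11
  ms <- tibble::tibble(
    dataset = c("ebov3", "ebov7", "ebov23"),
    assembler = "Trans-ABySS",
    ms = c(14.35, 14.11, 13.87))
  datasets <- tibble::tibble(dataset_id = c("ebov3", "ebov7", "ebov23"),
                             layout = "paired_end",
                             replicate_group = "ebov")
  oms <- overall_metric_score(ms, datasets)
  expect_equal(oms$oms, (14.35 + 14.11 + 13.87) / 3)
  expect_equal(oms$oms, 14.11, tolerance = 1e-10)

  # no groups -> plain sum
  oms2 <- overall_metric_score(ms, NULL)
  expect_equal(oms2$oms, sum(ms$ms))

  # a group of identical values m plus k ungrouped datasets at m -> (k+1)m
  m <- 7.5
  k <- 3
  ms3 <- tibble::tibble(
    dataset = c("g1", "g2", paste0("u", seq_len(k))),
    assembler = "A", ms = m)
  ds3 <- tibble::tibble(dataset_id = ms3$dataset, layout = "paired_end",
                        replicate_group = c("grp", "grp", rep(NA, k)))
  expect_equal(overall_metric_score(ms3, ds3)$oms, (k + 1) * m)

  # incomplete group: mean over available members
  ms4 <- ms[1:2, ]
  expect_equal(overall_metric_score(ms4, datasets)$oms, mean(ms4$ms))
})

test_that("ranking is by descending OMS with lexicographic ties", {
  published <- c(Trinity = 95.9, `SPAdes-sc` = 95.8, `Trans-ABySS` = 94.8,
                 `SPAdes-rna` = 93.3, Bridger = 89.3,
                 `SOAPdenovo-Trans` = 87.3, Shannon = 74.8,
                 `IDBA-Tran` = 73.3, Oases = 62.6, BinPacker = 54.1)
  ranked <- rank_assemblers(sample(published))
  expect_equal(ranked$assembler[1], "Trinity")
  expect_equal(ranked$assembler[10], "BinPacker")
  expect_equal(ranked$assembler, names(published))
  expect_equal(rank_assemblers(c(zeta = 1))$assembler, "zeta")
  expect_equal(rank_assemblers(c(beta = 2, alpha = 2))$assembler,
               c("alpha", "beta"))
  expect_error(rank_assemblers(numeric(0)), "empty")
})

test_that("clustering separates planted quality tiers and is scale-stable", {
  # two identical profiles merge at distance zero
  ms <- tidyr::expand_grid(dataset = c("d1", "d2"),
                           assembler = c("a1", "a2", "a3"))
  ms$ms <- c(5, 5, 1, 5, 5, 1)
  cl <- cluster_profiles(ms)
  expect_equal(min(cl$tree$height), 0)

  # two well-separated tiers (gap 5, noise sd 0.1): the top split
  # separates tier membership exactly
  withr::local_seed(11)
  tiers <- tidyr::expand_grid(dataset = paste0("d", 1:4),
                              assembler = paste0("a", 1:6))
  base <- ifelse(tiers$assembler %in% c("a1", "a2", "a3"), 15, 10)
  tiers$ms <- base + stats::rnorm(nrow(tiers), sd = 0.1)
  cl <- cluster_profiles(tiers)
  split <- stats::cutree(cl$tree, k = 2)
  expect_length(unique(split[c("a1", "a2", "a3")]), 1)
  expect_length(unique(split[c("a4", "a5", "a6")]), 1)
  expect_false(split[["a1"]] == split[["a4"]])

  # duplicating a dataset column scales all distances; leaf order unchanged
  doubled <- dplyr::bind_rows(tiers,
                              dplyr::mutate(tiers, dataset = paste0(dataset, "_copy")))
  expect_equal(cluster_profiles(doubled)$order, cl$order)

  expect_error(cluster_profiles(ms[ms$assembler == "a1", ]), "at least 2")
})

test_that("noise-free planted rankings are recovered exactly", {
  sim <- gen_metric_matrix(n_datasets = 9, noise_sd = 0, seed = 3,
                           quality = seq(1, 0.1, length.out = 10))
  norm <- normalize_matrix(sim$matrix, builtin_registry(), sim$datasets)
  ms <- metric_scores(norm, builtin_registry(), sim$datasets)
  oms <- overall_metric_score(ms, sim$datasets)
  expect_equal(rank_assemblers(oms)$assembler, sim$order)
})
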
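m5 <- repeat_model(k = 5)

test_that("an all-background path yields no regions", {
  p <- fake_path(rep("NR", 40), rep(0L, 40), m5)
  expect_equal(nrow(path_to_regions(p)), 0L)
})

test_that("region starts are adjusted down by one period", {
  kind <- rep("NR", 40); per <- rep(0L, 40)
  kind[11:30] <- "R"; per[11:30] <- 2L   # run over positions 11..30 (1-based)
  p <- fake_path(kind, per, m5)
  r <- path_to_regions(p, min_unit = 2)
  expect_equal(nrow(r), 1L)
  expect_equal(r$run_start, 10L)
  expect_equal(r$start, 8L)              # 10 - p, 0-based half-open
  expect_equal(r$end, 30L)
  # adjustment clamps at zero
  kind2 <- c(rep("R", 12), rep("NR", 8)); per2 <- c(rep(4L, 12), rep(0L, 8))
  r2 <- path_to_regions(fake_path(kind2, per2, m5), min_unit = 2)
  expect_equal(r2$start, 0L)
})

test_that("regions below min_unit full units are dropped", {
  kind <- rep("NR", 30); per <- rep(0L, 30)
  kind[11:18] <- "R"; per[11:18] <- 5L   # 8 positions < 2 units of period 5
  p <- fake_path(kind, per, m5)
  expect_equal(nrow(path_to_regions(p, min_unit = 2)), 0L)
  expect_equal(nrow(path_to_regions(p, min_unit = 0)), 1L)
})

test_that("relaxing min_unit never reports fewer regions", {
  set.seed(21)
  for (i in 1:5) {
    sq <- paste0(random_sequence(400, 0.6, i), strrep("ACT", 5),
                 random_sequence(200, 0.6, i + 50), strrep("GT", 30))
    path <- viterbi_decode(sq, m5)
    n2 <- nrow(path_to_regions(path, min_unit = 2))
    n0 <- nrow(path_to_regions(path, min_unit = 0))
    expect_gte(n0, n2)
  }
})

test_that("region score equals the cumulative-log difference and the term sum", {
  sq <- paste0(random_sequence(60, 0.5, 31), strrep("TTAGGG", 20),
               random_sequence(60, 0.5, 32))
  path <- viterbi_decode(sq, repeat_model(k = 8))
  regions <- path_to_regions(path)
  expect_gte(nrow(regions), 1L)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    s <- score_region(r, path)
    expect_equal(s, r$score, tolerance = 1e-6)
  }
  # empty range scores zero
  r0 <- tibble::tibble(run_start = 10L, end = 10L)
  expect_equal(score_region(r0, path), 0)
  # region not derived from this path
  expect_error(score_region(tibble::tibble(run_start = 0L, end = 10000L),
                            path), "fit")
})

test_that("a perfect repeat outscores a permutation of its letters", {
  m <- repeat_model(k = 5)
  perfect <- strrep("AC", 10)
  set.seed(9)
  perm <- paste(sample(strsplit(perfect, "")[[1]]), collapse = "")
  expect_gt(viterbi_decode(perfect, m)$score,
            viterbi_decode(perm, m)$score)
})

test_that("window-overlap merging unions equal periods and keeps unequal ones", {
  regs <- tibble::tibble(start = c(100L, 180L), end = c(200L, 260L),
                         run_start = c(103L, 183L), period = c(3L, 3L),
                         score = c(10, 12), window = 1:2)
  merged <- merge_window_overlaps(regs)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 100L)
  expect_equal(merged$end, 260L)
  regs$period <- c(3L, 4L)
  kept <- merge_window_overlaps(regs)
  expect_equal(nrow(kept), 2L)
  disjoint <- tibble::tibble(start = c(0L, 500L), end = c(100L, 600L),
                             run_start = c(3L, 503L), period = c(3L, 3L),
                             score = c(5, 6), window = 1:2)
  expect_equal(nrow(merge_window_overlaps(disjoint)), 2L)
  # merged spans are re-scored when the sequence is available
  sq <- paste0(random_sequence(100, 0.5, 3), strrep("ACT", 100),
               random_sequence(100, 0.5, 4))
  r2 <- tibble::tibble(start = c(97L, 200L), end = c(250L, 400L),
                       run_start = c(100L, 203L), period = c(3L, 3L),
                       score = c(50, 60), window = 1:2)
  m2 <- merge_window_overlaps(r2, sequence = sq, model = repeat_model(k = 5))
  expect_equal(nrow(m2), 1L)
  expect_false(is.na(m2$score))
})

test_that("no two reported regions of equal period overlap", {
  sq <- make_synthetic_genome(n_blocks = 8L, block = 1500L, seed = 5L)
  ann <- annotate_repeats(sq, repeat_model(k = 10), split = FALSE,
                          winsize = 4000, overlap = 800)
  by_p <- split(ann, ann$period)
  for (g in by_p) {
    if (nrow(g) < 2L) next
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("annotation output is a tidy per-region tibble", {
  sq <- c(two = paste0(strrep("ACG", 30), strrep("TTAGGG", 15)))
  ann <- annotate_repeats(sq, repeat_model(k = 10))
  expect_s3_class(ann, "tbl_df")
  expect_true(all(c("seq_id", "start", "end", "period", "score", "unit",
                    "n_subrepeats", "subrepeats") %in% names(ann)))
  expect_equal(unique(ann$seq_id), "two")
  expect_true(all(vapply(ann$subrepeats, tibble::is_tibble, TRUE)))
  # subrepeats tile the unadjusted region span
  for (i in seq_len(nrow(ann))) {
    s <- ann$subrepeats[[i]]
    expect_equal(s$start[1], ann$run_start[i])
    expect_equal(s$end[nrow(s)], ann$end[i])
    if (nrow(s) > 1L) expect_equal(s$start[-1], s$end[-nrow(s)])
  }
  # P-values attach when requested and lie in (0, 1]
  ann_p <- annotate_repeats(sq, repeat_model(k = 10), pvalues = TRUE)
  expect_true(all(ann_p$pvalue > 0 & ann_p$pvalue <= 1))
})

test_that("runs of ambiguity letters are not annotated as repeats", {
  sq <- paste0(random_sequence(100, 0.5, 41), strrep("N", 60),
               random_sequence(100, 0.5, 42))
  ann <- annotate_repeats(sq, repeat_model(k = 10))
  if (nrow(ann) > 0L) {
    expect_false(any(ann$start < 160 & ann$end > 100))
  } else succeed()
})
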
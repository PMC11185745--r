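test_that("profile indices advance cyclically, insertions excluded, deletions skip", {
  # decoded worked example: inserted letter gets '*' (0) without breaking
  # the register of the following letters
  path <- viterbi_decode("CATCATCAGTCATCAT", repeat_model(k = 4))
  expect_equal(path$labels$kind[9], "I")
  idx <- assign_profile_indices(path$labels, 3L)
  expect_equal(idx, c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 0L, 3L, 1L, 2L, 3L,
                      1L, 2L, 3L))
  # perfect period-2 repeat
  lab2 <- tibble::tibble(kind = rep("R", 6), del_before = 0L)
  expect_equal(assign_profile_indices(lab2, 2L), rep(1:2, 3))
  # deletion advances the cycle without consuming a letter: after index 2
  # a single deletion makes the next letter index 1 (3 skipped)
  lab3 <- tibble::tibble(kind = rep("R", 6),
                         del_before = c(0L, 0L, 1L, 0L, 0L, 0L))
  expect_equal(assign_profile_indices(lab3, 3L), c(1L, 2L, 1L, 2L, 3L, 1L))
})

test_that("profile divergence matches the halved symmetrized KL sum", {
  L <- matrix(c(0.75, 0.25), nrow = 1)
  R <- matrix(c(0.25, 0.75), nrow = 1)
  expect_equal(jsd(L, R), 0.5 * log(3))
  expect_equal(jsd(L, L), 0)
  set.seed(4)
  for (i in 1:10) {
    A <- matrix(runif(12, 0.05, 1), 3); A <- A / rowSums(A)
    B <- matrix(runif(12, 0.05, 1), 3); B <- B / rowSums(B)
    expect_equal(jsd(A, B), jsd(B, A))
    expect_gte(jsd(A, B), 0)
  }
  expect_error(jsd(L, matrix(0.5, 2, 2)), "shape")
  expect_error(jsd(matrix(c(0, 1), 1), R), "positive")
})

test_that("profiles are pseudocounted and row-normalized", {
  prof <- build_profile("ACACAC", rep(1:2, 3), 2L, pseudocount = 0.5)
  expect_equal(dim(prof), c(2L, 4L))
  expect_equal(rowSums(prof), c(1, 1))
  expect_true(all(prof > 0))
  expect_equal(unname(prof[1, "A"]), 3.5 / 5)
})

test_that("splits are found at pattern changes and nowhere else", {
  # homogeneous repeat: flat divergence, no splits
  hom <- strrep("AC", 100)
  idx <- rep(1:2, 100)
  expect_equal(length(find_splits(hom, idx, 2L)), 0L)
  # one clean change of pattern: one split within 10 letters of the truth
  two <- paste0(strrep("AC", 50), strrep("GC", 50))
  cuts <- find_splits(two, rep(1:2, 100), 2L)
  expect_equal(length(cuts), 1L)
  expect_lte(abs(cuts - 100L), 10L)
  # unreachable threshold: no splits on any input
  expect_equal(length(find_splits(two, rep(1:2, 100), 2L, split_val = Inf)),
               0L)
  # regions shorter than two windows cannot be split
  expect_equal(length(find_splits("ACACAC", rep(1:2, 3), 2L)), 0L)
})

test_that("canonical units are minimal rotations", {
  expect_equal(canonical_unit("GTTG"), "GGTT")
  expect_equal(canonical_unit("AAC"), "AAC")
  expect_equal(canonical_unit("CAT"), "ATC")
  # class function on rotation classes; idempotent
  set.seed(5)
  for (i in 1:20) {
    p <- sample(1:8, 1)
    u <- paste(sample(c("A", "C", "G", "T"), p, TRUE), collapse = "")
    cu <- canonical_unit(u)
    for (r in seq_len(p)) {
      rot <- paste0(substr(u, r, p), substr(u, 1, r - 1))
      expect_equal(canonical_unit(rot), cu)
    }
    expect_equal(canonical_unit(cu), cu)
  }
  expect_error(canonical_unit(""), "empty")
})

test_that("consensus units take the per-index majority with alphabet ties", {
  counts <- matrix(0, nrow = 3, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[1, "A"] <- 5; counts[2, "A"] <- 5; counts[3, "C"] <- 5
  expect_equal(consensus_unit(counts), "AAC")
  counts[3, ] <- 0
  expect_equal(consensus_unit(counts), "AAN")   # no observations
  counts[3, c("A", "C")] <- 4                   # tie -> alphabet order
  expect_equal(consensus_unit(counts), "AAA")
  # majority vote recovers the unit under 10% substitutions
  set.seed(6)
  sq <- mutate_sequence(strrep("AAC", 40), 0.1, seed = 7)
  prof <- tandemscan:::segment_counts(tandemscan:::encode_sequence(sq),
                                      rep(1:3, 40), 3L)
  expect_equal(consensus_unit(prof), "AAC")
})

test_that("rotation-equivalent neighbouring subrepeats are merged", {
  subs <- tibble::tibble(start = c(0L, 40L), end = c(40L, 80L),
                         pattern = c("GTTG", "GGTT"),
                         canonical_unit = canonical_unit(c("GTTG", "GGTT")))
  merged <- merge_equivalent(subs)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$end, 80L)
  subs2 <- tibble::tibble(start = c(0L, 40L), end = c(40L, 80L),
                          pattern = c("AAAC", "GGTT"),
                          canonical_unit = canonical_unit(c("AAAC", "GGTT")))
  expect_equal(nrow(merge_equivalent(subs2)), 2L)
  one <- subs2[1, ]
  expect_equal(merge_equivalent(one), one)
  # applied to fixpoint
  subs3 <- tibble::tibble(start = c(0L, 30L, 60L), end = c(30L, 60L, 90L),
                          pattern = c("AC", "CA", "AC"),
                          canonical_unit = canonical_unit(c("AC", "CA", "AC")))
  expect_equal(nrow(merge_equivalent(subs3)), 1L)
})

test_that("a two-pattern repeat region is split into two named subrepeats", {
  sq <- paste0(strrep("AAAC", 60), strrep("GGTT", 60))
  ann <- annotate_repeats(sq, repeat_model(k = 8))
  expect_equal(nrow(ann), 1L)
  subs <- ann$subrepeats[[1]]
  expect_equal(nrow(subs), 2L)
  expect_equal(sort(subs$canonical_unit), c("AAAC", "GGTT"))
  expect_lte(abs(subs$end[1] - 240L), 10L)
})
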
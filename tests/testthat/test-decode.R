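test_that("a perfect dinucleotide repeat decodes to period-2 repetitive states", {
  p <- viterbi_decode(strrep("AC", 10), repeat_model(k = 5))
  labs <- p$labels
  expect_true(all(labs$kind[3:20] == "R"))
  expect_true(all(labs$period[labs$kind == "R"] == 2L))
})

test_that("repeats are unreachable when nu_in is zero", {
  m <- repeat_model(k = 5, nu_in = 0)
  p <- viterbi_decode(strrep("ACG", 12), m)
  expect_true(all(p$labels$kind == "NR"))
})

test_that("empty and invalid sequences are handled", {
  p <- viterbi_decode("", repeat_model(k = 3))
  expect_equal(p$n, 0L)
  expect_equal(p$score, 0)
  expect_error(viterbi_decode("ACGTB", repeat_model(k = 3)), "position 5")
})

test_that("optimized decoder matches the explicit-state brute force", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    idl <- sample(0:1, 1)
    m <- repeat_model(k = k, max_insert = idl, max_delete = idl,
                      at_richness = runif(1, 0.3, 0.7),
                      match_prob = runif(1, 0.6, 0.9),
                      lambda = runif(1, 0.5, 1),
                      nu_in = 0.02, nu_out = 0.03, indel_open = 0.005)
    n <- sample(15:40, 1)
    sq <- paste(sample(c("A", "C", "G", "T"), n, TRUE, c(.3, .2, .2, .3)),
                collapse = "")
    o <- oracle_viterbi(sq, m)
    d <- viterbi_decode(sq, m)
    expect_equal(d$score, o$score, tolerance = 1e-12)
  }
})

test_that("decoder matches brute force on indel-bearing repeats, with labels", {
  set.seed(12)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    m <- repeat_model(k = k, max_insert = 1, max_delete = 1,
                      match_prob = 0.85, nu_in = 0.02, nu_out = 0.03,
                      indel_open = 0.02)
    p <- sample(2:k, 1)
    unit <- paste(sample(c("A", "C", "G", "T"), p, TRUE), collapse = "")
    chars <- strsplit(strrep(unit, 12), "")[[1]]
    pos <- sample(8:20, 1)
    chars <- if (runif(1) < 0.5) {
      append(chars, sample(c("A", "C", "G", "T"), 1), pos)
    } else chars[-pos]
    sq <- paste(head(chars, 36), collapse = "")
    o <- oracle_viterbi(sq, m)
    d <- viterbi_decode(sq, m)
    expect_equal(d$score, o$score, tolerance = 1e-12)
    # the repetitive/non-repetitive labelling agrees wherever the optimum is
    # unambiguous; compare the repetitive footprint
    expect_equal(d$labels$kind == "NR", o$labels$kind == "NR")
  }
})

test_that("with uniform background, relative and absolute emissions pick the same path", {
  # dividing by a constant E0 shifts every state's per-position score
  # equally, so the argmax path is unchanged
  set.seed(13)
  m <- repeat_model(k = 3, max_insert = 1, max_delete = 1,
                    at_richness = 0.5, nu_in = 0.02, nu_out = 0.03,
                    indel_open = 0.01)
  for (i in 1:5) {
    sq <- paste(c(sample(c("A", "C", "G", "T"), 12, TRUE),
                  strsplit(strrep("AG", 8), "")[[1]]), collapse = "")
    rel <- viterbi_decode(sq, m)
    abs_o <- oracle_viterbi_absolute(sq, m)
    expect_equal(rel$labels$kind, abs_o$labels$kind)
    expect_equal(rel$labels$period, abs_o$labels$period)
    # scores differ by exactly n * log(4) (E0 = 1/4 per position)
    expect_equal(abs_o$score + nchar(sq) * log(4), rel$score,
                 tolerance = 1e-9)
  }
})

test_that("cumulative log-score is additive along the path", {
  sq <- paste0(random_sequence(80, 0.5, 7), strrep("ACT", 30),
               random_sequence(60, 0.5, 8))
  p <- viterbi_decode(sq, repeat_model(k = 6))
  kinds <- c(NR = 0L, R = 1L, I = 2L, J = 3L)
  terms <- tandemscan:::.path_terms(
    p$codes, kinds[p$labels$kind], p$labels$period, p$labels$run,
    p$labels$look_back, p$labels$del_before,
    tandemscan:::model_par_list(p$model))
  expect_equal(p$cumulative_log, cumsum(terms), tolerance = 1e-6)
  t1 <- 50L; t2 <- 150L
  expect_equal(p$cumulative_log[t2] - p$cumulative_log[t1],
               sum(terms[(t1 + 1L):t2]), tolerance = 1e-6)
})

test_that("window plans tile the sequence with the requested overlap", {
  plan <- plan_windows(10000, 126, winsize = 4000, overlap = 1000)
  expect_equal(plan$windows$start, c(0L, 3000L, 6000L))
  expect_equal(plan$windows$end, c(4000L, 7000L, 10000L))
  # single window when the sequence fits
  p1 <- plan_windows(500, 126, winsize = 4000, overlap = 1000)
  expect_equal(nrow(p1$windows), 1L)
  expect_equal(p1$overlap, 0L)
  # more states never enlarge the window
  w <- vapply(c(1e3, 1e4, 1e5, 1e6),
              function(sc) plan_windows(1e7, sc, k = 50)$window_size, 0L)
  expect_true(all(diff(w) <= 0))
  expect_error(plan_windows(10000, 126, winsize = 800, overlap = 1000),
               "overlap")
  # coverage of the sequence, random configurations
  set.seed(3)
  for (i in 1:10) {
    n <- sample(2000:50000, 1)
    pl <- plan_windows(n, sample(100:1e5, 1), k = sample(c(10, 50, 100), 1))
    expect_equal(pl$windows$start[1], 0L)
    expect_equal(max(pl$windows$end), n)
    if (nrow(pl$windows) > 1L) {
      expect_true(all(pl$windows$start[-1] <
                        pl$windows$end[-nrow(pl$windows)]))
    }
  }
})

test_that("memory estimate is the window-matrix product, linear in threads", {
  plan <- plan_windows(10000, 126, winsize = 1000, overlap = 100)
  expect_equal(estimate_memory(plan, 126, threads = 1, cell_bytes = 16),
               1000 * 126 * 16)
  expect_equal(estimate_memory(plan, 126, threads = 2),
               2 * estimate_memory(plan, 126, threads = 1))
})

test_that("windowed decoding agrees with single-window decoding", {
  m <- repeat_model(k = 5)
  sq <- paste0(random_sequence(300, 0.5, 1), strrep("ACT", 40),
               random_sequence(200, 0.5, 2))
  expect_identical(decode_windowed(sq, m)$labels,
                   viterbi_decode(sq, m)$labels)
  # repeat spanning a window boundary: one merged region, same as unwindowed
  sq2 <- paste0(random_sequence(3800, 0.5, 1), strrep("ACT", 140),
                random_sequence(3800, 0.5, 2))
  plan <- plan_windows(nchar(sq2), state_count(m), winsize = 4000,
                       overlap = 1000, k = m$k)
  expect_gt(nrow(plan$windows), 1L)
  rw <- path_to_regions(decode_windowed(sq2, m, plan = plan))
  ru <- path_to_regions(viterbi_decode(sq2, m))
  expect_equal(nrow(rw), 1L)
  expect_equal(rw[c("start", "end", "period")], ru[c("start", "end", "period")])
  expect_equal(rw$score, ru$score, tolerance = 1e-6)
})

test_that("thread count does not change the decoded result", {
  m <- repeat_model(k = 4)
  sq <- paste0(random_sequence(2500, 0.6, 5), strrep("GAAT", 80),
               random_sequence(2500, 0.6, 6))
  plan <- plan_windows(nchar(sq), state_count(m), winsize = 2500,
                       overlap = 600, k = m$k)
  p1 <- decode_windowed(sq, m, plan = plan, threads = 1L)
  p4 <- decode_windowed(sq, m, plan = plan, threads = 4L)
  expect_identical(p1$labels, p4$labels)
  expect_identical(p1$cumulative_log, p4$cumulative_log)
})
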
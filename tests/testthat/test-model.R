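test_that("period prior gamma follows the lambda-decay formula", {
  expect_equal(gamma_period(repeat_model(k = 4, lambda = 1), 2), 0.25)
  expect_equal(gamma_period(repeat_model(k = 2, lambda = 0.5), 1), 2 / 3)
  expect_error(gamma_period(repeat_model(k = 4), 5), "out of range")
  expect_error(gamma_period(repeat_model(k = 4), 0), "out of range")
  # normalization for randomized (lambda, k)
  set.seed(1)
  for (i in 1:20) {
    m <- repeat_model(k = sample(1:200, 1), lambda = runif(1, 0.01, 1))
    expect_equal(sum(gamma_period(m, seq_len(m$k))), 1)
  }
})

test_that("background frequencies reflect AT richness; N is ratio-neutral", {
  expect_equal(background_prob("A", repeat_model(at_richness = 0.5)), 0.25)
  expect_equal(background_prob("G", repeat_model(at_richness = 0.6)), 0.2)
  expect_equal(background_prob("N", repeat_model(at_richness = 0.6)), 1)
  expect_equal(sum(background_probs(repeat_model(at_richness = 0.37))), 1)
  expect_error(background_prob("X", repeat_model()), "alphabet")
})

test_that("repetitive emission favours the look-back letter and normalizes", {
  m9 <- repeat_model(match_prob = 0.9)
  expect_equal(repeat_emission_prob("A", "A", m9), 0.9)
  m7 <- repeat_model(match_prob = 0.7, at_richness = 0.5)
  expect_equal(repeat_emission_prob("C", "A", m7), 0.1)
  for (lb in c("A", "C", "G", "T")) {
    m <- repeat_model(match_prob = 0.77, at_richness = 0.63)
    tot <- sum(vapply(c("A", "C", "G", "T"),
                      repeat_emission_prob, 0, lookback = lb, model = m))
    expect_equal(tot, 1)
  }
  # ambiguity is a guaranteed mismatch
  expect_equal(repeat_emission_prob("N", "A", m9), 0.1)
  expect_equal(repeat_emission_prob("A", "N", m9), 0.1)
})

test_that("explicit state space has the documented size and topology", {
  expect_equal(nrow(build_state_space(
    repeat_model(k = 1, max_insert = 0, max_delete = 0))$states), 2L)
  ss <- build_state_space(repeat_model(k = 5, max_insert = 3, max_delete = 3))
  expect_equal(nrow(ss$states), 126L)
  expect_equal(nrow(ss$states), state_count(ss$model))
  st <- ss$states
  expect_equal(sum(st$kind == "NR"), 1L)
  expect_equal(sort(st$period[st$kind == "R"]), 1:5)
  # closed-form count for random configurations
  set.seed(2)
  for (i in 1:5) {
    m <- repeat_model(k = sample(1:6, 1), max_insert = sample(0:3, 1),
                      max_delete = sample(0:3, 1))
    expect_equal(nrow(build_state_space(m)$states), state_count(m))
  }
})

test_that("J-chain look-backs shift by the indel run length", {
  ss <- build_state_space(repeat_model(k = 5, max_insert = 3, max_delete = 3))
  st <- ss$states
  for (p in 1:5) {
    for (a in 1:3) {
      jj <- st[st$kind == "J" & st$period == p & st$run == a, ]
      expect_equal(nrow(jj), p)
      expect_true(all(jj$look_back == p + a))
    }
    for (j in 1:3) {
      jj <- st[st$kind == "J" & st$period == p & st$run == -j, ]
      expect_true(all(jj$look_back == max(0L, p - j)))
    }
  }
  expect_true(all(st$look_back[st$kind %in% c("NR", "I")] == 0L))
})

test_that("every state's outgoing transition mass sums to 1", {
  for (m in list(repeat_model(k = 4, max_insert = 2, max_delete = 2),
                 repeat_model(k = 3, max_insert = 0, max_delete = 0),
                 repeat_model(k = 2, max_insert = 1, max_delete = 3,
                              indel_extend = 0.5))) {
    ss <- build_state_space(m)
    mass <- tapply(exp(ss$transitions$logp), ss$transitions$from, sum)
    expect_equal(length(mass), nrow(ss$states))
    expect_true(all(abs(mass - 1) < 1e-12))
  }
})

test_that("invalid model parameters are rejected", {
  expect_error(repeat_model(k = 0), "positive")
  expect_error(repeat_model(match_prob = 0.2), "1/4")
  expect_error(repeat_model(lambda = 0), "lambda")
  expect_error(repeat_model(nu_out = 0.9, indel_open = 0.1), "persist")
})

test_that("sequence encoding validates the alphabet and names positions", {
  expect_equal(tandemscan:::encode_sequence("ACGTN"), 1:5)
  expect_equal(tandemscan:::encode_sequence("acgu"), 1:4)
  err <- tryCatch(tandemscan:::encode_sequence("ACGX"), error = conditionMessage)
  expect_match(err, "position 4")
})
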
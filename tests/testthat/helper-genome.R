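# Synthetic genome used by the tuning tests: random 60% AT background
# alternating with mutated tandem-repeat blocks. Repeat units use at least
# three distinct letters so that window-shuffling genuinely destroys the
# repeats (a shuffled homopolymer block would remain repetitive).
make_synthetic_genome <- function(n_blocks = 40L, block = 2500L,
                                  repeat_rate = 0.1, seed = 77L) {
  blocks <- lapply(seq_len(n_blocks), function(i) {
    if (i %% 2L == 0L) {
      unit <- tandemscan:::with_seed(seed + i, {
        repeat {
          p <- sample(3:8, 1)
          u <- paste(sample(c("A", "C", "G", "T"), p, TRUE), collapse = "")
          if (length(unique(strsplit(u, "")[[1]])) >= 3) break
        }
        u
      })
      perfect <- substr(strrep(unit, ceiling(block / nchar(unit))), 1, block)
      mutate_sequence(perfect, repeat_rate, seed = seed + 1000L + i)
    } else {
      random_sequence(block, 0.6, seed = seed + 2000L + i)
    }
  })
  paste(unlist(blocks), collapse = "")
}

# A synthetic decoded_path built directly from labels, for exercising the
# annotation logic on exactly controlled paths.
fake_path <- function(kind, period, model, codes = NULL,
                      run = integer(length(kind)),
                      look_back = ifelse(kind == "R", period, 0L),
                      del_before = integer(length(kind))) {
  n <- length(kind)
  if (is.null(codes)) codes <- rep(1L, n)
  labels <- tibble::tibble(pos = seq_len(n), kind = kind,
                           period = as.integer(period),
                           run = as.integer(run),
                           look_back = as.integer(look_back),
                           del_before = as.integer(del_before))
  kinds <- c(NR = 0L, R = 1L, I = 2L, J = 3L)
  terms <- tandemscan:::.path_terms(codes, kinds[labels$kind], labels$period,
                                    labels$run, labels$look_back,
                                    labels$del_before,
                                    tandemscan:::model_par_list(model))
  structure(list(labels = labels, cumulative_log = cumsum(terms),
                 score = sum(terms), n = n, model = model, codes = codes),
            class = "decoded_path")
}
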
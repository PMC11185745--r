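# Brute-force reference Viterbi over the explicit state space from
# build_state_space(). Materializes every I/D/J state, handles silent
# deletion states by within-column relaxation, and never uses the
# production decoder's implicit J-chain shortcut. Only feasible for tiny
# models/sequences; used as the independent oracle.

oracle_viterbi <- function(sequence, model, relative = TRUE) {
  codes <- if (is.character(sequence)) tandemscan:::encode_sequence(sequence) else sequence
  ss <- build_state_space(model)
  st <- ss$states
  m <- nrow(st)
  n <- length(codes)

  trans_by_to <- split(ss$transitions, ss$transitions$to)
  silent_ids <- st$id[!st$emitting]          # D states, increasing run order
  emit_ids <- st$id[st$emitting]
  nr_id <- st$id[st$kind == "NR"]

  bg <- c(model$at_richness / 2, (1 - model$at_richness) / 2,
          (1 - model$at_richness) / 2, model$at_richness / 2, 1)
  elog <- if (relative) {
    function(t, id) {
      if (st$kind[id] %in% c("NR", "I")) return(0)
      tandemscan:::emission_log_ratio(codes, t, st$look_back[id], model)
    }
  } else {
    # absolute emission probabilities (basic Viterbi)
    function(t, id) {
      L <- st$look_back[id]
      if (st$kind[id] %in% c("NR", "I") || L <= 0L || t - L < 1L) {
        return(log(bg[codes[t]]))
      }
      cur <- codes[t]; lb <- codes[t - L]
      if (cur == 5L || lb == 5L) return(log1p(-model$match_prob))
      if (cur == lb) log(model$match_prob) else {
        log((1 - model$match_prob) * bg[cur] / (1 - bg[lb]))
      }
    }
  }

  val <- matrix(-Inf, nrow = n + 1L, ncol = m)
  bp <- matrix(0L, nrow = n + 1L, ncol = m)
  val[1L, nr_id] <- 0
  for (t in seq_len(n)) {
    for (v in emit_ids) {
      tr <- trans_by_to[[as.character(v)]]
      if (is.null(tr)) next
      cand <- val[t, tr$from] + tr$logp
      b <- which.max(cand)
      val[t + 1L, v] <- cand[b] + elog(t, v)
      bp[t + 1L, v] <- tr$from[b]
    }
    for (v in silent_ids) {  # same-column relaxation (sources have smaller id)
      tr <- trans_by_to[[as.character(v)]]
      if (is.null(tr)) next
      cand <- val[t + 1L, tr$from] + tr$logp
      b <- which.max(cand)
      val[t + 1L, v] <- cand[b]
      bp[t + 1L, v] <- tr$from[b]
    }
  }

  best_id <- emit_ids[which.max(val[n + 1L, emit_ids])]
  score <- val[n + 1L, best_id]

  # traceback over emitting positions; silent states are crossed within a
  # column and recorded as deletions before the following position
  kind <- character(n); period <- integer(n); look_back <- integer(n)
  del_before <- integer(n)
  id <- best_id
  t <- n
  while (t >= 1L) {
    kind[t] <- st$kind[id]; period[t] <- st$period[id]
    look_back[t] <- st$look_back[id]
    prev <- bp[t + 1L, id]
    ndel <- 0L
    # silent D predecessors live in the previous column (deletions occur
    # between emissions); follow their chain back to an emitting state
    while (prev != 0L && !st$emitting[prev]) {
      ndel <- ndel + 1L
      prev <- bp[t, prev]
    }
    del_before[t] <- ndel
    id <- prev
    t <- t - 1L
  }
  list(score = score,
       labels = tibble::tibble(pos = seq_len(n), kind = kind,
                               period = period, look_back = look_back,
                               del_before = del_before))
}

oracle_viterbi_absolute <- function(sequence, model) {
  oracle_viterbi(sequence, model, relative = FALSE)
}
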
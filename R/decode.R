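# Viterbi decoding: single-window decode, window planning, windowed decode.

model_par_list <- function(model) {
  model[c("k", "max_insert", "max_delete", "lambda", "nu_in", "nu_out",
          "match_prob", "at_richness", "indel_open", "indel_extend")]
}

#' Number of states of the explicit HMM
#'
#' Closed form of the explicit state count:
#' `1 + sum_{p=1..k} (1 + i + d + (i + d) * p)`.
#'
#' @param model A [repeat_model()].
#' @return Integer state count.
#' @export
state_count <- function(model) {
  k <- model$k; i <- model$max_insert; d <- model$max_delete
  as.integer(1 + k * (1 + i + d) + (i + d) * k * (k + 1) / 2)
}

new_decoded_path <- function(labels, cumulative_log, score, model, codes) {
  structure(
    list(labels = labels, cumulative_log = cumulative_log,
         score = score, n = nrow(labels), model = model, codes = codes),
    class = "decoded_path"
  )
}

#' @export
print.decoded_path <- function(x, ...) {
  rep_frac <- if (x$n > 0) mean(x$labels$kind != "NR") else 0
  cat(sprintf("<decoded_path> %d positions, %.1f%% repetitive, path score %.2f nats\n",
              x$n, 100 * rep_frac, x$score))
  invisible(x)
}

label_tibble <- function(res) {
  kinds <- c("NR", "R", "I", "J")
  tibble::tibble(
    pos = seq_along(res$kind),
    kind = kinds[res$kind + 1L],
    period = res$period,
    run = res$run,
    look_back = res$look_back,
    del_before = res$del_before
  )
}

#' Viterbi decoding of a sequence
#'
#' Computes the most probable state path of the repeat HMM for a sequence,
#' using relative emission likelihoods (model emission probability divided by
#' the background letter frequency) so that scores are composition-aware.
#' All arithmetic is in natural-log space. Decoding starts in the
#' non-repetitive state with probability 1. Ties are broken deterministically
#' in favour of the non-repetitive state, then smaller periods, then
#' non-indel state kinds.
#'
#' @param sequence A single character string over `A,C,G,T,U,N`
#'   (case-insensitive), or an integer vector of codes 1..5.
#' @param model A [repeat_model()].
#' @return A `decoded_path`: per-position labels (`kind` one of NR/R/I/J,
#'   `period`, `run` — indel run length, `look_back`, `del_before` — number
#'   of silent deletion states crossed immediately before the position),
#'   the running log-score `cumulative_log`, and the total path `score` in
#'   nats. Deleted pattern positions occupy no sequence positions; they are
#'   recorded via `del_before` on the following position.
#' @examples
#' p <- viterbi_decode(strrep("AC", 10), repeat_model(k = 5))
#' table(p$labels$kind, p$labels$period)
#' @export
viterbi_decode <- function(sequence, model = repeat_model()) {
  codes <- if (is.character(sequence)) encode_sequence(sequence) else as.integer(sequence)
  if (length(codes) == 0L) {
    return(new_decoded_path(label_tibble(list(kind = integer(0), period = integer(0),
                                              run = integer(0), look_back = integer(0),
                                              del_before = integer(0))),
                            numeric(0), 0, model, integer(0)))
  }
  res <- .decode_core(codes, model_par_list(model))
  labels <- label_tibble(res)
  terms <- .path_terms(codes, res$kind, res$period, res$run, res$look_back,
                       res$del_before, model_par_list(model))
  new_decoded_path(labels, cumsum(terms), res$score, model, codes)
}

#' Plan decoding windows for a long sequence
#'
#' Splits a sequence into overlapping windows so that the Viterbi matrix for
#' one window fits in a memory budget. The window size shrinks as the state
#' count grows; the overlap is at least `max(1000, 4 * k)` positions so any
#' repeat shorter than the overlap is seen whole by at least one window.
#'
#' @param sequence_length Length of the sequence to decode.
#' @param state_count Explicit state count of the model (see [state_count()]).
#' @param winsize Optional window-size override (positions).
#' @param overlap Optional overlap override (positions).
#' @param mem_budget Memory budget per thread in bytes (default 256 MB).
#' @param k Maximum period of the model (used for the minimum window size
#'   and default overlap).
#' @return A `window_plan`: list with `window_size`, `overlap` and `windows`,
#'   a tibble of 0-based half-open `[start, end)` intervals covering the
#'   sequence, consecutive windows overlapping by exactly `overlap`.
#' @examples
#' plan_windows(10000, 126, winsize = 4000, overlap = 1000)
#' @export
plan_windows <- function(sequence_length, state_count, winsize = NULL,
                         overlap = NULL, mem_budget = 256e6, k = 100L) {
  stopifnot(sequence_length >= 1)
  cell_bytes <- 16
  if (is.null(overlap)) overlap <- max(1000L, 4L * k)
  overlap <- as.integer(overlap)
  if (is.null(winsize)) {
    winsize <- floor(mem_budget / (state_count * cell_bytes))
    winsize <- max(winsize, 10L * k, 2L * overlap)
  }
  winsize <- as.integer(min(winsize, sequence_length))
  if (winsize >= sequence_length) {
    windows <- tibble::tibble(start = 0L, end = as.integer(sequence_length))
    return(structure(list(window_size = winsize, overlap = 0L, windows = windows),
                     class = "window_plan"))
  }
  if (overlap >= winsize) {
    stop(sprintf("overlap (%d) must be smaller than window size (%d)",
                 overlap, winsize))
  }
  step <- winsize - overlap
  starts <- seq(0L, sequence_length - 1L, by = step)
  keep <- c(TRUE, starts[-1] < sequence_length - overlap)
  starts <- starts[keep]
  ends <- pmin(starts + winsize, as.integer(sequence_length))
  structure(list(window_size = winsize, overlap = overlap,
                 windows = tibble::tibble(start = as.integer(starts),
                                          end = as.integer(ends))),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("<window_plan> %d window(s) of size %d, overlap %d\n",
              nrow(x$windows), x$window_size, x$overlap))
  invisible(x)
}

#' Expected decoding memory
#'
#' Rough upper bound of the memory the decoder needs: one Viterbi matrix of
#' `window_size x state_count` cells per thread. Printed for planning; not
#' enforced.
#'
#' @param plan A [plan_windows()] result.
#' @param state_count Explicit model state count.
#' @param threads Number of decoding threads.
#' @param cell_bytes Bytes per matrix cell.
#' @return Estimated bytes.
#' @export
estimate_memory <- function(plan, state_count, threads = 1L, cell_bytes = 16) {
  if (nrow(plan$windows) == 0L || plan$window_size == 0L) return(0)
  as.numeric(plan$window_size) * state_count * cell_bytes * threads
}

#' Windowed Viterbi decoding
#'
#' Decodes a sequence window by window (windows are independent) and
#' stitches the per-window paths into a single path. Within each overlap the
#' seam is placed at a position both windows label as non-repetitive when
#' one exists, otherwise at the overlap midpoint. For a sequence that fits
#' in a single window the result is identical to [viterbi_decode()].
#'
#' @param sequence Character string or integer codes.
#' @param model A [repeat_model()].
#' @param plan Optional [plan_windows()] result; computed from the model and
#'   sequence length when `NULL`.
#' @param threads Number of worker processes for window decoding
#'   (results are deterministic and independent of `threads`).
#' @inheritParams plan_windows
#' @return A `decoded_path` (see [viterbi_decode()]).
#' @export
decode_windowed <- function(sequence, model = repeat_model(), plan = NULL,
                            threads = 1L, winsize = NULL, overlap = NULL,
                            mem_budget = 256e6) {
  codes <- if (is.character(sequence)) encode_sequence(sequence) else as.integer(sequence)
  n <- length(codes)
  if (n == 0L) return(viterbi_decode(codes, model))
  if (is.null(plan)) {
    plan <- plan_windows(n, state_count(model), winsize = winsize,
                         overlap = overlap, mem_budget = mem_budget,
                         k = model$k)
  }
  if (nrow(plan$windows) == 1L) return(viterbi_decode(codes, model))

  par <- model_par_list(model)
  decode_one <- function(i) {
    s <- plan$windows$start[i]; e <- plan$windows$end[i]
    res <- tryCatch(.decode_core(codes[(s + 1L):e], par), error = function(err) {
      stop(sprintf("window %d [%d,%d): %s", i, s, e, conditionMessage(err)))
    })
    res
  }
  nw <- nrow(plan$windows)
  results <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nw), decode_one, mc.cores = threads)
  } else {
    lapply(seq_len(nw), decode_one)
  }

  # stitch: position-wise labels; for each overlap choose a seam position
  kind <- integer(n); period <- integer(n); run <- integer(n)
  look_back <- integer(n); del_before <- integer(n)
  cuts <- integer(nw + 1L)  # window i supplies positions (cuts[i], cuts[i+1]]
  cuts[1L] <- 0L; cuts[nw + 1L] <- n
  for (i in seq_len(nw - 1L)) {
    os <- plan$windows$start[i + 1L]          # overlap [os, oe) 0-based
    oe <- plan$windows$end[i]
    li <- results[[i]]; ri <- results[[i + 1L]]
    rel_l <- (os + 1L):oe - plan$windows$start[i]       # indices in window i
    rel_r <- (os + 1L):oe - plan$windows$start[i + 1L]  # indices in window i+1
    both_nr <- which(li$kind[rel_l] == 0L & ri$kind[rel_r] == 0L)
    cut_rel <- if (length(both_nr) > 0L) {
      both_nr[ceiling(length(both_nr) / 2)]
    } else {
      as.integer(ceiling(length(rel_l) / 2))
    }
    cuts[i + 1L] <- os + cut_rel
  }
  for (i in seq_len(nw)) {
    lo <- cuts[i] + 1L; hi <- cuts[i + 1L]
    if (hi < lo) next
    rel <- (lo:hi) - plan$windows$start[i]
    res <- results[[i]]
    kind[lo:hi] <- res$kind[rel]; period[lo:hi] <- res$period[rel]
    run[lo:hi] <- res$run[rel]; look_back[lo:hi] <- res$look_back[rel]
    del_before[lo:hi] <- res$del_before[rel]
  }
  terms <- .path_terms(codes, kind, period, run, look_back, del_before, par)
  labels <- label_tibble(list(kind = kind, period = period, run = run,
                              look_back = look_back, del_before = del_before))
  cum <- cumsum(terms)
  new_decoded_path(labels, cum, cum[n], model, codes)
}
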
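# Local-shuffle null construction, FDR estimation and grid-search tuning.

#' Shuffle a sequence within local windows
#'
#' Permutes the letters of each non-overlapping window independently,
#' preserving every window's letter multiset. Local shuffling retains
#' regional composition variability (as seen in isochores) while destroying
#' biologically caused tandem repeats, which makes the shuffled sequence a
#' null for estimating false annotation coverage.
#'
#' @param sequence Character string.
#' @param window_size Shuffle window length (>= 2).
#' @param seed Integer seed (deterministic output).
#' @return Shuffled sequence string of the same length.
#' @export
window_shuffle <- function(sequence, window_size = 20000L, seed = 1L) {
  window_size <- as.integer(window_size)
  stopifnot(window_size >= 2L)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n == 0L) return("")
  with_seed(seed, {
    starts <- seq(1L, n, by = window_size)
    for (s in starts) {
      e <- min(s + window_size - 1L, n)
      chars[s:e] <- chars[sample.int(e - s + 1L) + s - 1L]
    }
    paste(chars, collapse = "")
  })
}

#' Fraction of a sequence covered by annotations
#'
#' Length of the union of all region intervals divided by the sequence
#' length; overlapping regions (of different periods) are counted once.
#'
#' @param regions Tibble with `start`, `end` (0-based half-open).
#' @param sequence_length Total sequence length (> 0).
#' @return Fraction in [0, 1].
#' @export
coverage_fraction <- function(regions, sequence_length) {
  stopifnot(sequence_length > 0)
  if (nrow(regions) == 0L) return(0)
  o <- order(regions$start)
  s <- regions$start[o]; e <- regions$end[o]
  tot <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      tot <- tot + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  tot <- tot + (cur_e - cur_s)
  tot / sequence_length
}

#' Estimated false discovery rate from shuffled coverage
#'
#' Repetitive coverage of the locally shuffled sequence divided by the
#' repetitive coverage of the original sequence. Returns `NA` (candidate
#' disqualified) when the original coverage is zero.
#'
#' @param cov_shuffled Coverage fraction on the shuffled sequence.
#' @param cov_original Coverage fraction on the original sequence.
#' @return FDR estimate, or `NA_real_` if undefined.
#' @export
estimate_fdr <- function(cov_shuffled, cov_original) {
  if (is.na(cov_original) || cov_original == 0) return(NA_real_)
  cov_shuffled / cov_original
}

#' Default tuning grid
#'
#' The built-in candidate grid crosses background AT richness
#' (0.3, 0.4, 0.5, 0.6, 0.7) with repeat match probability (0.6, 0.7, 0.9):
#' 15 parameter combinations. Arbitrary grids can be supplied via
#' `tune_config(grid = ...)` or a tune file (one `key=value ...` line per
#' candidate).
#'
#' @param model Base model whose other parameters are kept.
#' @return List of [repeat_model()] candidates.
#' @export
default_tune_grid <- function(model = repeat_model()) {
  grid <- expand.grid(at = c(0.3, 0.4, 0.5, 0.6, 0.7),
                      m = c(0.6, 0.7, 0.9))
  lapply(seq_len(nrow(grid)), function(i) {
    update_model(model, at_richness = grid$at[i], match_prob = grid$m[i])
  })
}

# Rebuild a repeat_model with some parameters replaced (revalidates).
update_model <- function(model, ...) {
  args <- utils::modifyList(
    list(k = model$k, lambda = model$lambda, nu_in = model$nu_in,
         nu_out = model$nu_out, match_prob = model$match_prob,
         at_richness = model$at_richness, indel_open = model$indel_open,
         max_insert = model$max_insert, max_delete = model$max_delete,
         indel_extend = model$indel_extend, min_unit = model$min_unit),
    list(...))
  do.call(repeat_model, args)
}

#' Tuning configuration
#'
#' @param grid List of candidate [repeat_model()]s (default:
#'   [default_tune_grid()]).
#' @param fdr_threshold Maximum acceptable estimated FDR (default 0.10).
#' @param shuffle_window Local-shuffle window size; `NULL` uses the decode
#'   window size of the window plan.
#' @param tune_indel Keep indel states enabled during candidate evaluation?
#'   By default indels are disabled while scoring candidates (much faster)
#'   and re-enabled for the final annotation run with the chosen parameters.
#' @param seed Integer seed for the shuffle.
#' @return Object of class `tune_config`.
#' @export
tune_config <- function(grid = NULL, fdr_threshold = 0.10,
                        shuffle_window = NULL, tune_indel = FALSE,
                        seed = 1L) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  structure(list(grid = grid, fdr_threshold = fdr_threshold,
                 shuffle_window = shuffle_window,
                 tune_indel = isTRUE(tune_indel), seed = as.integer(seed)),
            class = "tune_config")
}

#' Grid-search parameter tuning with a shuffle-based FDR estimate
#'
#' Annotates the input sequence once per candidate parameter set, and a
#' locally shuffled copy of the sequence alongside, estimating each
#' candidate's false discovery rate as shuffled coverage over original
#' coverage. The chosen candidate maximizes coverage among those with FDR at
#' or below the threshold (10% by default). Unless `tune_indel` is set,
#' candidates are evaluated with indel states disabled and the final
#' annotation run re-enables them.
#'
#' @param sequence Character string to tune on.
#' @param model Base model supplying non-tuned parameters.
#' @param config A [tune_config()].
#' @param ... Passed to [annotate_repeats()] (e.g. `winsize`).
#' @return Object of class `tune_result`: `chosen` model (indels enabled;
#'   `NULL` if no candidate qualified), `results` tibble (per-candidate
#'   `at_richness`, `match_prob`, `coverage`, `shuffled_coverage`, `fdr`,
#'   `qualified`), `annotation` from the final run, and `config`.
#' @export
tune_repeat_model <- function(sequence, model = repeat_model(),
                              config = tune_config(), ...) {
  grid <- config$grid
  if (is.null(grid)) grid <- default_tune_grid(model)
  stopifnot(length(grid) > 0L)
  n <- nchar(sequence)
  shuffle_win <- config$shuffle_window
  if (is.null(shuffle_win)) {
    shuffle_win <- plan_windows(n, state_count(model), k = model$k)$window_size
  }
  shuffled <- window_shuffle(sequence, shuffle_win, seed = config$seed)

  rows <- lapply(seq_along(grid), function(i) {
    cand <- grid[[i]]
    eval_model <- if (config$tune_indel) cand else {
      update_model(cand, max_insert = 0L, max_delete = 0L, indel_open = 0)
    }
    cov_o <- coverage_fraction(
      annotate_repeats(sequence, eval_model, split = FALSE, ...), n)
    cov_s <- coverage_fraction(
      annotate_repeats(shuffled, eval_model, split = FALSE, ...), n)
    fdr <- estimate_fdr(cov_s, cov_o)
    tibble::tibble(candidate = i, at_richness = cand$at_richness,
                   match_prob = cand$match_prob, coverage = cov_o,
                   shuffled_coverage = cov_s, fdr = fdr,
                   qualified = !is.na(fdr) & fdr <= config$fdr_threshold)
  })
  results <- dplyr::bind_rows(rows)

  chosen <- NULL
  annotation <- NULL
  q <- which(results$qualified)
  if (length(q) > 0L) {
    best <- q[which.max(results$coverage[q])]
    chosen <- grid[[best]] # indels as in the base candidates (enabled)
    annotation <- annotate_repeats(sequence, chosen, ...)
  }
  structure(list(chosen = chosen, results = results,
                 annotation = annotation, config = config),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result> %d candidates, %d under FDR threshold %.0f%%\n",
              nrow(x$results), sum(x$results$qualified),
              100 * x$config$fdr_threshold))
  if (is.null(x$chosen)) {
    cat("  no qualifying candidate (all FDR estimates above threshold)\n")
  } else {
    b <- x$results[x$results$qualified, ]
    b <- b[which.max(b$coverage), ]
    cat(sprintf("  chosen: at_richness = %g, match_prob = %g (coverage %.3f, FDR %.3f)\n",
                x$chosen$at_richness, x$chosen$match_prob, b$coverage, b$fdr))
  }
  invisible(x)
}

#' @export
tidy.tune_result <- function(x, ...) x$results

#' @export
glance.tune_result <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$results),
    n_qualified = sum(x$results$qualified),
    chosen_at = if (is.null(x$chosen)) NA_real_ else x$chosen$at_richness,
    chosen_match = if (is.null(x$chosen)) NA_real_ else x$chosen$match_prob,
    fdr_threshold = x$config$fdr_threshold
  )
}

#' Read a tuning grid from a file
#'
#' One candidate per line as whitespace-separated `key=value` pairs; keys
#' are [repeat_model()] argument names (e.g.
#' `at_richness=0.4 match_prob=0.7`). Empty lines and `#` comments are
#' skipped.
#'
#' @param path File path.
#' @param model Base model supplying unspecified parameters.
#' @return List of [repeat_model()] candidates.
#' @export
read_tune_file <- function(path, model = repeat_model()) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("tune file contains no candidates: ", path)
  lapply(lines, function(ln) {
    kv <- strsplit(strsplit(ln, "[[:space:]]+")[[1]], "=")
    bad <- lengths(kv) != 2L
    if (any(bad)) stop("malformed tune-file entry: ", ln)
    args <- stats::setNames(lapply(kv, function(x) as.numeric(x[2])),
                            vapply(kv, `[`, "", 1L))
    do.call(update_model, c(list(model = model), args))
  })
}
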
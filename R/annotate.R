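# Converting decoded paths into scored repeat-region annotations.

#' Extract repeat regions from a decoded path
#'
#' Maximal runs of positions not labelled non-repetitive become candidate
#' regions. Each region takes the period of its governing repetitive state,
#' its start is adjusted down by one period (the first `p` letters of a
#' repeat precede the first position the look-back can reward), and regions
#' spanning fewer than `min_unit` full units (measured on the un-adjusted
#' run) are dropped.
#'
#' Coordinates are 0-based half-open throughout the package's internal
#' tables; see [write_annotations()] for the 1-based TSV convention.
#'
#' @param path A `decoded_path` from [viterbi_decode()] or
#'   [decode_windowed()].
#' @param min_unit Minimum number of full repeat units (default: the
#'   model's `min_unit`).
#' @return Tibble with columns `start` (adjusted), `end`, `run_start`
#'   (un-adjusted first path position), `period`, `score` (nats), sorted by
#'   `start`.
#' @export
path_to_regions <- function(path, min_unit = path$model$min_unit) {
  labs <- path$labels
  if (nrow(labs) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          run_start = integer(0), period = integer(0),
                          score = numeric(0)))
  }
  rep_pos <- labs$kind != "NR"
  r <- rle(rep_pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(i) {
    s <- starts[i]; e <- ends[i]
    pv <- labs$period[s:e]
    tab <- table(pv[pv > 0L])
    p <- as.integer(names(tab)[which.max(tab)])  # ties: smallest period
    score <- path$cumulative_log[e] - if (s > 1L) path$cumulative_log[s - 1L] else 0
    list(run_start = s - 1L, end = e, period = p, score = score)
  })
  regions <- dplyr::bind_rows(lapply(out, tibble::as_tibble))
  if (nrow(regions) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          run_start = integer(0), period = integer(0),
                          score = numeric(0)))
  }
  regions <- regions[regions$end - regions$run_start >=
                       min_unit * regions$period, , drop = FALSE]
  regions$start <- pmax(0L, regions$run_start - regions$period)
  regions <- regions[order(regions$start), c("start", "end", "run_start",
                                             "period", "score")]
  tibble::as_tibble(regions)
}

#' Score a repeat region
#'
#' The region score is the sum of log transition plus log relative-emission
#' terms along the Viterbi path across the region, which equals the
#' difference of the path's cumulative log-score at the region's ends. Both
#' formulations are computed and checked against each other (they must agree
#' within 1e-6).
#'
#' @param region A one-row region (as from [path_to_regions()]), or a list
#'   with `run_start` and `end`.
#' @param path The `decoded_path` the region was derived from.
#' @return Score in nats.
#' @export
score_region <- function(region, path) {
  rs <- region$run_start[1]; e <- region$end[1]
  if (e < rs) stop("region end precedes start")
  if (e > path$n) stop("region does not fit the decoded path")
  if (e == rs) return(0)
  diff_form <- path$cumulative_log[e] -
    (if (rs > 0L) path$cumulative_log[rs] else 0)
  labs <- path$labels
  kinds <- c(NR = 0L, R = 1L, I = 2L, J = 3L)
  terms <- .path_terms(path$codes, kinds[labs$kind], labs$period, labs$run,
                       labs$look_back, labs$del_before,
                       model_par_list(path$model))
  sum_form <- sum(terms[(rs + 1L):e])
  if (!isTRUE(all.equal(diff_form, sum_form, tolerance = 1e-6))) {
    stop("score formulations disagree; region does not match this path")
  }
  sum_form
}

#' Merge overlapping repeat regions from adjacent windows
#'
#' Regions discovered independently in overlapping decode windows are merged
#' when they overlap and have the same repetitive period; overlapping
#' regions of unequal period are both kept. Merged regions are re-scored by
#' decoding the merged span as a single window (when the sequence is
#' supplied), avoiding double-counted overlap scores.
#'
#' @param regions Tibble of regions (columns `start`, `end`, `run_start`,
#'   `period`, `score`, optionally `window` provenance).
#' @param sequence Optional sequence (string or codes) for re-scoring merged
#'   regions; when absent, merged regions get `NA` scores.
#' @param model Model used for re-scoring.
#' @return Tibble of merged regions sorted by `start`.
#' @export
merge_window_overlaps <- function(regions, sequence = NULL, model = NULL) {
  if (nrow(regions) == 0L) return(regions)
  pieces <- lapply(split(regions, regions$period), function(gr) {
    gr <- gr[order(gr$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(gr$start[-1] >= cummax(gr$end)[-nrow(gr)])))
    merged <- dplyr::group_by(gr, grp = grp)
    merged <- dplyr::summarise(
      merged,
      start = min(.data$start), end = max(.data$end),
      run_start = min(.data$run_start), period = .data$period[1],
      score = if (dplyr::n() == 1L) .data$score[1] else NA_real_,
      .groups = "drop"
    )
    merged$grp <- NULL
    merged
  })
  out <- dplyr::bind_rows(pieces)
  needs <- which(is.na(out$score))
  if (length(needs) > 0L && !is.null(sequence)) {
    codes <- if (is.character(sequence)) encode_sequence(sequence) else as.integer(sequence)
    for (i in needs) {
      span <- codes[(out$run_start[i] + 1L):out$end[i]]
      out$score[i] <- viterbi_decode(span, model)$score
    }
  }
  out <- out[order(out$start, out$period), , drop = FALSE]
  tibble::as_tibble(out)
}

#' Annotate tandem repeats in sequences
#'
#' The top-level annotation pipeline: decode each sequence with the windowed
#' Viterbi algorithm, convert the state path into scored repeat regions,
#' optionally split each region into subrepeats at changes of repetitive
#' pattern, and optionally attach P-values calibrated against random
#' sequence.
#'
#' @param x Sequences: a (possibly named) character vector, a
#'   `Biostrings::DNAStringSet`, the path to a FASTA file, or a tibble from
#'   [read_fasta()].
#' @param model A [repeat_model()].
#' @param split Split regions into subrepeats at pattern changes?
#' @param split_val Threshold on the windowed Jensen-Shannon divergence for
#'   declaring a repeat split; `NULL` uses the calibrated default (which
#'   scales with the region's period; see [find_splits()]).
#' @param pvalues Attach P-values? Requires `fit` (or uses the packaged
#'   default calibration when `fit = NULL`).
#' @param fit A `score_dist_fit` from [calibrate_scores()] (or
#'   [score_dist_fit()] with explicit location/scale/frequency).
#' @param min_unit Override of the model's minimum reported unit count.
#' @param winsize,overlap,mem_budget,threads Windowing controls; see
#'   [plan_windows()] and [decode_windowed()].
#' @return A tibble with one row per repeat region: `seq_id`, `start`,
#'   `end` (0-based half-open, start adjusted down by one period), `period`,
#'   `score` (nats), `pvalue` (if requested), `unit` (canonical consensus
#'   repeat unit), `n_subrepeats` and `subrepeats` (list-column of tibbles
#'   with `start`, `end`, `pattern`, `canonical_unit`).
#' @examples
#' annotate_repeats(c(rpt = paste0(strrep("ACG", 30), strrep("TTAGGG", 15))),
#'                  model = repeat_model(k = 10))
#' @export
annotate_repeats <- function(x, model = repeat_model(), split = TRUE,
                             split_val = NULL, pvalues = FALSE, fit = NULL,
                             min_unit = model$min_unit, winsize = NULL,
                             overlap = NULL, mem_budget = 256e6,
                             threads = 1L) {
  seqs <- as_sequences(x)
  res <- lapply(seq_along(seqs), function(si) {
    sq <- toupper(seqs[[si]])
    path <- decode_windowed(sq, model, threads = threads, winsize = winsize,
                            overlap = overlap, mem_budget = mem_budget)
    regions <- path_to_regions(path, min_unit = min_unit)
    if (nrow(regions) == 0L) return(NULL)
    regions$seq_id <- names(seqs)[si]
    if (split) {
      subs <- lapply(seq_len(nrow(regions)), function(ri) {
        split_region(path, regions[ri, ], split_val = split_val)
      })
      regions$unit <- vapply(subs, function(s) attr(s, "region_unit"), "")
      regions$n_subrepeats <- vapply(subs, nrow, 0L)
      regions$subrepeats <- lapply(subs, function(s) {
        attr(s, "region_unit") <- NULL
        s
      })
    } else {
      regions$unit <- vapply(seq_len(nrow(regions)), function(ri) {
        region_consensus(path, regions[ri, ])
      }, "")
      regions$n_subrepeats <- 1L
      regions$subrepeats <- lapply(seq_len(nrow(regions)), function(ri) {
        tibble::tibble(start = regions$run_start[ri], end = regions$end[ri],
                       pattern = regions$unit[ri],
                       canonical_unit = regions$unit[ri])
      })
    }
    regions
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(seq_id = character(0), start = integer(0),
                          end = integer(0), run_start = integer(0),
                          period = integer(0), score = numeric(0),
                          unit = character(0), n_subrepeats = integer(0),
                          subrepeats = list())
  }
  if (pvalues) {
    if (is.null(fit)) fit <- default_score_fit()
    out$pvalue <- pvalue(out$score, fit)
  }
  cols <- c("seq_id", "start", "end", "run_start", "period", "score",
            if (pvalues) "pvalue", "unit", "n_subrepeats", "subrepeats")
  out <- out[order(out$seq_id, out$start), cols]
  tibble::as_tibble(out)
}

# Normalize sequence input to a named list of character strings.
as_sequences <- function(x) {
  if (inherits(x, "DNAStringSet") || inherits(x, "BStringSet") ||
      inherits(x, "RNAStringSet")) {
    seqs <- as.character(x)
  } else if (is.data.frame(x) && all(c("id", "sequence") %in% names(x))) {
    seqs <- stats::setNames(x$sequence, x$id)
  } else if (is.character(x) && length(x) == 1L && !grepl("[ACGTUNacgtun]{20,}", x) &&
             file.exists(x)) {
    fa <- read_fasta(x)
    seqs <- stats::setNames(fa$sequence, fa$id)
  } else if (is.character(x)) {
    seqs <- x
  } else {
    stop("cannot interpret `x` as sequences")
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  names(seqs)[names(seqs) == ""] <- paste0("seq", which(names(seqs) == ""))
  as.list(seqs)
}
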
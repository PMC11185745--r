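# ggplot2 diagnostics.

#' Plot the null score distribution and its exponential fit
#'
#' Log-scale survival plot of region scores with the fitted curve
#' `omega * exp((mu - s) / sigma)` overlaid; on random sequence the points
#' should fall on the line (exponential decay of null scores).
#'
#' @param scores Numeric vector of region scores (e.g. from annotating
#'   random sequence).
#' @param fit A [score_dist_fit()].
#' @return A ggplot object.
#' @export
plot_score_survival <- function(scores, fit) {
  s <- sort(scores)
  df <- tibble::tibble(
    score = s,
    survival = fit$omega * (length(s):1) / length(s),
    fitted = fit$omega * exp((fit$mu - s) / fit$sigma)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$survival), size = 0.6,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "region score (nats)",
                  y = "null survival  ω·P(score ≥ s)",
                  title = "Null annotation-score distribution") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.score_dist_fit <- function(object, scores = NULL, ...) {
  if (is.null(scores)) stop("supply the null `scores` used for the fit")
  plot_score_survival(scores, object)
}

#' Plot annotated repeat regions along a sequence
#'
#' @param annotation Tibble from [annotate_repeats()].
#' @param seq_id Sequence to show (default: first).
#' @return A ggplot object with one segment per region, height = score.
#' @export
plot_regions <- function(annotation, seq_id = NULL) {
  if (is.null(seq_id)) seq_id <- annotation$seq_id[1]
  df <- annotation[annotation$seq_id == seq_id, , drop = FALSE]
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$score, yend = .data$score,
                                       colour = factor(.data$period)),
                          linewidth = 2) +
    ggplot2::labs(x = "position (0-based)", y = "score (nats)",
                  colour = "period", title = seq_id) +
    ggplot2::theme_minimal()
}

#' Plot the sliding divergence series used for repeat splitting
#'
#' Shows the windowed profile divergence along one region of a decoded
#' path, with detected splits marked; peaks above the threshold indicate a
#' change of repetitive pattern.
#'
#' @param path A `decoded_path`.
#' @param region One-row region tibble (from [path_to_regions()]).
#' @param split_val,window See [find_splits()].
#' @return A ggplot object.
#' @export
plot_split_profile <- function(path, region, split_val = NULL, window = NULL) {
  p <- region$period
  span <- (region$run_start + 1L):region$end
  letters <- path$codes[span]
  idx <- assign_profile_indices(path$labels[span, ], p)
  if (is.null(window)) window <- max(4L * p, 24L)
  if (is.null(split_val)) split_val <- default_split_val(p)
  series <- .jsd_series(letters, idx, as.integer(p), as.integer(window), 0.5)
  cuts <- find_splits(letters, idx, p, split_val = split_val, window = window)
  df <- tibble::tibble(pos = region$run_start + seq_along(series),
                       jsd = series)
  gg <- ggplot2::ggplot(df[!is.na(df$jsd), ],
                        ggplot2::aes(x = .data$pos, y = .data$jsd)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = split_val, linetype = 2,
                        colour = "red3") +
    ggplot2::labs(x = "position (0-based)", y = "profile divergence (nats)",
                  title = sprintf("period %d region [%d, %d)", p,
                                  region$start, region$end)) +
    ggplot2::theme_minimal()
  if (length(cuts) > 0L) {
    gg <- gg + ggplot2::geom_vline(xintercept = region$run_start + cuts,
                                   colour = "blue3", linetype = 3)
  }
  gg
}

#' Plot tuning results
#'
#' Coverage against estimated FDR for every tuning candidate; qualifying
#' candidates (FDR at or below the threshold) are highlighted and the
#' chosen one labelled.
#'
#' @param object A `tune_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tune_result <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fdr, y = .data$coverage,
                                   colour = .data$qualified)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$config$fdr_threshold,
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "estimated FDR (shuffled / original coverage)",
                  y = "annotation coverage",
                  title = "Parameter tuning under the shuffle-FDR constraint") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
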
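# Null score-distribution calibration and P-values.

#' Fit a location-scale exponential to annotation scores
#'
#' Maximum-likelihood fit of an exponential distribution with location
#' `mu` and scale `sigma` to a sample of scores: `mu` is the sample minimum
#' and `sigma` the mean excess over it.
#'
#' @param scores Numeric vector of at least 2 region scores.
#' @return List with `mu` and `sigma`.
#' @examples
#' fit_exponential(c(1, 2, 3)) # mu 1, sigma 1
#' @export
fit_exponential <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 scores to fit")
  mu <- min(scores)
  sigma <- mean(scores) - mu
  if (sigma <= 0) stop("degenerate fit: all scores equal (scale would be 0)")
  list(mu = mu, sigma = sigma)
}

#' Null score distribution fit
#'
#' Bundles the three constants that parameterize the distribution of
#' annotation scores in random sequence: the exponential location `mu` and
#' scale `sigma`, and `omega`, the fraction of letters annotated as
#' repetitive in random sequence.
#'
#' @param mu Location (score units, nats).
#' @param sigma Scale (score units, > 0).
#' @param omega Repetitive fraction of null sequence, in `[0, 1]`.
#' @param n_regions,null_length,seed Optional calibration metadata.
#' @return Object of class `score_dist_fit`.
#' @export
score_dist_fit <- function(mu, sigma, omega, n_regions = NA_integer_,
                           null_length = NA_real_, seed = NA_integer_) {
  stopifnot("sigma must be > 0" = sigma > 0,
            "omega must be in [0, 1]" = omega >= 0 && omega <= 1)
  structure(list(mu = mu, sigma = sigma, omega = omega,
                 n_regions = n_regions, null_length = null_length,
                 seed = seed),
            class = "score_dist_fit")
}

#' @export
print.score_dist_fit <- function(x, ...) {
  cat(sprintf("<score_dist_fit> mu = %.4g, sigma = %.4g, omega = %.4g\n",
              x$mu, x$sigma, x$omega))
  if (!is.na(x$n_regions)) {
    cat(sprintf("  calibrated on %g null letters (%d regions, seed %d)\n",
                x$null_length, x$n_regions, x$seed))
  }
  invisible(x)
}

#' @export
tidy.score_dist_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma", "omega"),
                 estimate = c(x$mu, x$sigma, x$omega))
}

#' @export
glance.score_dist_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, omega = x$omega,
                 n_regions = x$n_regions, null_length = x$null_length,
                 seed = x$seed)
}

#' P-value of an annotation score
#'
#' Probability of a random-sequence annotation attaining score `s` or
#' greater: `omega * exp((mu - s) / sigma)`, clamped at 1. Strictly
#' decreasing in `s`; equals `omega` at `s = mu`.
#'
#' @param score Annotation score(s) in nats.
#' @param fit A [score_dist_fit()].
#' @return P-value(s) in `[0, 1]`.
#' @export
pvalue <- function(score, fit) {
  pmin(1, fit$omega * exp((fit$mu - score) / fit$sigma))
}

#' Calibrate the null score distribution on random sequence
#'
#' Generates random sequence at the model's background composition,
#' annotates it with the model, and summarizes the resulting null
#' annotations: `omega` is the fraction of letters covered by annotations
#' and `(mu, sigma)` the exponential fit to the region scores.
#'
#' @param null_length Length of random sequence to generate. A
#'   production-grade calibration uses hundreds of Mb; a few Mb give a
#'   stable fit for testing (the scale `sigma` is typically stable within
#'   ~10% across seeds at 10 Mb).
#' @param model A [repeat_model()].
#' @param seed Integer seed for the null sequence.
#' @param chunk Sequence is generated and annotated in chunks of this size
#'   to bound memory (each chunk is decoded windowed as usual).
#' @param ... Passed to [annotate_repeats()] (e.g. `winsize`).
#' @return A [score_dist_fit()] with calibration metadata.
#' @export
calibrate_scores <- function(null_length, model = repeat_model(), seed = 1L,
                             chunk = 2e6, ...) {
  null_length <- as.numeric(null_length)
  stopifnot(null_length >= 1)
  n_chunks <- ceiling(null_length / chunk)
  scores <- list()
  covered <- 0
  for (ci in seq_len(n_chunks)) {
    len <- min(chunk, null_length - (ci - 1) * chunk)
    sq <- random_sequence(len, at_richness = model$at_richness,
                          seed = seed + ci - 1L)
    ann <- annotate_repeats(sq, model = model, split = FALSE, ...)
    if (nrow(ann) > 0L) {
      scores[[ci]] <- ann$score
      covered <- covered + coverage_fraction(ann, len) * len
    }
  }
  scores <- unlist(scores)
  if (length(scores) == 0L) stop("calibration failed: no null annotations")
  if (length(scores) < 1000L) {
    warning(sprintf("only %d null annotations; consider a longer null sequence",
                    length(scores)))
  }
  fe <- fit_exponential(scores)
  score_dist_fit(fe$mu, fe$sigma, covered / null_length,
                 n_regions = length(scores), null_length = null_length,
                 seed = as.integer(seed))
}

# Packaged default P-value parameters (--ploc, --pscale, --pfreq
# equivalents). Produced by calibrate_scores(1e7, repeat_model(), seed = 101,
# winsize = 20000); regenerate with data-raw/default_fit.R after changing
# model defaults.
default_score_fit <- function() {
  score_dist_fit(mu = 3.586358621, sigma = 1.196802429, omega = 0.0006069,
                 n_regions = 277L, null_length = 1e7, seed = 101L)
}
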
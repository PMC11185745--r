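# Model parameterization and explicit state-space construction for the
# context-sensitive repeat HMM.

DNA_LETTERS <- c("A", "C", "G", "T")
AMBIGUITY <- "N"

#' Define a tandem-repeat HMM model
#'
#' Constructs the parameter set of the context-sensitive hidden Markov model
#' used throughout the package. The model has one non-repetitive (background)
#' state and, for every period `p` in `1..k`, a repetitive state whose
#' emission distribution favours repeating the letter observed `p` positions
#' back. Insertions and deletions are modelled by period-specific indel
#' states: up to `max_insert` consecutive insertions and `max_delete`
#' consecutive deletions, each followed by a chain of `p` offset-recovery
#' (J) states that carries the shifted look-back until the path returns to
#' the main repetitive state.
#'
#' @param k Maximum repeat period modelled (positive integer).
#' @param lambda Period decay parameter in (0, 1]. The prior probability of
#'   entering a period-`p` repeat decays geometrically: see [gamma_period()].
#' @param nu_in Probability of entering a repetitive state from the
#'   non-repetitive state.
#' @param nu_out Probability of leaving a repetitive state back to the
#'   non-repetitive state.
#' @param match_prob Probability that a repetitive state repeats the letter
#'   observed one period back, `Pr[S_t = S_(t-p)]`. Must exceed `1/4` (the
#'   uniform chance) and be below 1.
#' @param at_richness Fraction of A+T in the background composition, in
#'   (0, 1). Background frequencies are `P(A) = P(T) = at_richness/2` and
#'   `P(C) = P(G) = (1 - at_richness)/2`.
#' @param indel_open Probability of opening an insertion (and, separately, a
#'   deletion) from a repetitive state.
#' @param max_insert Maximum number of consecutive insertion states.
#' @param max_delete Maximum number of consecutive deletion states. For a
#'   period-`p` repeat only up to `min(max_delete, p - 1)` deletions are
#'   usable (a deletion shortens the look-back to `p - j`, which must stay
#'   at least 1).
#' @param indel_extend Probability of extending a run of consecutive
#'   insertions (or deletions) by one more indel state.
#' @param min_unit Minimum number of full repeat units a reported annotation
#'   must span (applied to the un-adjusted region length). Use 0 to disable
#'   filtering.
#'
#' @return An object of class `repeat_model`: a named list of validated
#'   parameters.
#' @examples
#' m <- repeat_model(k = 10)
#' gamma_period(m, 1:10)
#' @export
repeat_model <- function(k = 100L,
                         lambda = 0.85,
                         nu_in = 0.01,
                         nu_out = 0.02,
                         match_prob = 0.8,
                         at_richness = 0.6,
                         indel_open = 0.001,
                         max_insert = 10L,
                         max_delete = 10L,
                         indel_extend = 0.2,
                         min_unit = 2) {
  k <- as.integer(k)
  max_insert <- as.integer(max_insert)
  max_delete <- as.integer(max_delete)
  stopifnot(
    "k must be a positive integer" = length(k) == 1L && !is.na(k) && k >= 1L,
    "lambda must be in (0, 1]" = is.numeric(lambda) && lambda > 0 && lambda <= 1,
    "nu_in must be in [0, 1]" = nu_in >= 0 && nu_in <= 1,
    "nu_out must be in [0, 1]" = nu_out >= 0 && nu_out <= 1,
    "match_prob must be in (1/4, 1)" = match_prob > 0.25 && match_prob < 1,
    "at_richness must be in (0, 1)" = at_richness > 0 && at_richness < 1,
    "indel_open must be in [0, 1]" = indel_open >= 0 && indel_open <= 1,
    "max_insert must be >= 0" = max_insert >= 0L,
    "max_delete must be >= 0" = max_delete >= 0L,
    "indel_extend must be in [0, 1)" = indel_extend >= 0 && indel_extend < 1,
    "min_unit must be >= 0" = min_unit >= 0
  )
  if (nu_in + (1 - nu_in) < 0) stop("invalid nu_in")
  # Repetitive-state outgoing mass: self + nu_out + up to two indel openings.
  if (nu_out + 2 * indel_open >= 1) {
    stop("nu_out + 2 * indel_open must be < 1 so repetitive states can persist")
  }
  if (max_delete >= k && max_delete > 0 && k == 1L && indel_open > 0) {
    # deletions are unusable at k = 1; they are pruned rather than an error
  }
  structure(
    list(
      k = k, lambda = lambda, nu_in = nu_in, nu_out = nu_out,
      match_prob = match_prob, at_richness = at_richness,
      indel_open = indel_open, max_insert = max_insert,
      max_delete = max_delete, indel_extend = indel_extend,
      min_unit = min_unit
    ),
    class = "repeat_model"
  )
}

#' @export
print.repeat_model <- function(x, ...) {
  cat("<repeat_model>\n")
  cat(sprintf("  max period k        : %d\n", x$k))
  cat(sprintf("  lambda (period decay): %g\n", x$lambda))
  cat(sprintf("  nu_in / nu_out       : %g / %g\n", x$nu_in, x$nu_out))
  cat(sprintf("  match probability    : %g\n", x$match_prob))
  cat(sprintf("  AT richness          : %g\n", x$at_richness))
  cat(sprintf("  indel open/extend    : %g / %g (i = %d, d = %d)\n",
              x$indel_open, x$indel_extend, x$max_insert, x$max_delete))
  cat(sprintf("  min_unit             : %g\n", x$min_unit))
  invisible(x)
}

#' Period prior of the repeat model
#'
#' Probability of entering a period-`p` repetitive state from the
#' non-repetitive state, relative to other periods:
#' `gamma_p = lambda^p / sum_{i=1..k} lambda^i`. Larger periods are less
#' likely a priori; `lambda = 1` makes all periods equally likely.
#'
#' @param model A [repeat_model()].
#' @param p Period(s), each in `1..k`.
#' @return Numeric vector of probabilities summing to 1 over `p = 1..k`.
#' @export
gamma_period <- function(model, p) {
  p <- as.integer(p)
  if (any(is.na(p)) || any(p < 1L) || any(p > model$k)) {
    stop("period p out of range 1..k")
  }
  model$lambda^p / sum(model$lambda^seq_len(model$k))
}

#' Background letter frequencies
#'
#' @param model A [repeat_model()].
#' @return Named numeric vector over A, C, G, T with
#'   `P(A) = P(T) = at_richness / 2` and `P(C) = P(G) = (1 - at_richness)/2`.
#' @export
background_probs <- function(model) {
  at <- model$at_richness
  c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
}

#' Background probability of a single letter
#'
#' The ambiguity letter `N` is ratio-neutral: it is assigned the value 1 so
#' that its relative emission likelihood (emission over background) is 1 in
#' every context-blind state.
#'
#' @param letter A single letter in `A, C, G, T, N` (case-insensitive).
#' @param model A [repeat_model()].
#' @return A probability (or 1 for `N`).
#' @export
background_prob <- function(letter, model) {
  letter <- toupper(letter)
  if (letter == AMBIGUITY) return(1)
  bg <- background_probs(model)
  if (!letter %in% names(bg)) stop("letter outside alphabet: ", letter)
  unname(bg[[letter]])
}

#' Emission probability of a repetitive state
#'
#' A period-`p` repetitive state at position `t` emits the letter seen at
#' `t - p` with probability `match_prob`; the remaining `1 - match_prob` is
#' distributed over the three mismatching letters proportionally to their
#' background frequencies. The ambiguity letter `N` (as either the current
#' or the look-back letter) is treated as a guaranteed mismatch.
#'
#' @param current Letter emitted at the current position.
#' @param lookback Letter observed one period back.
#' @param model A [repeat_model()].
#' @return Emission probability; sums to 1 over `current` in A,C,G,T for any
#'   fixed `lookback`.
#' @export
repeat_emission_prob <- function(current, lookback, model) {
  current <- toupper(current)
  lookback <- toupper(lookback)
  m <- model$match_prob
  bg <- background_probs(model)
  if (current == AMBIGUITY || lookback == AMBIGUITY) {
    return(1 - m)
  }
  if (!current %in% names(bg)) stop("letter outside alphabet: ", current)
  if (!lookback %in% names(bg)) stop("letter outside alphabet: ", lookback)
  if (current == lookback) {
    m
  } else {
    (1 - m) * unname(bg[[current]]) / (1 - unname(bg[[lookback]]))
  }
}

# Usable deletion-run bound for period p: a run of j deletions leaves the
# following J-chain with look-back p - j, which must stay >= 1.
usable_deletes <- function(model, p) {
  min(model$max_delete, p - 1L)
}

#' Construct the explicit HMM state space
#'
#' Enumerates every state of the model: one non-repetitive (NR) state and,
#' per period `p`, one repetitive (R) state, `max_insert` insertion (I)
#' states, `max_delete` deletion (D) states, and a chain of `p`
#' offset-recovery (J) states for every I and D run length. The explicit
#' state count is therefore
#' `1 + sum_p (1 + i + d + (i + d) * p)`.
#'
#' The production decoder never materializes this space (J-chains are forced
#' and handled implicitly); the explicit enumeration exists for inspection,
#' for the brute-force reference decoder used in tests, and to document the
#' topology. Deletion states whose run length `j >= p` are enumerated but
#' unreachable (no incoming transitions): a deletion run must leave look-back
#' `p - j >= 1`.
#'
#' @param model A [repeat_model()].
#' @return An object of class `state_space`: a list with
#'   * `states`: tibble with columns `id`, `kind` (NR/R/I/D/J), `period`,
#'     `run` (indel run length; NA for NR/R), `phase` (position within a
#'     J-chain; NA otherwise), `look_back`, `emitting`;
#'   * `transitions`: tibble with columns `from`, `to`, `logp`.
#' @examples
#' ss <- build_state_space(repeat_model(k = 2, max_insert = 1, max_delete = 1))
#' nrow(ss$states)
#' @export
build_state_space <- function(model) {
  k <- model$k; i <- model$max_insert; d <- model$max_delete
  rows <- list()
  add <- function(kind, period, run, phase, look_back, emitting) {
    rows[[length(rows) + 1L]] <<- list(
      kind = kind, period = period, run = run, phase = phase,
      look_back = look_back, emitting = emitting
    )
  }
  add("NR", 0L, NA_integer_, NA_integer_, 0L, TRUE)
  for (p in seq_len(k)) {
    add("R", p, NA_integer_, NA_integer_, p, TRUE)
    for (a in seq_len(i)) add("I", p, a, NA_integer_, 0L, TRUE)
    for (j in seq_len(d)) add("D", p, j, NA_integer_, 0L, FALSE)
    for (a in seq_len(i)) {
      for (ph in seq_len(p)) add("J", p, a, ph, p + a, TRUE)
    }
    for (j in seq_len(d)) {
      for (ph in seq_len(p)) add("J", p, -j, ph, max(0L, p - j), TRUE)
    }
  }
  states <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  states$id <- seq_len(nrow(states))
  states <- states[, c("id", "kind", "period", "run", "phase", "look_back",
                       "emitting")]

  # index helpers (J runs are signed: +a for insertion chains, -j for deletion)
  sid <- function(kind, period = 0L, run = NA_integer_, phase = NA_integer_) {
    hit <- states$kind == kind & states$period == period &
      (is.na(run) & is.na(states$run) | !is.na(run) & !is.na(states$run) &
         states$run == run) &
      (is.na(phase) & is.na(states$phase) | !is.na(phase) &
         !is.na(states$phase) & states$phase == phase)
    states$id[which(hit)]
  }

  gam <- gamma_period(model, seq_len(k))
  tr <- list()
  addt <- function(from, to, prob) {
    if (prob > 0) {
      tr[[length(tr) + 1L]] <<- list(from = from, to = to, logp = log(prob))
    }
  }
  nr <- sid("NR")
  addt(nr, nr, 1 - model$nu_in)
  for (p in seq_len(k)) {
    rp <- sid("R", p)
    addt(nr, rp, model$nu_in * gam[p])
    open_i <- if (i >= 1L) model$indel_open else 0
    open_d <- if (usable_deletes(model, p) >= 1L) model$indel_open else 0
    addt(rp, rp, 1 - model$nu_out - open_i - open_d)
    addt(rp, nr, model$nu_out)
    if (open_i > 0) addt(rp, sid("I", p, 1L), open_i)
    if (open_d > 0) addt(rp, sid("D", p, 1L), open_d)
    for (a in seq_len(i)) {
      ia <- sid("I", p, a)
      cont <- if (a < i) model$indel_extend else 0
      if (cont > 0) addt(ia, sid("I", p, a + 1L), cont)
      addt(ia, sid("J", p, a, 1L), 1 - cont)
    }
    dmax <- usable_deletes(model, p)
    for (j in seq_len(d)) {
      dj <- sid("D", p, j)
      cont <- if (j < dmax) model$indel_extend else 0
      if (cont > 0) addt(dj, sid("D", p, j + 1L), cont)
      addt(dj, sid("J", p, -j, 1L), 1 - cont)
    }
    for (r in c(seq_len(i), -seq_len(d))) {
      for (ph in seq_len(p)) {
        jst <- sid("J", p, r, ph)
        if (ph < p) addt(jst, sid("J", p, r, ph + 1L), 1) else addt(jst, rp, 1)
      }
    }
  }
  transitions <- dplyr::bind_rows(lapply(tr, tibble::as_tibble))
  structure(list(states = states, transitions = transitions, model = model),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> %d states, %d transitions (k = %d, i = %d, d = %d)\n",
              nrow(x$states), nrow(x$transitions), x$model$k,
              x$model$max_insert, x$model$max_delete))
  invisible(x)
}

# --- letter encoding ---------------------------------------------------------

.encode_lut <- local({
  lut <- rep(NA_integer_, 256L)
  for (ch in c("A", "C", "G", "T", "N")) {
    code <- match(ch, c("A", "C", "G", "T", "N"))
    lut[as.integer(charToRaw(ch)) + 1L] <- code
    lut[as.integer(charToRaw(tolower(ch))) + 1L] <- code
  }
  # RNA: U maps to T
  lut[as.integer(charToRaw("U")) + 1L] <- 4L
  lut[as.integer(charToRaw("u")) + 1L] <- 4L
  lut
})

# Encode a sequence string to integer codes A=1, C=2, G=3, T/U=4, N=5.
# Errors name the first offending position.
encode_sequence <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  codes <- .encode_lut[as.integer(charToRaw(x)) + 1L]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf("letter outside alphabet ACGTN at position %d: '%s'",
                 bad, substr(x, bad, bad)))
  }
  codes
}

decode_sequence <- function(codes) {
  paste(c("A", "C", "G", "T", "N")[codes], collapse = "")
}

# Per-state log relative-emission term used by both the reference decoder and
# path re-scoring. `codes` is the encoded sequence; `t` the (1-based)
# position; `L` the look-back (0 = context-blind, ratio 1). Positions whose
# look-back reaches before the sequence start are ratio-neutral.
emission_log_ratio <- function(codes, t, L, model) {
  if (L <= 0L || t - L < 1L) return(0)
  cur <- codes[t]; lb <- codes[t - L]
  m <- model$match_prob
  if (cur == 5L || lb == 5L) return(log1p(-m))
  bg <- c(model$at_richness / 2, (1 - model$at_richness) / 2,
          (1 - model$at_richness) / 2, model$at_richness / 2)
  if (cur == lb) log(m / bg[cur]) else log((1 - m) / (1 - bg[lb]))
}
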
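# Seeded generators: random background sequence, mutated tandem repeats,
# and the two-subrepeat split-detection benchmark.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so generators are pure functions of their
# seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Random background sequence
#'
#' I.i.d. letters at a given AT richness:
#' `P(A) = P(T) = at_richness / 2`, `P(C) = P(G) = (1 - at_richness) / 2`.
#'
#' @param length Sequence length (>= 0).
#' @param at_richness Fraction of A+T, in (0, 1).
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return A character string of `length` letters.
#' @examples
#' random_sequence(20, 0.6, seed = 1)
#' @export
random_sequence <- function(length, at_richness = 0.5, seed = 1L) {
  length <- as.numeric(length)
  stopifnot(length >= 0)
  if (length == 0) return("")
  probs <- c(at_richness / 2, (1 - at_richness) / 2,
             (1 - at_richness) / 2, at_richness / 2)
  with_seed(seed, {
    paste(sample(DNA_LETTERS, length, replace = TRUE, prob = probs),
          collapse = "")
  })
}

#' Apply random substitutions to a sequence
#'
#' Each position is independently substituted with probability
#' `substitution_rate`; a substituted letter is replaced by one of the three
#' other letters, chosen uniformly.
#'
#' @param sequence Character string over ACGT.
#' @param substitution_rate Per-position substitution probability in [0, 1].
#' @param seed Integer seed.
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(sequence, substitution_rate, seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1)
  codes <- encode_sequence(sequence)
  with_seed(seed, {
    hit <- which(runif(length(codes)) < substitution_rate & codes <= 4L)
    if (length(hit) > 0L) {
      # uniform over the 3 other letters: shift by 1..3 mod 4
      shift <- sample(1:3, length(hit), replace = TRUE)
      codes[hit] <- ((codes[hit] - 1L + shift) %% 4L) + 1L
    }
    decode_sequence(codes)
  })
}

#' Best rotation identity between two repeat units
#'
#' Maximum over all rotations of `u1` of the positionwise identity fraction
#' with `u2`. Used to require benchmark unit pairs to share at most 50%
#' similarity under any rotation.
#'
#' @param u1,u2 Unit strings of equal length.
#' @return Fraction in [0, 1].
#' @examples
#' rotation_similarity("ACCGG", "GGAGG") # 0.6 via rotation "GGACC"
#' @export
rotation_similarity <- function(u1, u2) {
  if (nchar(u1) != nchar(u2)) stop("units must have equal length")
  a <- strsplit(u1, "")[[1]]
  b <- strsplit(u2, "")[[1]]
  p <- length(a)
  max(vapply(seq_len(p), function(r) {
    rot <- c(a[r:p], if (r > 1) a[1:(r - 1)])
    mean(rot == b)
  }, 0))
}

#' Generate a two-subrepeat benchmark sequence
#'
#' Samples two period-`p` repeat units sharing at most 50% rotation
#' similarity (rejection sampling, uniform over units), builds two perfect
#' tandem repeats of 500 letters each, concatenates them into a 1000-letter
#' sequence with the pattern change at position 500, and applies random
#' substitutions.
#'
#' @param p Repeat period, 1..10.
#' @param substitution_rate Per-position substitution probability.
#' @param seed Integer seed.
#' @param half_length Length of each perfect half (default 500).
#' @return List with `sequence`, `true_boundary` (= `half_length`),
#'   `period`, `unit_left`, `unit_right`, `substitution_rate`, `seed`.
#' @export
make_split_case <- function(p, substitution_rate = 0, seed = 1L,
                            half_length = 500L) {
  p <- as.integer(p)
  stopifnot(p >= 1L, p <= 10L)
  units <- with_seed(seed, {
    repeat {
      u1 <- paste(sample(DNA_LETTERS, p, replace = TRUE), collapse = "")
      u2 <- paste(sample(DNA_LETTERS, p, replace = TRUE), collapse = "")
      if (rotation_similarity(u1, u2) <= 0.5) break
    }
    list(u1 = u1, u2 = u2)
  })
  perfect <- function(u) substr(strrep(u, ceiling(half_length / p)), 1L, half_length)
  sq <- paste0(perfect(units$u1), perfect(units$u2))
  if (substitution_rate > 0) {
    sq <- mutate_sequence(sq, substitution_rate, seed = seed + 500009L)
  }
  list(sequence = sq, true_boundary = as.integer(half_length), period = p,
       unit_left = units$u1, unit_right = units$u2,
       substitution_rate = substitution_rate, seed = as.integer(seed))
}

# Primitive root of a repeat unit: the shortest unit whose repetition gives
# the pattern ("TTTTT" -> "T", "ATATAT" -> "AT").
primitive_unit <- function(u) {
  n <- nchar(u)
  for (d in seq_len(n)) {
    if (n %% d == 0L && strrep(substr(u, 1L, d), n / d) == u) {
      return(substr(u, 1L, d))
    }
  }
  u
}

# Do two (possibly noisy) consensus units describe the same repetitive
# pattern? Primitive roots are expanded to their least common multiple
# length and compared under the best rotation; more than 50% identity
# counts as the same pattern (the same similarity level that defines
# distinct units in the splitting benchmark).
pattern_equivalent <- function(u1, u2) {
  a <- primitive_unit(u1); b <- primitive_unit(u2)
  la <- nchar(a); lb <- nchar(b)
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  l <- la * lb / g(la, lb)
  rotation_similarity(strrep(a, l / la), strrep(b, l / lb)) > 0.5
}

# Detected pattern-change positions for one annotated sequence: internal
# repeat splits of every region, plus junctions between consecutive regions
# whose repeat patterns genuinely differ (same-pattern fragments of one
# noisy repeat, e.g. a "T" region abutting a "TTTTT" region, are one block).
# Junction positions are gap midpoints.
pattern_changes <- function(annotation, junction_gap = 100L) {
  if (nrow(annotation) == 0L) return(integer(0))
  ann <- annotation[order(annotation$start), ]
  splits <- unlist(lapply(seq_len(nrow(ann)), function(i) {
    s <- ann$subrepeats[[i]]
    if (nrow(s) <= 1L) return(integer(0))
    units <- s$canonical_unit
    b <- which(!mapply(pattern_equivalent, units[-length(units)], units[-1L]))
    s$end[b]
  }))
  junctions <- integer(0)
  if (nrow(ann) > 1L) {
    # compare the subrepeats that actually flank each junction
    first_unit <- vapply(ann$subrepeats, function(s) s$canonical_unit[1L], "")
    last_unit <- vapply(ann$subrepeats, function(s) {
      s$canonical_unit[nrow(s)]
    }, "")
    gap <- ann$run_start[-1L] - ann$end[-nrow(ann)]
    j <- which(!mapply(pattern_equivalent, last_unit[-length(last_unit)],
                       first_unit[-1L]) & gap <= junction_gap)
    junctions <- as.integer(round((ann$end[j] + ann$run_start[j + 1L]) / 2))
  }
  sort(c(as.integer(splits), junctions))
}

#' Measure repeat-splitting accuracy on simulated two-subrepeat sequences
#'
#' For each combination of period and substitution rate, generates
#' `cases_per_condition` benchmark sequences ([make_split_case()]),
#' annotates and splits each, and scores a case as a success when exactly
#' one pattern change is detected and it lies within `tolerance` letters of
#' the true boundary.
#'
#' @param periods Integer vector of repeat periods (subset of 1..10).
#' @param rates Substitution rates to test.
#' @param cases_per_condition Simulated sequences per (period, rate) cell.
#' @param tolerance Maximum distance (letters) between the detected and true
#'   boundary.
#' @param model Annotation model; the default is a `k = 10` model matching
#'   the benchmark's period range, parameterized for heavily mutated
#'   repeats (lower match probability so substitutions are cheap, and a
#'   small exit probability so a noisy repeat is held together as one
#'   region, which lets the divergence peak localize the pattern change).
#' @param seed Base seed; each case derives its own seed from it.
#' @param split_val Optional splitting-threshold override.
#' @return Tibble with `period`, `rate`, `n`, `accuracy`.
#' @export
splitting_accuracy <- function(periods = 1:10, rates = c(0, 0.1, 0.2),
                               cases_per_condition = 200L, tolerance = 10L,
                               model = repeat_model(k = 10, match_prob = 0.65,
                                                    nu_out = 0.001,
                                                    nu_in = 0.02),
                               seed = 1L, split_val = NULL) {
  stopifnot(cases_per_condition >= 1L)
  grid <- expand.grid(period = periods, rate = rates)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    p <- grid$period[g]; rate <- grid$rate[g]
    ok <- vapply(seq_len(cases_per_condition), function(i) {
      case_seed <- (as.integer(seed) + 7919L * as.integer(p) +
                      104729L * as.integer(round(rate * 1000)) + 611L * i) %%
        2147483647L
      cs <- make_split_case(p, rate, seed = case_seed)
      ann <- annotate_repeats(cs$sequence, model = model,
                              split_val = split_val)
      ch <- pattern_changes(ann)
      length(ch) == 1L && abs(ch - cs$true_boundary) <= tolerance
    }, logical(1))
    tibble::tibble(period = p, rate = rate, n = cases_per_condition,
                   accuracy = mean(ok))
  })
  dplyr::bind_rows(res)
}
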
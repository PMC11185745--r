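# Detecting changes of repetitive pattern inside a region (repeat splitting),
# consensus repeat units, and canonical unit naming.

#' Assign profile indices to the letters of a repeat region
#'
#' Letters of a period-`p` repeat are numbered cyclically `1..p` so that
#' letters at the same index belong to the same position of the repeat
#' unit. Letters emitted by insertion states receive index 0 (displayed as
#' `*`) and do not advance the cycle; deletions advance the cycle without
#' consuming a letter, so the skipped unit positions keep the remaining
#' letters in register.
#'
#' @param labels Label tibble rows covering the region (columns `kind`,
#'   `del_before` as produced by [viterbi_decode()]).
#' @param p Repeat period governing the region.
#' @return Integer vector of per-letter indices in `1..p`, with 0 marking
#'   insertion letters.
#' @examples
#' path <- viterbi_decode("CATCATCAGTCATCAT", repeat_model(k = 4))
#' @export
assign_profile_indices <- function(labels, p) {
  n <- nrow(labels)
  idx <- integer(n)
  cyc <- 0L
  for (t in seq_len(n)) {
    if (labels$kind[t] == "I") {
      idx[t] <- 0L
      next
    }
    cyc <- cyc + labels$del_before[t]
    idx[t] <- (cyc %% p) + 1L
    cyc <- cyc + 1L
  }
  idx
}

#' Build a repeat profile matrix
#'
#' Frequency of each letter at each profile index within a set of letters.
#' A pseudocount is added to every cell before row normalization so all
#' entries are strictly positive.
#'
#' @param letters Integer letter codes (1..4; 5 = N, excluded) or a
#'   character string.
#' @param indices Profile indices from [assign_profile_indices()] (0 =
#'   excluded insertion letters).
#' @param p Period (number of profile rows).
#' @param pseudocount Added to every cell before normalization.
#' @return A `p x 4` matrix with rows summing to 1.
#' @export
build_profile <- function(letters, indices, p, pseudocount = 0.5) {
  if (is.character(letters)) letters <- encode_sequence(letters)
  counts <- matrix(pseudocount, nrow = p, ncol = 4,
                   dimnames = list(NULL, DNA_LETTERS))
  use <- indices >= 1L & letters <= 4L
  for (t in which(use)) {
    counts[indices[t], letters[t]] <- counts[indices[t], letters[t]] + 1
  }
  counts / rowSums(counts)
}

#' Divergence between two repeat profiles
#'
#' Half the symmetrized Kullback-Leibler sum between two profile matrices,
#' accumulated over all profile indices and letters (natural log):
#' `-1/2 * sum_i sum_c [ L_ic log(R_ic / L_ic) + R_ic log(L_ic / R_ic) ]`.
#' Symmetric, non-negative, and zero iff the profiles are equal.
#'
#' @param L,R Profile matrices of identical shape with strictly positive
#'   entries (see [build_profile()]).
#' @return Non-negative divergence in nats.
#' @examples
#' jsd(matrix(c(.75, .25), 1), matrix(c(.25, .75), 1)) # 0.5 * log(3)
#' @export
jsd <- function(L, R) {
  if (!all(dim(L) == dim(R))) stop("profile shape mismatch")
  if (any(L <= 0) || any(R <= 0)) stop("profile entries must be positive; apply a pseudocount")
  -0.5 * sum(L * log(R / L) + R * log(L / R))
}

# Default splitting threshold per profile row. Calibrated on simulated
# homogeneous (no-split) repeats across periods 1..10 and substitution rates
# up to 0.3 so that fewer than 1% of null regions produce a split; see the
# methods vignette.
.split_val_per_row <- 0.42

default_split_val <- function(p) .split_val_per_row * p

#' Find repeat splits within a region
#'
#' Slides two adjacent windows of `window` letters along the region,
#' computing at every admissible boundary the divergence ([jsd()]) between
#' the two windows' repeat profiles. Boundaries that are local maxima of the
#' divergence series (a flat-topped plateau counts once, at its midpoint),
#' exceed `split_val`, and lie at least two window lengths from any stronger
#' split are reported.
#'
#' @param letters Letter codes (or string) of the region.
#' @param indices Profile indices from [assign_profile_indices()].
#' @param p Region period.
#' @param split_val Divergence threshold; `NULL` uses the calibrated default
#'   `0.42 * p` (the divergence sums over `p` profile rows, so the default
#'   scales with the period).
#' @param window Profile window length per side; default `max(4 * p, 24)`
#'   letters so every profile cell averages several observations and narrow
#'   substitution clusters are diluted.
#' @param pseudocount Pseudocount for profile cells.
#' @return Integer vector of split positions (number of region letters to
#'   the left of each split boundary), possibly empty.
#' @export
find_splits <- function(letters, indices, p, split_val = NULL,
                        window = NULL, pseudocount = 0.5) {
  if (is.character(letters)) letters <- encode_sequence(letters)
  if (is.null(window)) window <- max(4L * p, 24L)
  if (is.null(split_val)) split_val <- default_split_val(p)
  n <- length(letters)
  if (n < 2L * window) return(integer(0))
  series <- .jsd_series(letters, indices, as.integer(p), as.integer(window),
                        pseudocount)
  ok <- which(!is.na(series))
  if (length(ok) < 3L) return(integer(0))
  v <- series[ok]
  # local maxima; a flat-topped run of equal values (common in periodic
  # sequence) counts as one peak at its midpoint
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  is_peak <- vapply(seq_len(nr), function(i) {
    (i > 1L && r$values[i] > r$values[i - 1L]) &&
      (i < nr && r$values[i] > r$values[i + 1L])
  }, logical(1))
  peak <- as.integer(floor((starts[is_peak] + ends[is_peak]) / 2))
  peak <- peak[v[peak] > split_val]
  if (length(peak) == 0L) return(integer(0))
  # enforce a minimum separation of two window lengths, keeping stronger
  # peaks: paired cuts bracketing a one-window noise patch collapse to a
  # single cut, whose flanking segments then merge if their units agree
  peak <- peak[order(-v[peak])]
  kept <- integer(0)
  for (b in peak) {
    if (all(abs(ok[b] - ok[kept]) >= 2L * window)) kept <- c(kept, b)
  }
  sort(ok[kept])
}

#' Canonical form of a repeat unit
#'
#' The lexicographically smallest rotation of the pattern; all rotations of
#' a unit map to the same canonical form, which is used to name repeats.
#'
#' @param pattern Non-empty unit string.
#' @return The minimal rotation.
#' @examples
#' canonical_unit("GTTG") # "GGTT"
#' @export
canonical_unit <- function(pattern) {
  vapply(pattern, function(u) {
    nc <- nchar(u)
    if (nc == 0L) stop("empty pattern")
    if (nc == 1L) return(u)
    rots <- vapply(seq_len(nc), function(r) {
      paste0(substr(u, r, nc), substr(u, 1, r - 1L))
    }, "")
    sort(rots, method = "radix")[1L]
  }, "", USE.NAMES = FALSE)
}

#' Consensus repeat unit from a profile
#'
#' The letter at each unit position is the most frequent letter at that
#' profile index; ties are broken in alphabet order (A < C < G < T). A
#' position observed only as ambiguity letters yields `N`.
#'
#' @param profile A `p x 4` count or frequency matrix (see
#'   [build_profile()]); pass raw counts (pseudocount 0) to allow all-zero
#'   rows to surface as `N`.
#' @return Consensus unit string of length `p`.
#' @export
consensus_unit <- function(profile) {
  letters4 <- DNA_LETTERS
  paste(apply(profile, 1L, function(row) {
    if (all(row == 0) || all(!is.finite(row))) "N" else letters4[which.max(row)]
  }), collapse = "")
}

#' Merge neighbouring subrepeats with equivalent units
#'
#' A split between two subrepeats whose consensus units are rotations of
#' each other (equal canonical units) is an artifact — typically of an
#' undetected indel shifting the profile register — and is removed. Applied
#' until no adjacent pair matches.
#'
#' @param subrepeats Tibble with columns `start`, `end`, `pattern`,
#'   `canonical_unit`, ordered by `start`.
#' @param letters,indices,p Optional region context; when given, merged
#'   segments get a freshly computed consensus pattern.
#' @return Tibble of merged subrepeats.
#' @export
merge_equivalent <- function(subrepeats, letters = NULL, indices = NULL,
                             p = NULL) {
  repeat {
    if (nrow(subrepeats) <= 1L) break
    same <- which(subrepeats$canonical_unit[-nrow(subrepeats)] ==
                    subrepeats$canonical_unit[-1L])
    if (length(same) == 0L) break
    i <- same[1L]
    subrepeats$end[i] <- subrepeats$end[i + 1L]
    if (!is.null(letters)) {
      seg <- (subrepeats$start[i] + 1L):subrepeats$end[i]
      prof <- segment_counts(letters[seg], indices[seg], p)
      subrepeats$pattern[i] <- consensus_unit(prof)
      subrepeats$canonical_unit[i] <- canonical_unit(subrepeats$pattern[i])
    }
    subrepeats <- subrepeats[-(i + 1L), , drop = FALSE]
  }
  subrepeats
}

segment_counts <- function(letters, indices, p) {
  counts <- matrix(0, nrow = p, ncol = 4, dimnames = list(NULL, DNA_LETTERS))
  use <- indices >= 1L & letters <= 4L
  for (t in which(use)) {
    counts[indices[t], letters[t]] <- counts[indices[t], letters[t]] + 1
  }
  counts
}

# Consensus unit of a whole region of a decoded path (canonical form).
region_consensus <- function(path, region) {
  span <- (region$run_start + 1L):region$end
  labs <- path$labels[span, ]
  letters <- path$codes[span]
  idx <- assign_profile_indices(labs, region$period)
  canonical_unit(consensus_unit(segment_counts(letters, idx, region$period)))
}

# Full splitting pipeline for one region of a decoded path: profile indices,
# JSD splits, per-segment consensus units, merging of rotation-equivalent
# neighbours. Returns a subrepeat tibble (absolute 0-based half-open
# coordinates); attribute "region_unit" holds the region-wide canonical
# consensus unit.
split_region <- function(path, region, split_val = NULL, window = NULL) {
  p <- region$period
  span <- (region$run_start + 1L):region$end
  labs <- path$labels[span, ]
  letters <- path$codes[span]
  idx <- assign_profile_indices(labs, p)
  cuts <- find_splits(letters, idx, p, split_val = split_val, window = window)
  bounds <- c(0L, cuts, length(letters))
  subs <- tibble::tibble(
    start = bounds[-length(bounds)],
    end = bounds[-1L]
  )
  subs$pattern <- vapply(seq_len(nrow(subs)), function(i) {
    seg <- (subs$start[i] + 1L):subs$end[i]
    consensus_unit(segment_counts(letters[seg], idx[seg], p))
  }, "")
  subs$canonical_unit <- canonical_unit(subs$pattern)
  subs <- merge_equivalent(subs, letters, idx, p)
  subs$start <- subs$start + region$run_start
  subs$end <- subs$end + region$run_start
  attr(subs, "region_unit") <-
    canonical_unit(consensus_unit(segment_counts(letters, idx, p)))
  subs
}
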
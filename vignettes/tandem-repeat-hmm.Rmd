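---
title: "Annotating tandem repeats with a context-sensitive HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating tandem repeats with a context-sensitive HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemscan)
```

## The model

Tandem repeats — adjacent copies of a short unit, from homopolymer runs to
satellite arrays — are detected here with a hidden Markov model whose
repetitive states are *context-sensitive*: a period-`p` repetitive state
emitting position `t` rewards repeating the letter observed at `t - p` and
penalizes anything else. The model has

* one non-repetitive (NR) state whose emissions follow the background
  composition (parameterized by AT richness, since most genomes are well
  described by a strand-symmetric two-parameter composition);
* one repetitive state `R(p)` per period `p = 1..k`, with
  `Pr[S_t = S_(t-p)] = match_prob` and the remaining mass spread over the
  three mismatching letters proportionally to their background frequency;
* per period, insertion (I), deletion (D) and offset-recovery (J) states.

An insertion inside a repeat emits letters that are independent of the
pattern and — crucially — shifts the register of the following letters: the
next `p` letters must be compared with look-back `p + a` after `a`
insertions (or `p - j` after `j` deletions) before the plain look-back `p`
is valid again. Each I/D run therefore feeds a chain of exactly `p`
J-states carrying the shifted look-back back to `R(p)`. Runs are bounded at
`max_insert` and `max_delete` consecutive indels (10 by default); deletions
are additionally bounded at `p - 1` so the shifted look-back stays
positive. D-states are silent, so the decode remains acyclic and bounded.

Entry into period `p` is weighted by a geometric prior
`gamma_p = lambda^p / sum_i lambda^i`: small periods are a priori more
common, `lambda = 1` makes all periods equal.

`build_state_space()` materializes this state space explicitly —
`1 + sum_p (1 + i + d + (i+d) p)` states — for inspection and for the
brute-force reference decoder in the test suite. The production decoder
never builds it: J-chains are forced paths, so the score of a chain entered
at a known position is the entry score plus a contiguous sum of
per-look-back emission terms, which per-window prefix sums provide in
constant time. The two implementations are checked against each other
exactly (up to floating-point round-off) on hundreds of seeded cases.

## Decoding

Decoding uses the Viterbi algorithm with *relative* emission likelihoods:
each emission probability is divided by the background frequency of the
emitted letter. In biased composition this is what distinguishes "letters
that repeat because they are common" from genuine tandem repeats; with
uniform background it provably selects the same path as absolute emissions
(a per-position constant), which the test suite asserts. All arithmetic is
in natural-log space; scores are reported in nats.

Boundary conditions: decoding starts in NR with probability 1, and a
look-back that reaches before the start of the (window's) sequence is
ratio-neutral — the state neither gains nor loses. Ties are broken
deterministically: NR first, then smaller periods, then non-indel kinds.

The ambiguity letter `N` is ratio-neutral in context-blind states and a
guaranteed mismatch in repetitive states (with penalty `1 - match_prob`,
composition-independent), so `N` runs never score as repeats.

Long sequences are decoded in overlapping windows (`plan_windows()`): the
window size is the per-thread memory budget (256 MB by default) divided by
the explicit state count at 16 bytes per conceptual matrix cell, floored at
`max(10 k, 2 * overlap)` so a valid plan always exists; the overlap is
`max(1000, 4 k)`, at least twice the largest period, so any repeat shorter
than the overlap is seen whole by one window. Windows are decoded
independently (and may be decoded in parallel — results are identical
regardless of thread count); the per-window paths are stitched at a
position both windows label non-repetitive when one exists, otherwise at
the overlap midpoint. Annotations that would be split by a window seam are
merged when they overlap and agree in period (`merge_window_overlaps()`);
a merged span is re-scored by decoding it as a single window rather than
summing partial scores, which would double-count the overlap.

## From path to annotation

Maximal runs of non-NR states become regions. Because repetitive states
only look backwards, the first `p` letters of a repeat cannot be rewarded,
so the reported start is moved down by one period (clamped at zero).
Regions spanning fewer than `min_unit` (default 2) full units — measured on
the un-adjusted run — are dropped; `min_unit = 0` disables the filter. The
region score is the sum of log-transition plus log-relative-emission terms
along the path, which equals the difference of the cumulative path score at
the region's ends; both formulations are computed and must agree to 1e-6.

## Repeat splitting

A change of repetitive pattern (say `(AC)*` to `(GC)*`) costs the decoder
only a mismatch or two, so it is invisible in the path. Splitting detects
such changes afterwards. Letters are assigned *profile indices* cycling
`1..p`; insertion letters are excluded (`*`) without advancing the cycle,
deletions advance the cycle without a letter, so indices stay in register
across indels. Two adjacent windows slide along the region; at each
boundary the letters of each window are tabulated into `p x 4` profiles
(pseudocount 0.5 per cell, then row-normalized) and compared with half the
symmetrized Kullback–Leibler sum (`jsd()`, in nats). Peaks in this series
mark pattern changes.

Numerical choices here, made after calibrating on simulated null
(single-pattern) repeats at substitution rates up to 0.3:

* **Window length** `max(4 p, 24)` letters per side. Four observations per
  profile cell is the floor that keeps profiles meaningful; the absolute
  floor of 24 dilutes short substitution clusters that otherwise mimic
  pattern changes at small periods.
* **Threshold** `split_val = 0.42 * p`. The divergence sums over `p`
  profile rows, so the natural scale of both signal and noise grows with
  the period; a per-row threshold of 0.42 keeps false splits on null
  repeats below 1% while retaining clearly-changed boundaries.
* **Peaks** are local maxima with flat-topped plateaus counted once, at
  their midpoint — periodic sequence routinely produces exactly-equal
  neighbouring divergence values, on which a strict local-maximum rule
  never fires.
* **Separation**: peaks closer than two window lengths to a stronger peak
  are suppressed. A one-window noise patch otherwise yields a pair of cuts
  bracketing it; collapsing the pair leaves segments whose units agree,
  which the merge step below removes entirely.

Each segment's unit is the per-index majority letter (ties to alphabet
order; all-ambiguous positions give `N`), named by its canonical form — the
lexicographically smallest rotation, so `GTTG`, `TTGG`, `TGGT` and `GGTT`
are all reported as `GGTT`. Neighbouring segments whose canonical units are
equal are merged back (to fixpoint): such splits are artifacts, typically
of an undetected indel shifting the profile register.

## P-values

Scores are made interpretable by calibrating against random sequence:
annotate a long i.i.d. sequence at the model's background composition,
record the fraction of letters annotated (`omega`) and fit a location-scale
exponential to the region scores. The fit is maximum likelihood — location
`mu` is the sample minimum, scale `sigma` the mean excess — chosen for
robustness on the few hundred to few thousand regions a desk-scale null
yields. A region with score `s` then gets
`P = min(1, omega * exp((mu - s) / sigma))`; the clamp matters because the
formula exceeds 1 below `mu`. The test suite verifies both the exponential
decay of null scores (log-survival linear, R² ≥ 0.95) and that the fitted
curve tracks fresh-null survival within a factor of 2 over the central 95%
of scores, at a 5 Mb null with `k = 50`.

The packaged default parameters (used by `--pval` when no overrides are
given) come from `calibrate_scores(1e7, repeat_model(), seed = 101,
winsize = 20000)` — 10 Mb of 60% AT-rich sequence under the default model —
and are regenerated by `data-raw/default_fit.R`. A 10 Mb null yields only a
few hundred regions under the default (specificity-oriented) model, so
these defaults are indicative; calibrate on your own composition, or at a
longer null length, for production P-values.

## Tuning

Default parameters cannot suit every genome. `tune_repeat_model()` runs the
annotator over a candidate grid — by default AT richness
{0.3, 0.4, 0.5, 0.6, 0.7} crossed with match probability {0.6, 0.7, 0.9},
15 candidates; arbitrary grids via `tune_config()` or a key=value tune
file — and scores each candidate by annotation coverage next to coverage on
a *locally shuffled* copy of the input. Shuffling within windows preserves
regional composition (isochore-like variation) while destroying genuine
tandem repeats, so shuffled coverage over original coverage estimates the
false discovery rate. The chosen candidate maximizes coverage subject to
FDR ≤ 10% (configurable); if none qualifies the result says so rather than
returning a bad fit. Candidates are evaluated with indel states disabled
for speed (an order of magnitude fewer states); the final annotation run
re-enables them — enable `tune_indel` to pay the full cost during
evaluation when the indel model materially changes the FDR.

One caveat surfaced by the tests: shuffling cannot destroy
composition-driven repeats. A homopolymer or `AT`-rich block survives
window shuffling essentially intact, so inputs dominated by such blocks
yield high shuffled coverage and honest-but-high FDR estimates for every
candidate.

## Synthetic data

The generators are pure functions of their seed: `random_sequence()`
(i.i.d. letters at a given AT richness), `mutate_sequence()` (independent
substitutions, replacement uniform over the other three letters), and
`make_split_case()`, which reproduces the two-subrepeat benchmark: two
units of the same period sharing at most 50% identity under the best
rotation (rejection-sampled uniformly), each repeated perfectly to 500
letters, concatenated and mutated. `splitting_accuracy()` scores, per
period and substitution rate, the fraction of cases where exactly one
pattern change is detected within 10 letters of the true boundary.

Two analysis choices in that benchmark deserve explanation. First, a
"detected pattern change" is a subrepeat split *or* a junction between
adjacent regions whose flanking units genuinely differ — identity judged at
the same >50% best-rotation-similarity level (after expanding primitive
roots to a common length) that defines distinct units in the generator;
without this, a `T` region abutting a `TTTTT` region of a fragmented
homopolymer would count as a pattern change. Second, the benchmark's
default model (`k = 10`, `match_prob = 0.65`, `nu_out = 0.001`,
`nu_in = 0.02`) is persistence-oriented rather than the package default: at
20% substitution roughly a third of positions mismatch their look-back
partner, and the specificity-oriented default fragments such repeats into
several regions, destroying split localization. Choosing parameters per
task is the intended workflow (that is what tuning is for); the benchmark
model is the analogue of a tuned configuration for heavily mutated
repeats.

What the simulations do *not* emulate: indel mutations in the benchmark
(substitutions only), linkage between repeats and composition, satellite
higher-order structure, and real genomes' repeat length and period
distributions. Passing these tests therefore demonstrates correct
mechanics and calibrated thresholds on clean statistical nulls, not
genome-scale coverage performance.

## Problem sizes and runtime

The shipped test-suite scales are deliberate desk-scale choices: 5 Mb nulls
(five 1 Mb chunks) at `k = 50` for the score-distribution and calibration
checks, 200 cases per (period, rate) condition for splitting accuracy, and
a 100 kb synthetic genome for tuning. The same experiments re-run unchanged
at larger sizes by raising the corresponding arguments
(`splitting_accuracy(cases_per_condition = 5000)` reproduces the full-size
benchmark).

## Known limitations

* DNA/RNA only; no protein alphabet.
* Repeats can only change period through the non-repetitive state; a
  direct period switch is annotated either as two regions or as one region
  with a subrepeat split, depending on which path scores higher.
* The windowed decoder's look-back is blind across window starts; repeats
  longer than a window are recovered by overlap-merging, but their scores
  come from re-decoding the merged span.
* Null calibration at desk scale yields few regions (the default model
  annotates ~0.06% of random sequence); treat packaged P-value defaults as
  indicative.
* The `--mem` estimate describes the conceptual full Viterbi matrix, an
  upper bound the implicit-chain decoder stays well under.
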
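---
title: "Measuring linear and nonlinear coexpression with coexmi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring linear and nonlinear coexpression with coexmi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmi)
```

## The estimation problem

Given a matrix of P expression profiles over n samples, `coexmi` scores
every probe pair twice: with the Pearson correlation coefficient r, which
measures the linear component of coexpression, and with mutual information
I(X,Y) = H(X) + H(Y) − H(X,Y) in bits, which measures dependency of any
shape. The two views genuinely disagree on interesting pairs: a profile
that is a deterministic but non-monotone function of another has maximal
MI and r near zero. Both measures are turned into percentile ranks among
all pairs of the matrix, which puts them on a common, comparable scale.

Three assumptions underlie the MI estimate:

* Profiles are continuous signal intensities with enough distinct values
  to support an M-interval partition. Constant or heavily tied profiles
  are rejected (`coexmi_degenerate_input_error`) rather than silently
  re-binned, because a silent change of M would change the value range of
  the rank index.
* The plug-in estimator over discretized values is used as-is. It is
  biased upward for finite n (for independent profiles the bias is
  approximately (M−1)²/(2n ln 2) bits, about 0.07 at n = 1,000, M = 11);
  ranks are unaffected because every pair is estimated under the same
  scheme, which is precisely why the package compares ranks rather than
  raw values. No bias-corrected or continuous (kernel, k-NN) estimator is
  provided.
* Samples are exchangeable: both r and MI are invariant under a joint
  permutation of the sample axis, and the test suite checks this.

## Discretization

Two partitions of a profile's value range are implemented.
`fixed_interval_bins(values, m, lo, hi)` cuts [lo, hi] into m equal-width
intervals, half-open on the right except the last (so the right edge of
the range belongs to the final interval). It exists mainly for didactic
worked examples and for callers that need a common absolute scale.

`adaptive_bins(values, m = 11)` is the production choice: boundaries at
the empirical quantiles, so each interval holds approximately n/m points
and dense regions get narrow intervals. Cut positions are `ceil(i*n/m)`
in the sorted order; when a cut would split a run of tied values, the run
is absorbed into the lower interval, keeping intervals genuine
subintervals of the value range (equal values can never straddle a
boundary). Under heavy ties this can leave intervals empty — they simply
contribute nothing to the entropy. The reported boundary between two
intervals is the midpoint between the neighboring sorted values.

M = 11 is the default because it caps pairwise MI at log₂11 ≈ 3.459 bits,
which is the design assumption behind the rank index's fixed [0, 3.5]
histogram range; changing M therefore means rebuilding indexes, and the
index refuses to rank against a matrix with a different fingerprint.

## The compressed rank index

Percentile ranks need the distribution of all P(P−1)/2 pairwise values,
which is too large to store per pair (8.6 × 10⁸ pairs for a 41,477-probe
array). `build_rank_index()` streams the all-pairs scan into two
fixed-width histograms: 35,000 bins of width 10⁻⁴ over [0, 3.5] for MI and
10,000 bins of the same width over [0, 1] for |r| — a value v lands in bin
`floor(v·10⁴) + 1`, i.e. bin j counts values in [(j−1)/10⁴, j/10⁴). From
the histogram, `percentiles_from_histogram()` extracts the 101 thresholds
v₀..v₁₀₀: v₀ is the lower edge of the first occupied bin and vᵢ the upper
edge of the first bin where the cumulative count reaches ⌈i·total/100⌉.
`rank_percent(value, pv)` then returns the largest i with vᵢ ≤ value,
clamped into [1, 99]: "i percent of all values are smaller". The clamp
means extremes display as 1% and 99%, never 0% or 100%, and ties at a
threshold resolve downward (deterministic and order-independent). Against
a full sort the compressed rank is within ±1 percentile; the histogram
bins are two orders of magnitude finer than the percent resolution
actually reported.

Ranks for the correlation are taken on |r|, not signed r: a strongly
negative and a strongly positive correlation are equally extreme evidence
of linear coexpression, and a near-zero r must rank at the bottom, not in
the middle. (Signed ranking would put r ≈ 0 at the 50th percentile,
contradicting the intended reading of "low linear correlation".)

Two further devices keep the scan cheap: each profile is discretized once
and only its interval labels are kept, and every `(k/N)log₂(k/N)` term of
the MI formula is read from the N+1-entry lookup table
(`build_log_table()`), which agrees with direct evaluation to 10⁻¹² (this
equivalence is tested, not assumed). The accumulators (`hist_add`) are
single-pass with memory proportional to the bin count; pair enumeration
proceeds probe by probe, so the raw pairwise values are never all held at
once. The index serializes to versioned JSON with an arithmetic
fingerprint (dimensions plus value sums) tying it to the matrix it was
built from.

## Queries

`pair_report()` assembles a pair's r, adaptive MI, RoMI, Ror, their
difference, and the hybrid score
MIr = β·r/max r + (1−β)·MI/max MI, where the maxima run over the query
probe's candidates (the query itself is excluded — a self-pair is
rejected). β defaults to 0.5, weighing the linear and nonlinear views
equally; β = 1 and β = 0 recover the single-measure rankings. The literal
signed r enters the ratio by default; `abs_r = TRUE` folds the sign for
consistency with |r|-based ranking. When every candidate correlation is
negative the maximum is nonpositive and the score is reported as
undefined rather than silently sign-flipped.

`top_related()` ranks all candidates under the three perspectives with
deterministic lexicographic tie-breaks; it recomputes candidate scores by
brute force (O(P) per query), which the test suite cross-checks against
independent scoring for P ≤ 100.

`cooccurrence_rates()` reports the present/present (pp), absent/absent
(aa), present/absent (pa/ap) fractions of samples from a detection-call
matrix, counting a sample in none of the four when either call is
marginal (M) — the calls' treatment of marginals is otherwise
unspecified, so they are excluded rather than folded into either class.
The composite pp + aa is exposed as `total_coexpression` alongside its
parts, since only the parts are unambiguous: a high aa with pp ≈ 0 flags
pairs whose large r reflects shared non-expression rather than
coexpression (the fourth rank-comparison regime).

## The synthetic generator

`simulate_pair(kind, n, noise_sd, seed)` provides four dependency kinds —
`linear` (y = x + ε), `monotone_nonlinear` (y = x² + ε),
`independent`, and `permuted_dependency`. The last is the interesting
one: y is a deterministic bijection of x's rank arranged to kill the
linear trend. A uniformly random rank bijection would also destroy the
coarse-grained joint structure and hence the MI, so the bijection is
blockwise: ranks are cut into 11 contiguous blocks (matching the default
interval count), the blocks are rearranged by a permutation whose rank
correlation is driven to ~0 by swap search, and order is preserved within
blocks; a second swap search *within* blocks — which cannot change any
block's membership, hence leaves the 11-bin joint table untouched —
cancels the residual within-block linear trend. For n ≤ 11 every block is
a single point and the construction reduces to a plain zero-correlation
permutation of the points. x is the evenly spaced grid (i−½)/n in
shuffled order for this kind, so the value correlation equals the rank
correlation being controlled; MI and |r|-rank statistics are invariant to
that marginal choice.

Defaults are chosen to emulate a cell-type-specific microarray
compendium at the scale the method targets: profiles on a unit intensity
scale, Gaussian noise with `noise_sd = 0.1` (10% of the signal range —
enough that planted dependencies are strong but not deterministic), and
`simulate_matrix()` planting dependent pairs into an independent
background (50 probes × 300 samples in the test suite's case studies;
sample counts of 150–1,000 elsewhere). What the generator does **not**
emulate: the heavy-tailed intensity distributions of real arrays,
probe-probe correlation *networks* (background probes are mutually
independent), batch effects, and absent-call floors. Passing tests
therefore demonstrate the estimator and rank machinery, not robustness to
array artifacts.

A consequence of the null background worth stating: a truly independent
pair's percentile rank is uniform on [1, 99] by construction, so "both
ranks low" is a property of the population of null pairs, not of any
single one. The corresponding checks are statistical (most background
pairs unflagged, ranks centered mid-scale) at a fixed seed.

## Numerical conventions

* Logarithms are base 2 throughout; MI and entropy are in bits.
  0·log₂0 ≡ 0.
* MI within 10⁻¹² below zero (floating-point cancellation in the entropy
  identity) is clamped to 0; larger negative values cannot occur.
* The histogram bin rule `floor(v·10⁴) + 1` is exact for the achievable
  MI values (irrational except at degenerate tables); values at or above
  the range top are clamped into the last bin with a warning.
* Percent thresholds use ⌈i·total/100⌉ in double precision; totals stay
  below 2⁵³ so the ceiling is exact.
* Matrices must be finite and nonnegative; missing values are rejected
  at parse time, never imputed.

## Limitations

* Ranks are resolved to whole percent and clamped to [1, 99]; exact
  global ranks are out of scope.
* The MI estimate depends on M; indexes and reports are only comparable
  at a fixed M (enforced via the index fingerprint).
* The all-pairs scan is single-threaded R; it is designed for the
  P ≤ a-few-hundred matrices of the test scale. The streaming structure
  (labels + lookup table + histogram accumulators) is what a scaled
  implementation would parallelize.
* MIr is undefined when a query's best candidate correlation is
  nonpositive; callers retrieving by MIr on anticorrelation-dominated
  data should use `abs_r = TRUE`.
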
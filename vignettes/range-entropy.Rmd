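---
title: "Range entropy: methods, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range entropy: methods, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangeen)
```

## The problem

Approximate entropy (ApEn) and sample entropy (SampEn) quantify the temporal
complexity of a signal as the negative log conditional probability that
templates (length-`m` windows in the delay-1 reconstructed phase space) which
are close at dimension `m` remain close at dimension `m + 1`. "Close" means
within a Chebyshev tolerance `r`. Two practical weaknesses follow directly
from that distance: it is unbounded, so the meaningful `r`-range depends on
the signal's amplitude, and it retains only the largest element-wise
difference between two templates. Both measures are therefore sensitive to
amplitude (gain) changes, and the usual remedy — dividing the signal by its
standard deviation — only works when a single global SD describes the whole
recording, which nonstationary physiological signals such as EEG routinely
violate.

Range entropy replaces the Chebyshev distance with the normalised range
distance between templates \(X_i\) and \(X_j\):

\[
d_{\mathrm{range}}(X_i, X_j) \;=\;
\frac{\max_k |x_{i+k} - x_{j+k}| \;-\; \min_k |x_{i+k} - x_{j+k}|}
     {\max_k |x_{i+k} - x_{j+k}| \;+\; \min_k |x_{i+k} - x_{j+k}|},
\qquad k = 0, \dots, m - 1 .
\]

This quantity lies in \([0, 1]\) whenever defined, and is exactly invariant
to a common offset and to joint rescaling of the two templates — so the
tolerance axis is bounded (`r = 1` matches every pair) and no amplitude
correction is ever needed. It is undefined when all element-wise differences
vanish, i.e. for identical templates, including every self-pair. Substituting
it into the ApEn-style estimator gives `RangeEnA` ([rangeen_a()]); into the
SampEn-style estimator, `RangeEnB` ([rangeen_b()]).

## Estimator conventions

All four estimators use delay 1 and inclusive tolerance comparison
(`distance <= r`, the Heaviside convention). Template indexing is 0-based
internally and 1-based in reports; windows are half-open `[i, i + m)`.

**ApEn** uses all `N - m + 1` templates at dimension `m` and `N - m` at
`m + 1`, includes the self-match, and averages per-template log conditional
probabilities (the mean-log form, each \(\Phi\) normalised by its own
template count). It is defined on every finite signal.

**SampEn** restricts both `i` and `j` to `1..N-m` at both dimensions,
excludes the self-pair, aggregates counts before taking a single logarithm,
and is undefined (a first-class state, reported as such and serialised as a
blank cell — never as 0) when either aggregate count is zero.

**RangeEnA / RangeEnB** apply the same two constructions with the range
distance. Three conventions needed fixing where the defining equations are
silent or internally inconsistent:

* *Self-pairs.* The range distance of a template with itself is undefined.
  We treat an undefined pair as a non-match, so RangeEnA (which counts over
  all `j` including `i`) can have a zero per-template count and hence an
  undefined value. This is the only reading consistent with RangeEnA being
  the measure with the most undefined values at small `r`: with a forced
  self-match it could never be undefined.
* *Normalisation.* Given that the self-pair is never a match, RangeEnA's
  per-template probabilities are normalised by the number of admissible
  comparisons (`N - m` at dimension `m`, `N - m - 1` at `m + 1`) rather than
  the template count. With the template-count denominator the estimate at
  `r >= 1` would be `ln[(N-m)^2 / ((N-m)^2 - 1)]`, a small positive bias,
  instead of exactly 0; the admissible-comparison denominator makes the
  terminal-zero property `RangeEn(x, m, r) = 0` for all `r >= 1` hold
  *exactly* on any signal without duplicate templates. RangeEnB inherits the
  property automatically because its aggregate ratio cancels the
  normalisation.
* *Duplicate non-self templates.* Ties between distinct indices also make
  the distance undefined. They are counted as non-matches, tallied in
  `n_excluded_pairs`, and left in the denominator. For continuous-valued
  signals exact ties have probability zero, so the choice cannot affect
  simulation results; it only matters for quantised inputs.

The SD correction (`sd_correction = TRUE` for ApEn/SampEn) divides the signal
by its *population* standard deviation (denominator `N`, matching the
centring convention used throughout); "tolerance `r` times SD" is
algebraically the same thing. Range-entropy measures never apply it: the
distance is self-normalising, and the package silently ignores the flag for
them rather than quietly changing their value.

## Key parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `m` | embedding dimension (template length, samples) | 2 | the conventional choice across the ApEn/SampEn literature |
| `r` | tolerance (dimensionless for RangeEn; amplitude units, or SD units after correction, for ApEn/SampEn) | 0.2 | the conventional operating point; RangeEn is only meaningful on \[0, 1\] |
| r-grid | tolerance sweep | 0.01–1, step 0.01 | covers the full bounded axis of the range distance |
| m-grid | dimension sweep at fixed `r = 0.2` | 2–10 | dimensions beyond ~10 exhaust templates at N = 1000 |

## Entropy profiles and exponents

[entropy_profile()] sweeps one measure over a tolerance or dimension grid.
For an `r`-sweep the pairwise distance matrices at `m` and `m + 1` are built
once and thresholded across the whole grid; this fast path is arithmetic
identical to independent per-point evaluation (a tested invariant). Undefined
grid points are preserved as `NA`.

[fit_exponent()] summarises a profile by the OLS slope of entropy against the
natural log of the swept parameter — the *r-exponent* or *m-exponent*. Two
open choices were fixed here: the fit estimator is ordinary least squares
(the plainest reading of a "fitted line"), and the abscissa uses the natural
logarithm throughout (a base-10 fit would change every slope by the constant
`ln 10` without affecting any monotonicity or rank-correlation statement).
A profile with *any* undefined grid point is excluded from fitting entirely
(`skipped = TRUE`) rather than fitted on the surviving points, so that
exponents are always comparable across signals; `n_points` is reported for
downstream filtering.

On fractional Brownian motion the RangeEnB r-exponent is monotonically
related to the generative Hurst exponent: at desk scale
(H = 0.1–0.9 in steps of 0.1, 10 seeds each, N = 1000, 10-point r-grid) the
test suite measures a Spearman rank correlation of magnitude above 0.8,
against essentially none for uncorrected SampEn. The correlation's *sign* is
positive here — RangeEnB trajectories fall with `r`, and larger `H` flattens
them, pulling the slope toward zero.

## Rescaled-range analysis

[rescaled_range_curve()] implements classical R/S analysis: split the series
into `n = 1, 2, 4, ...` equisized non-overlapping segments while the segment
length exceeds four samples (the tail beyond `n * floor(N/n)` is dropped);
mean-centre each segment, cumulate it, score `R = max - min` of the cumulative
sum over the segment's population SD; average R/S per scale. Locally constant
segments (`S = 0`) are skipped rather than erroring, to survive flat stretches
of real recordings; a scale with no usable segment is dropped, and fewer than
two surviving scales is an error. [hurst_rs()] fits `ln(mean R/S)` against
`ln(segment length)` by OLS; the slope is `H`, unclipped.

Two conventions deserve emphasis. First, the power law is fitted against
segment *length*, not segment count — the classical R/S law grows with
length, and regressing on count would flip the slope's sign. Second, the R/S
law describes the *increments* of an `H`-self-similar motion. Applied to a
raw motion (a Brownian or fBm path) the procedure returns a slope near 1
regardless of `H`, because both `R` and `S` then inherit a factor `L^H`.
`hurst_rs(x, input = "motion")` therefore first-differences the path before
the standard procedure, and this is the setting used to recover `H` from
simulated fBm (mean estimates at generative H = 0.2/0.5/0.8 are strictly
increasing, with ordinary Brownian motion recovered near 0.5). The default
`input = "increments"` analyses the series as given — the right choice for
noise-like signals, where white noise scores near 0.5.

## Simulators

The validation study is driven entirely by seeded generators; all are
bit-reproducible given `(parameters, seed)` and restore the session RNG
state afterwards.

* **Coloured noise** ([gen_noise()]): white is iid N(0, 1); pink (1/f) and
  brown (1/f²) are spectrally shaped white draws — Fourier amplitudes
  multiplied by `f^(-1/2)` or `f^(-1)` with the DC bin zeroed — then
  standardised to zero mean, unit population variance. Spectral shaping was
  chosen over AR approximations because the expected log-log periodogram
  slope is then exactly −1/−2 (tested at ±0.3 over 100 draws of N = 4096).
* **Fractional Brownian motion** ([gen_fbm()]): exact Gaussian draw on
  integer times `t = 1..n` with covariance
  `D (t^{2H} + s^{2H} - |t-s|^{2H}) / 2`, via Cholesky factorisation of the
  `D = 1` matrix and multiplication by `sqrt(D)` — so matched-seed paths at
  different `D` differ by an exact scalar, which is what makes the
  covariance-scaling robustness check a machine-precision statement. The
  integer time grid only fixes the amplitude unit, which RangeEn ignores and
  SD correction absorbs. Exact factorisation is O(n³); `n` is capped at
  4096, enough for the N = 1000 study sizes (no circulant-embedding path is
  provided).
* **Fractional Lévy motion** ([gen_flm()]): moving-average discretisation —
  symmetric α-stable innovations (Chambers–Mallows–Stuck; α = 2 reduces to
  Gaussian with variance 2, α = 1 to Cauchy) convolved with the kernel
  `a(k) = (k+1)^d - k^d`, `d = H - 1/α`, truncated at `M` (default 600)
  coefficients, then cumulated. `a(0)` is set to 1 (the `1 - 0^d` term of
  the formula diverges for `d < 0`). The kernel's implicit normalisation
  constant is left proportional: it is a pure amplitude factor, immaterial
  for RangeEn and for SD-corrected ApEn/SampEn.
* **Gain profiles** ([gain_profile()], [apply_gain()]): piecewise-constant
  amplitude modulation. The default — five 200-sample blocks with gains
  1, 3, 10, 4, 1 — is the nonstationary test signal whose time-varying SD
  defeats global SD correction.

Raw fBm/fLm paths are deliberately *not* standardised: amplitude sensitivity
is part of what the study measures.

## What the synthetic data do and do not show

The generators emulate controlled self-similarity (fBm/fLm with known `H`),
controlled spectral decay (the three noises), heavy tails (α = 1), and
nonstationary gain (the piecewise profile). They are stationary-increment,
artefact-free, and univariate; they do not emulate measurement noise floors,
line interference, electrode pops, band-pass filtering or the nonstationary
spectral content of real EEG. Passing the validation suite therefore shows
the estimators have their claimed mathematical properties and recover known
generative parameters — not that any of them separates clinical states; the
EEG-dialect reader and profiling machinery are provided for users to run on
real segments they supply themselves.

## Numerical choices and degenerate inputs

* Tolerance comparison is inclusive (`<= r`); counts are non-decreasing
  step functions of `r`.
* Undefined estimates propagate as a tagged state (`undefined = TRUE`,
  value `NA`), serialised as blank CSV cells; summary tables average defined
  values only and report undefined counts alongside.
* A constant signal: ApEn and SampEn are 0 (everything matches); both
  range entropies are undefined (every pair is a tie); R/S estimation
  errors (all segment SDs vanish).
* Signals shorter than `m + 2` samples are rejected with an error naming
  `N` and `m`.
* Equality tests on the amplitude-invariance properties use a 1e-12
  tolerance: invariance of the range distance is exact in real arithmetic,
  and in floating point a rescaling can only flip a match decision when a
  pairwise distance lies within rounding error of the threshold, an event of
  probability ~0 for continuous-valued signals.

## Problem sizes used in the validation suite

Signal-level checks run at the study's native N = 1000 with m = 2. Sweeps
run at desk scale: the Hurst sweep uses H = 0.1–0.9 in steps of 0.1 with 10
seeds per level and a 10-point r-grid (the full-scale protocol — ΔH = 0.01,
99 levels, 100-point grid — is available through
`experiment_config("hurst_sweep_fbm")` and reproduces the same monotone
relationship, just more finely). Brute-force cross-checks run at N ≤ 50
where exhaustive enumeration is cheap. Monte-Carlo calibration checks use
100–1000 draws as stated with each test.

## Known limitations

* No multiscale (delay > 1 / coarse-grained) variants, no multichannel
  inputs.
* Exact fBm is limited to n ≤ 4096 by the Cholesky route.
* The fLm construction is a truncated moving average — its small-`k` kernel
  behaviour is exact but memory beyond `M` samples is discarded; increase
  `M` for very long-memory studies.
* R/S Hurst estimation carries the classical small-sample bias (white noise
  scores slightly above 0.5 with the shortest segments included); no
  Anis–Lloyd correction is applied, and no DFA or wavelet estimator is
  provided.
* Entropy estimation is O(N²) in time and memory per signal; N = 4097
  EEG-length segments are feasible but slow in sweeps.

## A worked example

```{r example, eval = FALSE}
x1 <- gen_noise(1000, "white", seed = 42)
x3 <- apply_gain(x1, gain_profile())   # time-varying gain 1/3/10/4/1

rangeen_b(x3, m = 2, r = 0.2)
rangeen_b(5 * x3, m = 2, r = 0.2)      # identical: amplitude-invariant
sampen(x3, m = 2, r = 0.2, sd_correction = TRUE)  # still amplitude-sensitive

h <- hurst_rs(cumsum(x1), input = "motion")
h$H                                     # near 0.5 for Brownian motion
```
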
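---
title: "Entropic time-series and image analysis with entropics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic time-series and image analysis with entropics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entropics)
```

## The problem

Entropy, in the information-theoretic sense, measures how much
uncertainty a process carries: `H(X) = -Σ p(x_i) log_b p(x_i)` for state
probabilities `p(x_i)`, and conditionally,
`H(X|Y) = H(X,Y) - H(Y)` for the uncertainty remaining once `Y` is
known. Applied to a time series, an entropy estimator first reduces the
signal to a discrete description — template-match frequencies, ordinal
or amplitude symbols, a distance histogram, a power spectrum — and then
scores that description with a Shannon-type (or Rényi, for bubble
entropy) functional. Different reductions probe different aspects of a
signal, which is why the field has accumulated dozens of named
estimators; this package implements the eighteen base, eight cross and
four bidimensional estimators most used in biomedical signal processing
and nonlinear dynamics, plus the multiscale machinery that turns any of
them into a scale-resolved complexity profile.

## Conventions shared by all estimators

* **Delay embedding.** Template estimators compare delay vectors
  `(x_i, x_{i+τ}, …, x_{i+(m−1)τ})` with embedding dimension `m`
  (default 2) and delay `τ` (default 1, in samples).
* **Tolerance radius.** Where a radius is needed, the default is
  `r = 0.2 × SD` of the input (sample SD, `n−1` denominator) — the
  convention established for approximate/sample entropy. Cross
  estimators pool the SD of both series; neither series is individually
  rescaled unless requested.
* **Distance.** Chebyshev for the ApEn/SampEn/FuzzEn families (the
  canonical choice), Euclidean for the K2 correlation sums.
* **Logarithms.** Natural log everywhere by default; every estimator
  takes `log_base`. Some sources print specific estimators in bits
  (attention entropy, cosine similarity entropy); passing
  `log_base = 2` recovers those units.
* **`0 log 0 ≡ 0`** throughout; probability masses are validated to sum
  to 1 within 1e-12.
* **Degenerate input.** A constant series has zero SD: estimators that
  depend on a radius default warn and use the degenerate rule; the
  NCDF symboliser maps every sample to the middle class `⌈c/2⌉`. All
  applicable estimators then score 0, the correct "perfectly regular"
  answer.
* **Results.** Every estimator returns an `entropy_result` with the
  primary estimate (a level vector for ApEn/SampEn/FuzzEn/K2En, whose
  last element is "the" estimate), named secondary outputs, and the
  complete resolved parameter set — including every default that was
  applied — for auditability.
* **Missing matches.** SampEn-type ratios with a zero count return an
  `Inf` sentinel with a warning rather than an error, so batch analyses
  of short records do not abort.

## Estimator families

**Regularity (ApEn, SampEn, FuzzEn, K2En).** Counts of template pairs
within `r`. ApEn includes self-matches and differences the mean log
match frequency between dimensions (`Φ(m) − Φ(m+1)`, `Φ(0) ≡ 0`, so the
level-0 value is `−Φ(1)`); SampEn excludes self-matches and takes
`−log(A/B)` with both counts restricted to the templates whose
`(m+1)`-point extension exists. FuzzEn replaces the hard threshold by a
membership `exp(−d^p/r)` of the distance between mean-centred
templates; K2 uses the correlation-sum ratio at Euclidean distance.

**Symbolic (PermEn and variants, DispEn, SlopEn, IncrEn, SyDyEn,
CondEn).** A symbol stream (ordinal ranks, NCDF amplitude classes,
slope classes, signed increment magnitudes, quantile states, uniform
amplitude bins) is censused over `m`-symbol words. Ordinal ties are
broken deterministically by the earlier index ranking lower. The
dispersion-entropy secondary output is the reverse dispersion entropy
`Σ(p_i − c^{−m})²`, zero exactly when all `c^m` patterns are equally
used. The corrected conditional entropy adds the singleton-word
fraction times `H₁` to counteract the spurious conditional-entropy
decay on short series.

**Distribution/geometric (DistEn, EnofEn, AttnEn, CoSiEn, BubbEn,
GridEn, PhasEn, SpecEn).** Histogram or census entropies of inter-
template distances (Sturges' rule, `⌈log₂ n⌉ + 1` bins), window-level
entropies, peak-interval censuses, angular-distance matches, bubble-sort
inversion counts (Rényi-2), the gridded Poincaré plane, radius-weighted
angular sectors of the second-order difference plot, and the one-sided
power spectrum. Normalised outputs divide by the log of the relevant
alphabet or bin count and live in [0, 1]. One calibration worth knowing:
the *normalised spectral entropy* of finite white noise converges to
`1 − (1 − γ)/log n_bins` (≈ 0.945 at 4096 samples), not to 1 exactly,
because periodogram ordinates are exponentially distributed.

**Cross estimators** draw templates from one series and match them in
the other; there is no self-match concept, and `XSampEn(x, x)` equals
sample entropy with self-matches retained. XApEn is directional (first
argument supplies templates; the convention is recorded in the result
parameters). XK2En and XSpecEn are constructed by direct analogy with
their univariate forms, have no published validation, and are flagged
`unverified = TRUE` in their result parameters.

For **XPermEn** the exact statistic in the source literature was open
to interpretation; this package defines it as the conditional entropy
`H(π_y | π_x)` of the ordinal pattern of the `y`-window given the
simultaneous `x`-window pattern. It is bounded by `[0, log m!]`, is 0
when `y`'s ordinal structure is a function of `x`'s (identical series),
approaches `log m!` for independent series, and scores the Lorenz
`x`–`y` pair far below the independence level — the qualitative
behaviour the statistic exists to capture. Alternative cross-ordinal
statistics (reordered-window patterns, pattern-agreement entropy) were
evaluated and behave equivalently in rank terms; the conditional form
was chosen for its clean information-theoretic reading.

**Bidimensional estimators** slide fully in-bounds `m × m` submatrix
templates (no padding) over the image. SampEn2D/FuzzEn2D are quadratic
in the template count, so matrices beyond 128 × 128 require
`override = TRUE`; this guard exists because a 512 × 512 image
generates ~2.6 × 10⁵ templates and ~3.4 × 10¹⁰ pairs. DispEn2D
symbolises with statistics taken over the *whole matrix* (not per
template) — with per-template statistics the printed reference values
for Gaussian matrices are not reproducible — and returns unnormalised
nats by default, again to match the documented values; `normalise`
divides by `log(c^{m²})`. On pure-noise images SampEn2D frequently
finds no `(m+1)`-level matches (an honest `Inf`); textured or smoothed
images are its intended domain.

## Multiscale engines

`make_spec(name, params)` freezes an estimator and its keyword
arguments into an immutable spec (the multiscale-object pattern); the
drivers reuse it verbatim at every scale and error early on unknown
names or parameters. Drivers return the per-scale curve and its sum,
the complexity index; the per-scale scalar is the last element of the
estimator's level vector, matching the scalar-per-scale curves used in
practice.

* `msen` — classic coarse-graining: non-overlapping window means
  (`modified`: moving average without decimation, preserving the
  sampling rate; `generalized`: window variances, with scale 1 defined
  as the identity for all three methods).
* `cmsen` — composite: the mean over all `s` grain offsets;
  refined-composite pools the match counts (or fuzzy memberships)
  across offsets *before* the log, and is therefore only defined for
  estimators that expose them (SampEn/FuzzEn and their cross forms);
  other specs raise an explicit unsupported-combination error.
* `rmsen` — refined: zero-phase order-6 Butterworth low-pass at
  `0.5/s` of Nyquist followed by decimation by `s`, with a free radius
  re-derived as `0.2 × SD` of the filtered, decimated series, per the
  refined-multiscale formulation.
* `hmsen` — hierarchical: a binary tree of paired averages (low) and
  paired differences (high); `2^(depth+1) − 1` nodes, each scored by
  the spec, with the low/high pair losslessly reconstructing the
  parent.

A free radius in the *non-refined* drivers is computed once from the
raw series (`0.2 × SD(x)`; pooled SD for pairs) and frozen across
scales. This is the classic multiscale convention — entropy changes
along the curve then reflect the graining, not a tolerance that
shrinks with the grained series' SD — and it is what makes white-noise
multiscale sample entropy decrease with scale (the grained SD falls as
`1/√s` while `r` stays put). The refined driver is precisely the
variant that re-derives `r` per scale. Both behaviours are verified in
the test suite.

The default scale count is 3 and is always explicit in the returned
object; analyses in the field typically request 5–7 scales via
`scales`. Scales whose grained series falls below 10 samples are
reported as `NA` with a warning, never silently dropped. Cross drivers
grain both series with identical parameters and offsets — the simplest
contract that keeps the pair aligned — and reject base-family specs
with a type error.

## Synthetic fixtures: what they emulate and what they do not

`generate_fixture()` regenerates the standard validation datasets from
stated parameters: `gaussian` (N = 5000, μ = 0, σ = 1), `uniform2`
(two independent uniform(0,1) series, N = 4096), `randintegers`
(uniform on 1..8, N = 4096), `lorenz` (σ = 10, β = 8/3, ρ = 28, start
(10, 20, 10), N = 5917), `henon` (α = 1.4, β = 0.3, start (0, 0)),
`chirp` (`cos(2π(f0 t + ((f1−f0)/(2 t1)) t²))`, f0 = 0.01, f1 = 0.025
at t1 = 4000, N = 5000, zero phase), `gaussian_Mat` (60 × 120) and
`mandelbrot_Mat` (60 × 120 escape-time matrix). Stochastic fixtures
require an explicit seed; there is no hidden global random state.

Where generation details are not stated anywhere, they are fixed here
once: the Lorenz system is integrated with fixed-step RK4 at
`dt = 0.01` with no transient discard (recorded in the fixture's
`fixture_spec` attribute); the Hénon map starts at the origin; the
random-integer alphabet is 1..8; the Mandelbrot window is
re ∈ [−2, 0.6], im ∈ [−1.2, 1.2] at 100 iterations. A consequence
worth stating plainly: statistics that depend on the *sampling* of a
chaotic trajectory (for instance the ordinal agreement between the
Lorenz x and y components) are reproducible against this package's own
fixtures but not bit-exact against externally hosted copies of "the
same" system integrated differently; `fetch_hosted()` exists for that
replication case and fails with a clear pointer to the generated
fixtures when offline. These fixtures emulate stationary noise,
deterministic chaos and frequency sweeps; they do not emulate
nonstationary physiological records, artifacts, or missing data, so
passing tests certify algorithmic correctness, not robustness to
real-world recording conditions.

## Numerical choices

* NCDF symbolisation uses `class = min(c, ⌊c·z⌋ + 1)` on
  `z = Φ((x − mean)/SD)`, i.e. equal-probability slicing of the CDF;
  ties sit on measure-zero boundaries.
* Sturges' rule is `⌈log₂ n⌉ + 1` bins over `[min, max]`; identical
  values collapse to a single bin of mass 1.
* SampEn/XSampEn level 0 compares raw samples against `n(n−1)/2`
  (resp. `n²`) candidate pairs, so the level vector is defined from
  dimension 0 upward.
* The test suite pins every counting kernel to an exhaustive
  double-loop oracle at `n ≤ 40` to 1e-12 over 100 seeds, and checks
  the documented worked-example values on regenerated inputs at the
  tolerances those regenerations warrant (Monte-Carlo spread for noise
  inputs; phase-convention slack for the chirp).
* Problem sizes in the tests are the validation sizes themselves
  (N = 5000 series, 60 × 120 matrices, 25-seed averages), which the
  C++ kernels handle in seconds.

## Known limitations

* XK2En and XSpecEn are analogy constructions, flagged unverified.
* The modified permutation variant normalises by the ordered-Bell
  alphabet, and the fine-grained variant by the observed alphabet
  (its quantised-amplitude alphabet is unbounded); normalised values
  of different variants are therefore not directly comparable.
* `fetch_hosted()` depends on the availability and layout of the
  external host; checksums are recorded on first download, not
  distributed with the package.
* No streaming/online estimation and no GPU kernels; the intended
  regime is offline analysis of records up to ~10⁵ samples.
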
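---
title: "MSLD sample entropy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSLD sample entropy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msldSampEn)
```

## The problem

Epileptic EEG classification asks whether a single-channel recording
comes from a seizure (ictal), from the seizure-free interval of an
epilepsy patient (interictal), or from a healthy subject. The three
states differ in signal *complexity*: seizure EEG is the most irregular,
interictal EEG the most regular. This package quantifies that
irregularity with sample entropy computed not on the raw signal but on a
family of difference signals taken at multiple sample distances, and
classifies the resulting feature vectors with a kernel SVM.

## The MSLD transform

The Multidistance Signal Level Difference of a series
$x(1), \dots, x(N)$ at distance $d$ is

$$y_d(i) = \lvert x(i) - x(i+d) \rvert, \qquad i = 1, \dots, N - d,$$

for $d = 1, \dots, K$. It is the one-dimensional analogue of the
gray-level difference statistic used in image texture analysis. Each
$y_d$ is non-negative, one sample shorter per unit of distance, shift
invariant ($x + c$ gives the same $y_d$) and positively scale
equivariant ($c\,x$ gives $c\,y_d$).

The useful contrast is with coarse-graining, the usual multiscale
entropy preprocessing: averaging windows of width $s$ shrinks the
variance of white noise by $1/s$, so the coarse-grained series at large
scales is a different, tamer signal. MSLD keeps the variance of the
difference signal on the order of the source variance at every distance
(for white noise, $\mathrm{var}(y_d)/\mathrm{var}(x) \approx 0.73$
independent of $d$), which is why per-distance entropies remain
comparable across $d$. The test suite asserts both behaviours on
20 000-sample noise.

We restrict $d \le N - 2$ (slightly tighter than the transform alone
requires) so every difference signal retains at least two samples and
stays usable by the entropy estimator downstream.

## Sample entropy

For embedding dimension $m$ and tolerance $t$, let $B$ be the number of
unordered pairs $(i, j)$, $i \ne j$, of length-$m$ templates with
Chebyshev distance $\le t$, and $A$ the corresponding count for
length-$(m+1)$ templates. Both counts run over the same index range
$i = 1, \dots, N - m$, so the ratio compares like with like; this is the
convention implied by the symmetric $(N-m-1)(N-m)/2$ normalizers of the
usual estimator presentation (the normalizers cancel in the ratio and
are never computed separately). Then

$$\mathrm{SampEn}(m, t, N) = -\ln\frac{A}{B}.$$

Self-matches are excluded by construction, the well-known bias fix
relative to approximate entropy. Matching is inclusive ($\le t$): for
real-valued data the choice only affects measure-zero cases, but for
integer-valued archive records it is the standard convention.

Parameter choices, and why:

* **`m = 2` (default).** The embedding dimension is the one genuinely
  underdetermined parameter of this method's usual description; 2 is the
  standard choice in the sample-entropy literature for series of a few
  thousand samples and is configurable everywhere.
* **`r` relative to each difference signal's own SD (default).** `r`
  values such as 0.25 are conventionally fractions of the series SD. We
  use the *population* SD of the series actually analyzed — each MSLD
  level's own SD — which makes every feature exactly invariant to affine
  amplitude changes of the source signal ($c x + b$, $c > 0$). An
  `absolute` mode (tolerance in signal units) exists for testing, and
  the SD-of-the-raw-signal alternative can be emulated through it.
* **Chebyshev (max-norm) template distance**, the standard definition.

Degenerate and undefined cases are handled explicitly:

* A **constant series** returns 0 (perfect regularity) before any SD
  scaling is attempted — it is the limit of the definition as all pairs
  match, and it arises for real inputs (the MSLD of any constant or
  exactly $d$-periodic signal).
* When **no pairs match** ($B = 0$), or no match survives extension to
  $m + 1$ ($A = 0$), the estimator is undefined and the core function
  returns `NA`. The feature layer substitutes the finite ceiling
  $\ln\binom{N-m}{2}$ — the value the estimator would take if exactly
  one pair out of all $\binom{N-m}{2}$ matched — so feature tables stay
  finite while preserving the "maximally irregular" ordering. Each
  table reports how many substitutions occurred.

Two implementations coexist deliberately: an optimized C++ pair scan
(used everywhere) and a pure-R exhaustive enumeration that builds the
full pairwise distance matrices (`sample_entropy_bruteforce`, capped at
2000 samples). The suite requires agreement to `1e-12` across random
series in both tolerance modes; the oracle shares no code with the fast
path.

## Features and classification

The feature vector of a record is
$\big(\mathrm{SampEn}(y_1), \dots, \mathrm{SampEn}(y_K)\big)$ with
$K = 20$ by default. Because feature $d$ depends only on $y_d$, a table
extracted at $d = 1..20$ can be truncated by column slicing to obtain
the $1..15$, $1..10$ and $1..5$ variants exactly; the grid driver does
so rather than re-extracting.

Classification uses a soft-margin SVM with the linear kernel
$k(x, y) = x \cdot y$ or the polynomial kernel
$k(x, y) = (x \cdot y + c_0)^p$, $p = 2$ (quadratic) or 3 (cubic).
Choices made where the method's usual description is silent:

* **Features are standardized** to the training data's mean/SD before
  fitting. A homogeneous cubic kernel on raw features is
  scale-pathological; with standardization and the inhomogeneous
  default `coef0 = 1` the polynomial kernels are well behaved.
  `coef0 = 0` restores the homogeneous form.
* **Box constraint `C = 1`**, configurable; no hyperparameter search by
  design, since the method's interest is the feature set.
* **One-vs-one voting** for the three-class problem (libsvm's native
  reduction, via e1071).
* **Stratified 5-fold cross-validation** (plain k-fold is available):
  with balanced classes stratification is the faithful, lower-variance
  reading of "5-fold CV". Fold assignment is deterministic given the
  seed, and standardization statistics are fitted inside each training
  fold only — the suite asserts that perturbing a held-out fold leaves
  the training transform bit-identical.

Accuracies are reported in percent to one decimal in the grid output,
matching the usual presentation of such sweeps
(r in {0.1, 0.15, 0.2, 0.25} by scale ranges 1–20/1–15/1–10/1–5 by
three kernels).

## The synthetic generator

Real archive EEG cannot be redistributed with the package, so the
`synth` module generates a three-class stand-in whose *complexity
ordering* reproduces the qualitative structure of epileptic EEG:
per-distance mean entropy curves ordered ictal-like > normal-like >
interictal-like at every distance d = 1..20.

The frozen defaults:

* **ictal-like** — `spike_wave`: a 3 Hz spike-and-wave morphology
  (one sharp transient per cycle, random polarity) riding on dominant
  broadband Gaussian noise. Its difference signals are noise-like at
  every distance, holding the entropy profile near the white-noise
  ceiling (~1.77 at m = 2, r = 0.25).
* **normal-like** — a two-stage (cascaded) AR(1) with
  $\varphi = 0.9$: smooth background activity whose entropy profile
  runs roughly 1.5 down to 0.55 over d = 1..20.
* **interictal-like** — a two-stage AR(1) with $\varphi = 0.97$ plus a
  4 Hz sinusoid at twice the background SD: strongly autocorrelated and
  rhythmic, profile ~0.5 down to 0.33.

Why cascaded AR stages: the entropy of $y_d$ tracks the smoothness of
the *increments* of the source. A single-stage AR(1) has nearly white
increments, so at d = 1..2 its difference signal is almost as irregular
as noise and the intended ordering inverts; applying the recursion
twice low-passes the increments too, which keeps the smooth classes
smooth at short distances. The sine frequency (4 Hz) is kept below
$f_s/(2 \cdot 20)$ so the sinusoidal component of $y_d$ never vanishes
within d = 1..20. These parameters were tuned once on mean profiles
over five seeds and then frozen; they claim no physiological realism
beyond the complexity ordering and the burst morphology.

Every record's seed is derived from (master seed, class index, record
index), so any single record can be regenerated in isolation and
generation order is irrelevant.

What passing tests on this generator do and do not show: they verify
the pipeline — transform, estimator, feature assembly, fold hygiene,
kernels — end to end, and that the method separates classes whose
complexity ordering matches the epileptic-EEG structure. They do not
certify accuracy on real recordings, which have heavier tails,
nonstationarity and artifacts the generator does not emulate. On the
real three-class archive (4096-sample records at 173.61 Hz, 100 records
per class, obtainable from its source), the grid driver at r = 0.25,
d = 1–20 with the cubic kernel is expected to land in the mid-to-high
90s in percent accuracy; fold assignment and unstated SVM
hyperparameters make cell-exact reproduction of published sweeps
impossible, so this is documented as an expectation, not asserted by
the suite.

## Numerical choices and problem sizes

* Population (divide-by-N) SD for the tolerance; the distinction from
  the sample SD is negligible at N ≈ 4000 but is fixed for
  reproducibility.
* Oracle agreement tolerance `1e-12` (the two paths differ only in
  summation order).
* The test suite runs the full pipeline at the default study size —
  3 × 100 records of 4096 samples, d = 1..20, m = 2, r = 0.25 — and
  checks mean 5-fold accuracy ≥ 0.95 for five fold seeds; the
  qualitative ordering check uses 20 records per class, and the
  permutation null 20 reshuffles. These sizes keep the suite's total
  runtime in the minutes while leaving the statistical assertions
  well powered.
* All randomness (generation, folds, permutations) flows from explicit
  integer seeds; derived per-record seeds stay below $2^{31}$.

## Limitations

* Single-channel, plain-ASCII input only; no EDF/BDF, no multichannel
  montages, no filtering or artifact handling (the target archive data
  is already low-pass filtered).
* Only the linear/quadratic/cubic kernel menu; no RBF, no probability
  calibration, no feature selection beyond contiguous range truncation.
* Approximate entropy, coarse-grained multiscale entropy and composite
  complexity indices are out of scope.
* The distance range worth computing is an empirical matter; ranges
  beyond d ≈ 15 have been observed to add little, and the default
  d = 1..20 simply matches the widest sweep column.
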
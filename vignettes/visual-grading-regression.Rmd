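---
title: "Visual grading regression: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual grading regression: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgrkit)
```

## The problem

In a visual grading study of CT protocol optimisation, radiologists compare
pairs of reconstructed image stacks of the same patient, acquired at
different tube loads (quality-reference mAs) and reconstructed with
different algorithms, and score each image-quality criterion on a relative
5-point scale: −2 (left image better) to +2 (right image better), 0 meaning
equivalent. The analytical questions are (i) how much perceived quality a
given tube-load increase buys, (ii) how much an iterative reconstruction
algorithm buys relative to filtered back projection, (iii) how those two
currencies exchange — the potential dose reduction — and (iv) how
reproducible the gradings are within and between observers.

## The model

`fit_vgr()` fits a cumulative-logit (proportional-odds) model to the scores.
For a grading of pair (L, R) the latent relative quality is

$$\eta = a\,(\log \mathrm{mAs}_R - \log \mathrm{mAs}_L)
       + b_{\mathrm{algo}_R} - b_{\mathrm{algo}_L} + u + v,$$

with a standard-logistic residual and thresholds
$\theta_1 \le \dots \le \theta_4$ cutting the latent scale into the five
ordered categories: $P(\text{score} \le s) = \mathrm{logistic}(\theta_s - \eta)$.

Key modelling choices:

* **Right-minus-left coding.** Covariates enter as differences, so the model
  is invariant to which side a condition is hung on (mirroring every pair
  and negating every score leaves all coefficients unchanged and reverses
  the thresholds). This coding also identifies $a$ and $b$ exactly as the
  dose-reduction formula requires.
* **Proportional odds.** One set of $(a, b)$ shifts all four thresholds
  equally — the standard VGR assumption. No partial-proportional extension
  is offered.
* **Natural logarithm for tube load** throughout, both in the simulator and
  the fitter. This is required for $DR = 1 - e^{-b/a}$ to be
  base-consistent: $b/a$ is then the log tube-load change latently
  equivalent to the algorithm switch, and $e^{-b/a}$ the corresponding dose
  factor.
* **Crossed random intercepts** for patient and observer, drawn per
  criterion (each criterion is fitted separately). Because patients and
  observers are crossed rather than nested, the integrals do not factorize
  and Gauss–Hermite quadrature is not applicable; the marginal likelihood is
  maximized under a **Laplace approximation** at the joint mode of the
  random effects, with the exact curvature (including the patient-by-observer
  cross blocks) used for the determinant term. Only random intercepts are
  supported — no random slopes for tube load or algorithm.

### Numerical details

* Thresholds are parameterized as a first cutpoint plus log-increments, which
  enforces monotonicity unconditionally. Initialization comes from the
  empirical cumulative score frequencies; coefficients start at 0; mixed
  fits start from the fixed-effects solution.
* The fixed-effects likelihood is maximized with an analytic gradient,
  followed by damped Newton polishing steps on the observed information
  until the scaled gradient is below 1e−8; the coefficient covariance is the
  inverse observed information. Convergence defaults: relative tolerance
  1e−8, iteration cap 200.
* Score categories never used in the data are collapsed before fitting
  (their cutpoints are unidentifiable); a response with fewer than two
  distinct categories is an error, as is a rank-deficient model matrix
  (reported with the offending covariate).
* Random-intercept standard deviations are optimized on the log scale with a
  floor of 1e−4; a solution at the floor is reported as a variance *pinned
  at zero* with a recorded note, not an error (this is the expected outcome
  when, e.g., only one observer is present). Standard errors come from the
  numerically differentiated observed information of the Laplace objective,
  profiled over pinned variances.
* Wald p-values are reported with the conventional stars (0.05, 0.01,
  0.001; a degree sign for non-significant), and the per-criterion
  dose-reduction table suppresses DR cells whose $b$ is not significant at
  0.05, while keeping the numeric estimate programmatically available.

## Dose reduction and its uncertainty

`dose_reduction()` implements $DR = 1 - e^{-b/a}$, defined only for
$a > 0$ (if quality does not improve with dose there is nothing to trade).
It is negative when $b < 0$ — the algorithm switch would *cost* dose — and
satisfies the exact reciprocity $(1 - DR_{A\to B})(1 - DR_{B\to A}) = 1$
and invariance under rescaling of the latent scale.

How the published confidence limits for DR were computed is typically not
stated in study reports; `dose_reduction_ci()` therefore offers three
methods and defaults to the delta method on the ratio $r = b/a$ (smooth,
symmetric intervals on $r$, mapped through the monotone transform
$1 - e^{-r}$ so the endpoints carry over directly). The Fieller interval
solves the exact ratio quadratic and is reported as unbounded — never
silently truncated — when $a$ is not significantly positive; the parametric
bootstrap resamples $(a, b)$ from the fitted Gaussian and is seeded. On
well-determined fits the three agree closely (the test suite checks
delta-vs-bootstrap endpoint agreement within 0.03).

## The comparison design

The exact arrow set of a given study's pairwise scheme is rarely published.
The default 12-pair design was chosen so that every analysis of interest is
estimable from one dataset: for each of the three algorithms the two
adjacent dose pairs (42 vs 98, 98 vs 140 mAs), plus the three
between-algorithm comparisons at each of 42 and 98 mAs. Whether
cross-algorithm pairs are also shown at the top tube load is unknowable from
the literature; the design is overridable via `vgr_design()` and
YAML-serializable. Left/right side assignment is *not* part of the design:
it is randomized per (patient, pair) presentation at simulation time, so the
design object stays deterministic.

Analyses are restricted by default to the 42–98 mAs interval
(`dose_interval = c(42, 98)`) because the proportional relationship between
log tube load and latent quality typically breaks down at the top of the
dose range for iterative algorithms; records whose pair involves 140 mAs
are then excluded.

## What the simulator emulates — and what it does not

`simulate_study()` generates records with exactly the statistical structure
the model assumes: logistic residuals, per-criterion normal random
intercepts, side randomization, and replicated presentations that reuse the
original hanging and intercepts with fresh residuals. Defaults (50 patients,
5 observers, 6 criteria, 12 pairs, $a = 2.3$, $b_{IR3} = 1.0$,
$b_{IR5} = 1.7$, $\sigma_{patient} = \sigma_{observer} = 0.5$, symmetric
thresholds $(-3, -1, 1, 3)$, 5 replicated presentations per observer) match
the dimensions of a full single-centre reader study and effect magnitudes of
the size reported for iterative-reconstruction comparisons; the thresholds
put most probability on scores −1..+1, as observed score histograms usually
do.

Deliberately *not* simulated: image pixel data and noise texture, observer
search behaviour, drift or learning effects over reading sessions,
criterion-to-criterion correlation within a grading (criteria are
independent given the design), and any misspecification of the residual
distribution. Passing tests on simulated data therefore demonstrate that
the estimation machinery is correct *under the model's own assumptions*,
not that the model is adequate for any particular real reader study. The
replicate count is interpreted as five re-presented hangings **per
observer** (the natural reading for intra-observer reliability; a study
replicating five hangings once overall could not estimate per-observer
kappa), and is configurable.

## Observer reliability

`weighted_kappa()` computes the two-rater weighted kappa on the 5-category
scale with disagreement weights $|i-j|/4$ (linear, the default — the common
default of two-rater weighted-kappa procedures) or $((i-j)/4)^2$
(quadratic), a large-sample (Fleiss–Cohen–Everitt) confidence interval, and
exact-match percent agreement. Published "percent agreement" figures are
interpreted as exact-match agreement; a within-one-category agreement is
available separately (`within_one_agreement()`) and never conflated with
it. Inter-observer summaries use original assessments only; intra-observer
summaries pair each replicate with its original. Records are canonicalized
(side order normalized, scores sign-flipped accordingly) before matching, so
hangings randomized to different orientations remain comparable.

## Validation scale

The test suite validates the pipeline at sizes chosen to make the checks
sharp but quick: oracle comparisons on 30-record instances, mixed-model
parameter recovery on 20 full-size replicates (50 patients × 5 observers,
one criterion fitted per replicate since all criteria share the generating
truth), null calibration and interval coverage on 100 and 50 scaled-down
replicates (15 patients, 3 observers, one criterion). These sizes are the
package's own validation design; all are regenerated programmatically at
test time.

## Known limitations

* The Laplace approximation is a single-mode approximation; with very few
  observers the observer-variance estimate is noisy and its SE should not be
  over-interpreted.
* No Bayesian estimation, generalized estimating equations, multi-rater
  (Fleiss-type) kappa, or partial proportional odds.
* Dose reduction is reported as a fraction of tube load only; translation
  into CTDI_vol, SSDE or effective dose is out of scope.
* Real reader data from published studies are not redistributable; the
  bundled `published_coefficients()` table carries only the fitted
  coefficients, so printed coefficient values can be turned into DR worked
  examples but the underlying regressions cannot be refitted here.
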
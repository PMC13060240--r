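---
title: "Modelling biologically aligned developmental trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling biologically aligned developmental trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajalign)
```

`trajalign` analyses longitudinal developmental cohorts in which subjects
mature at different chronological ages. This vignette documents the
statistical machinery, the choices behind its defaults, and what the
package's synthetic validation does and does not establish.

## Biological age alignment

Chronological age is a poor common axis for small developmental cohorts:
two subjects of the same age can be at clearly different maturational
stages. The package therefore aligns every subject to a per-subject
biological marker — in the motivating setting, the age (months) at distal
tibial epiphyseal closure, a standard skeletal indicator of
mid-adolescence — and works throughout on

$$t_{ij} = \text{age}_{ij} - \text{marker}_i,$$

so $t = 0$ is the same biological stage for every subject. Alignment is a
pure shift: it is bijective per subject (`align_ages()` plus the marker
recovers chronological age exactly) and no marker is ever imputed — a
subject without one is an error, since silently mixing aligned and
unaligned axes would corrupt every downstream fit. Ages are carried in
months everywhere; the only year/month conversion factor (exactly 12) lives
at the I/O boundary.

## Trajectory model

For each outcome $y$ separately, with $i$ indexing subjects and $j$
sessions,

$$y_{ij} = f(t_{ij}) + b_{0i} + b_{1i}\,t_{ij} + \varepsilon_{ij},
  \qquad b_{0i} \sim N(0, \sigma_0^2),\;
  b_{1i} \sim N(0, \sigma_1^2),\;
  \varepsilon_{ij} \sim N(0, \sigma^2).$$

* $f$ is a cubic regression spline with **shrinkage penalty**
  (`bs = "cs"`, $k = 5$ basis functions): the penalty also shrinks the
  otherwise-unpenalized linear component, so as the smoothing parameter
  $\lambda \to \infty$ the smooth collapses to zero rather than to an
  arbitrary line. $k = 5$ is deliberately small: with quarterly visits over
  ~3.5 years there are ~14 distinct ages per subject, and developmental
  trajectories of this kind are monotone-to-saturating, not wiggly.
* Random intercepts *and* random slopes on aligned age absorb stable
  subject differences in level and growth rate. With four subjects the
  variance components are weakly identified; when the full structure fails
  to fit, `fit_smooth()` falls back to intercepts only, then to none, each
  with an explicit warning rather than silence.
* Estimation is REML throughout, via `mgcv::gam()` with the random effects
  expressed as `"re"` smooths. This is the standard modern equivalent of
  wrapping `lme` (identical model, one penalized-likelihood machinery) and
  is markedly more robust at very small subject counts, which drove the
  choice.
* Session percent-correct is modelled **as Gaussian on the percent scale**,
  not binomially on trials. The trajectory object of interest is the
  session-level metric that is plotted and correlated downstream; with
  ~360 trials per pooled session the within-session binomial error is small
  and approximately constant. This is a documented modelling choice, not a
  claim that trial counts are uninformative.

Fitted trajectories are predicted on a **fixed 100-point grid**, evenly
spaced between the earliest and latest *aligned behavioral* ages, shared by
every outcome in a similarity family so curves are comparable point by
point. (One hundred grid points, hence 99 intervals; extrapolation beyond
an outcome's own fitted range is permitted on the shared grid but flagged.)
Pointwise 95% intervals come from the Bayesian coefficient covariance
$V_\beta$.

A zero-variance response (a perfectly constant outcome) is represented
directly as the degenerate intercept-only fit — constant curve, zero
derivative, zero coefficient uncertainty — since REML machinery has nothing
to estimate there.

## Developmental-change windows

The derivative of the fitted curve is approximated by central finite
differences with step equal to the grid spacing, evaluated through the
difference of linear-predictor matrices so that
$\hat{f}'(t) = X_d \hat\beta$ is exactly linear in the coefficients. A
**simultaneous** $1-\alpha$ band is calibrated by posterior simulation:
draw $\beta^{(b)} \sim N(\hat\beta, V_\beta)$ (default
`n_sim = 10000`; fewer than 100 draws is refused), form the maximum over
the grid of the absolute standardized deviation, and take its $1-\alpha$
quantile as the critical multiplier. Contiguous grid runs where the band
excludes zero become signed change windows. Because the band is
simultaneous, under a flat truth the expected flagged fraction of the grid
is well below $\alpha$ — the suite's null calibration checks exactly this.
Where several outcomes are tested in separate fits, the per-outcome Wald
p-values of the smooth (a convention: the model summary's s-table test) are
Benjamini–Hochberg corrected via `fdr_adjust()`.

## Trajectory similarity

Two fitted curves $X, Y$ on the shared grid are compared by:

1. **z-scoring** each curve (sample SD, divisor $n-1$; the divisor cancels
   in $r$ and only rescales RMSE uniformly).
2. **Pearson $r$** between the z-scored curves.
3. **Folding**: each z-scored curve is shifted so its first grid value is
   zero and absolute values are taken,
   $\tilde X_i = |X_{z,i} - X_{z,1}|$, mapping rising and falling curves
   onto a common non-negative scale; then
   $\mathrm{RMSE} = \sqrt{\tfrac1n \sum_i (\tilde X_i - \tilde Y_i)^2}$.
   (The square root is part of the definition — the statistic is a
   root-mean-square error; folded curves are already non-negative so no
   second absolute-value pass occurs.)
4. **maxT permutation inference**: per permutation, every pair's $Y$ curve
   has its grid indices independently reshuffled and $r$ recomputed; the
   family null statistic is $T_b = \max_{\text{pairs}} |r|$, and
   $p_{\text{maxT}} = (1 + \#\{T_b \ge |r_{\text{obs}}|\})/(n_{\text{perm}}+1)$,
   bounded below by $1/(n_{\text{perm}}+1)$. The family is whatever set of
   pairs is passed in one call; the pipeline uses one family per tract
   metric (all FA tracts vs behavior; all RD tracts vs behavior), keeping
   the two metrics' corrections separate.

Two caveats are deliberate. Index permutation treats grid points as
exchangeable; fitted curves are smooth and strongly autocorrelated, so this
null is **anti-conservative** for smooth trajectories and the p-values
should be read as a family-wise-calibrated ranking device rather than exact
error rates (the test-suite calibration uses white-noise curves, where the
null is exact). And constant curves are refused outright: similarity of a
flat trajectory is undefined, not zero.

By construction the whole statistic chain is invariant to positive-scale
affine maps of either raw curve, and negating a curve flips $r$'s sign
while leaving the folded RMSE unchanged — both are enforced as
property-style tests.

## The synthetic cohort generator

No public data accompany the motivating study design, so validation rests
on a generator that emulates its stated conditions, fixed once:

| parameter | default | rationale |
|---|---|---|
| subjects | 4 | cohort size of the emulated design |
| visits | quarterly, 34–75 months | stated follow-up span and cadence |
| marker age | $N(57.9, 3.6^2)$ months | stated mid-adolescence distribution |
| sessions/visit | 19 | stated average session count per time point |
| task variants | logit offsets $+0.4, 0, -0.4$ | only the ease ordering (overlap > zero-gap > gap) is stated; magnitudes chosen to separate variant means by ~8–10 percentage points mid-range |
| behavior latent curve | logistic, 45→92%, midpoint $-8$ mo, scale 5 mo | steep early-adolescent gains then plateau |
| firing rate | logistic 12→32 Hz, midpoint 0, scale 8 mo; noise SD 3 Hz | gradual increase through the marker age |
| rate random effects | intercept SD 0.5 Hz, slope SD 0.01 Hz/mo | modest inter-individual variation, small relative to the 20 Hz dynamic range so the population curve stays identifiable from 4 subjects |
| tract batteries | 53 FA (rising 0.35→~0.5), 53 RD (falling ~1.05→~0.8 ×10⁻³ mm²/s) | tract count of the emulated atlas; FA/RD magnitudes typical of primate white matter |

Latent maturation curves are four-parameter logistics on aligned age;
tract-to-tract heterogeneity (midpoints spread over $[-12, 6]$ aligned
months, cycling steepness and asymptote separation) is deterministic by
tract index, so no extra random streams exist. FA-type shapes are
non-decreasing and RD-type non-increasing by contract, checked on a dense
grid. Binomial session probabilities that subject effects push outside
$[0,1]$ are clamped and counted, with a warning — never silently.

Randomness is organized as one master seed with per-outcome streams derived
by a stable string hash of (seed, outcome name): adding an outcome to a
config never perturbs existing realizations, and an identical config
regenerates byte-identical data. Each dataset carries its latent truth
sampled on the analysis grid (for pooled behavior: the variant-averaged
percent-scale curve) for recovery testing.

What the generator does **not** emulate: trial-by-trial eye movements,
spike trains, image- or tensor-level diffusion data, session-to-session
learning effects, missing visits, or any misalignment of the marker itself.
Passing recovery and calibration tests on this cohort therefore shows the
machinery is correct and well calibrated under the stated noise model — it
does not certify performance on real data whose noise is less well behaved.

## Numerical choices and problem sizes

* Finite-difference step = grid spacing; endpoint derivatives use the same
  central stencil, evaluating the spline basis just outside the grid
  (linear extrapolation of the cubic basis).
* Degenerate bands: grid points whose derivative standard error is below
  $10^{-12}$ cannot be standardized and are never flagged.
* Mann–Whitney `compare_timepoints()` switches from exhaustive enumeration
  of all group assignments (ties handled by construction) to a
  tie-corrected normal approximation with continuity correction at combined
  $n = 16$; identical samples return $p = 1$ by contract.
* Permutation p-values use the add-one convention and a $10^{-12}$ tie
  tolerance on $|r|$ comparisons.
* The stochastic validation suites run at sizes chosen to make Monte-Carlo
  error small relative to the asserted margins: 100 seeded replicates for
  logistic-truth recovery; 500 replicates (1000 posterior draws each) for
  the flat-null derivative calibration; 500 families of five length-100
  pairs at 200 permutations for maxT family-wise error; 200 replicates for
  pointwise CI coverage.

## Known limitations

* Four subjects identify the population curve only up to the cohort mean of
  the random effects; the recovery criterion implicitly assumes
  inter-individual variation modest relative to the outcome's dynamic
  range, as the generator's defaults encode.
* The Wald p-value feeding the FDR step is a convention, not a likelihood
  ratio; with $k = 5$ and strong signals this distinction is immaterial,
  but near-null outcomes inherit the usual anti-conservatism of smooth
  Wald tests.
* The similarity permutation null ignores curve autocorrelation (above); a
  circular-shift null would preserve it, and the pairing structure of
  `maxt_permutation()` accommodates one, but it is not part of the default
  pipeline because the emulated analysis used index permutation.
* Gaussian modelling of percent-correct can in principle predict outside
  $[0, 100]$ near the range ends; confidence intervals are not truncated.
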
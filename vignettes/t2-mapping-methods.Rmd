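---
title: "Methods: voxelwise T2 mapping and Bayes segmentation of carotid plaque"
author: "carotidT2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxelwise T2 mapping and Bayes segmentation of carotid plaque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotidT2)
```

This vignette is the package's account of the science it implements: the
signal model and its assumptions, the estimation and classification
procedures, the digital phantom used for validation, and the numerical and
design choices made where more than one defensible option existed.

## Signal model

A multiple-spin-echo (CPMG) acquisition collects one magnitude image per
echo time. For a voxel with transverse relaxation time $T_2$ the ideal
signal is mono-exponential,

$$ SI(TE) = \beta \, e^{-TE/T_2}, $$

where $\beta$ absorbs proton density, $T_1$ weighting, coil sensitivity
and amplifier gain. Two acquisition realities shape the estimator:

* **The first echo is special.** Refocusing pulses are never exactly
  180°, so echoes after the first contain stimulated-echo signal in
  addition to the primary echo; only the first echo is purely primary and
  therefore does *not* lie on the decay curve traced by the later echoes.
  The fit always discards echo 1 — with the default 8-echo grid
  $TE = 12.9k$ ms ($k = 1..8$), seven points remain. A corollary tested as
  an invariant: arbitrarily corrupting echo 1 (e.g. residual slow-flow
  signal that double-inversion-recovery failed to null) changes no output.
* **Magnitude noise is Rician.** At low SNR the magnitude operation turns
  zero-mean complex noise into a positive floor (Rayleigh with mean
  $\sigma\sqrt{\pi/2}$ in signal-free voxels). Echoes at long TE whose
  SNR ($SI/\sigma$) falls below 2 carry more floor than decay, so the
  trailing contiguous run of such points is removed, scanning from the
  last echo backwards. An isolated low point interior to the curve is
  kept: the rule targets "points at long TE", and removing interior noise
  dips would bias the fit against downward noise excursions.

## Voxelwise estimation

For each voxel with at least `min_points = 3` surviving echoes (three
points leave one residual degree of freedom for a two-parameter t-test):

1. **Robust log-linear initialization.** Ordinary least squares on
   $\ln SI$ is noise-sensitive because the log transform skews the error
   distribution, so the line is fitted by iteratively reweighted least
   squares with Tukey bisquare weights (tuning constant 4.685, the
   standard 95%-efficiency choice; scale = median absolute residual /
   0.6745, re-estimated each iteration; at most 50 iterations or a
   maximum weight change below 1e-8). Points with $SI \le 0$ are dropped
   before the log (they cannot occur in magnitude data but the guard is
   cheap). The slope $s$ and intercept $a$ give
   $T_2^{(0)} = -1/s$ (only meaningful for $s < 0$) and
   $\beta^{(0)} = e^a$. Standard errors come from the weighted normal
   equations and each estimate is tested against zero on the
   t-distribution with $n-2$ degrees of freedom.
2. **Initialization gate.** The linear estimates seed the nonlinear fit
   only when both reject the null at $p < 0.05$; otherwise the
   conventional defaults $\beta = 500$, $T_2 = 50$ ms are used. The gate
   exists purely to improve convergence — the final estimates come from
   the nonlinear fit either way.
3. **Levenberg–Marquardt fit** of $\sum_k (SI_k - \beta e^{-TE_k/T_2})^2$
   (via `minpack.lm::nls.lm` with the analytic Jacobian), relative
   tolerance 1e-8, at most 200 iterations, bounds $\beta > 0$ and
   $T_2 \in (1, 2000]$ ms. The bounds only exclude physically meaningless
   solutions; they are far outside the tissue range.
4. **Inference and acceptance.** Standard errors are the Gauss–Newton
   covariance $s^2 (J^\top J)^{-1}$ with $s^2 = RSS/(n-2)$; p-values are
   two-tailed on the t-distribution with $n-2$ degrees of freedom (the
   procedure names the t-distribution; $n-2$ is the natural residual
   dof for two parameters), and 95% confidence intervals are
   $\hat\theta \pm t_{0.975,\,n-2}\,SE$. A voxel enters the T2 map only
   when **both** $\beta$ and $T_2$ are significant at $p < 0.05$; each
   rejected voxel records why (`insufficient_points`, `below_noise`,
   `nonsignificant`, `nonconverged`). A singular curvature matrix yields
   infinite SEs and $p = 1$, i.e. rejection.

Useful invariants, all enforced by tests: rescaling all intensities and
the noise SD by a common factor leaves $T_2$ and p-values unchanged and
scales $\beta$ and SEs proportionally; on noise-free data the fit recovers
the generating parameters to solver tolerance; on pure noise the dual gate
accepts far fewer than 5% of voxels; and on any series the converged LM
solution's RSS is at or below the minimum of a dense 400×400 log-spaced
$(\beta, T_2)$ grid.

The noise SD $\sigma$ is a single scalar per acquisition. When it is not
supplied it is estimated from a signal-free background region on the last
echo by inverting the Rayleigh mean ($\hat\sigma = \bar m / \sqrt{\pi/2}$,
default) or the Rayleigh SD ($\hat\sigma = s_m/\sqrt{2 - \pi/2}$); the two
agree within a few percent on genuine background, which is itself a useful
sanity check of the mask.

## Segmentation

Accepted wall voxels are classified by a Gaussian naive-Bayes model over
T2: $P(C_i \mid T_2) \propto P(C_i)\, \phi\!\big((T_2-\mu_i)/\sigma_i\big)/\sigma_i$,
with equal priors by default and per-class $(\mu_i, \sigma_i)$ estimated
(sample mean, $n-1$ SD) from labelled training voxels — around 100 per
class, supplied either as `(class, t2_ms)` values or as `(class, row,
col)` coordinates resolved against a T2 map. The MAP rule assigns the
highest-posterior class; exact ties (measure zero for continuous T2) break
by the fixed class order LRNC < fibrous < recent IPH. Normal intima/media
is not a separate class — it shares the fibrous-tissue class, as its T2
(54 ± 13 ms) is indistinguishable from fibrous tissue (56 ± 9 ms) in this
framework.

The label as a function of T2 can change only at roots of pairwise
log-density equalities, which are quadratics in $T_2$ (linear for equal
SDs). `decision_boundaries()` solves them analytically; a 0.001-ms scan of
the classifier is the independent oracle in the tests. At the default
parameters the regions are IPH below ~17 ms (an inconsequential left-tail
artifact of the unequal variances), LRNC ~17–45 ms, fibrous ~45–74 ms and
recent IPH above ~74 ms.

**Calcification** precedes Bayes classification (a design choice the
procedure description leaves open; calcified voxels have no valid T2, so
they must not reach the classifier). Calcium carries almost no water
signal: a wall voxel is flagged when its synthetic proton-density-weighted
intensity — the decay curve evaluated at TE = 14 ms — has SNR < 2. For
voxels whose gated fit was rejected, two readings of "the curve" exist and
both are implemented:

* `pdw_mode = "fitted"` (default): evaluate a fitted curve for every
  voxel — the gated fit's estimates where that fit ran, otherwise a
  smoothing LM fit of all post-first-echo points with no SNR trimming.
  For a signal-free voxel this gives a smoothed noise-floor value rather
  than a single Rayleigh draw.
* `pdw_mode = "first_echo"`: trust only accepted fits and use the
  measured first-echo intensity (TE 12.9 ≈ 14 ms) everywhere else.

Neither reading flags every signal-free pixel: a single Rayleigh draw
falls below $2\sigma$ with probability $1 - e^{-2} \approx 86\%$, and the
smoothing fit occasionally chases a spurious decay pattern in the noise,
so either mode masks roughly 85–95% of truly calcified pixels at realistic
noise levels, with essentially no false positives on accepted tissue.

An optional post-filter (`min_iph_component`) removes recent-IPH islands
below a minimum 4-connected size, relabelling them to the runner-up class.
It exists because isolated T2 overestimates masquerade as IPH, but it is
**off by default** — the original analysis applied no such filter.

## The digital phantom

The phantom generates what the downstream stages need and nothing more: a
2D cross-section with a suppressed lumen (ideal black blood), an annular
vessel wall of fibrous tissue containing circular component blobs, an
optional sternocleidomastoid-muscle disc, per-pixel ground-truth
$(T_2, \beta)$ drawn from per-tissue Gaussians (T2 truncated at a 1 ms
physical floor), and a simulated Multi-SE series: mono-exponential decay,
first echo multiplied by `first_echo_scale = 0.85` (the
primary-vs-stimulated-echo mismatch has unspecified magnitude; any value
≠ 1 serves, because the first echo is always discarded and the pipeline
must be — and is tested to be — insensitive to it), optional smooth
multiplicative coil shading, and Rician noise
$\sqrt{(S+n_1)^2 + n_2^2}$, $n_{1,2} \sim N(0, \sigma)$.

Defaults, fixed once as the study conditions: 96×96 grid at 0.25 mm
(a 160 mm FOV reconstructed to 640 px), lumen radius 8 px, outer wall
radius 24 px; two LRNC blobs (r = 7 px) and one large recent-IPH blob
(r = 7 px) — component proportions then mirror the composition reported
for segmented advanced carotid plaques (~69% fibrous, ~19% LRNC, ~10%
recent IPH as in the single large confirmed haemorrhage, ~2%
calcification) — plus a 3-px calcification; tissue T2 distributions
LRNC 37 ± 5, fibrous 56 ± 9, intima/media 54 ± 13, recent IPH 107 ± 25,
muscle 39 ± 6 ms; amplitude means 500 (the conventional default
initializer is the only amplitude anchor in the source analysis — tissue
amplitudes are free phantom parameters) with SD 25; and
$\sigma = 11.25$, chosen so the *measured* first-echo SNR on the fibrous
wall is 30, which puts the last echo near SNR 7 — inside the "≥ 30 down
to ≥ 4" range typical of normal carotid wall in vivo.

What the phantom deliberately does **not** emulate — and therefore what
passing tests do not certify about real data: stimulated-echo pathways
(no Bloch/EPG simulation, so no $T_1$-weighting contamination of late
echoes and no genuine first-echo physics, just the amplitude scale),
partial-volume mixing at tissue boundaries (pixel-center rasterization
gives pure-tissue pixels), k-space effects (partial Fourier, blurring,
zero-padding correlations — noise is i.i.d. per pixel), multi-coil noise
correlations, motion and flow artifacts beyond an optional echo-1 lumen
term, and through-plane geometry.

## Numerical and interface choices

* Degenerate inputs: fewer than 3 positive points fail the log-linear
  stage; a non-negative log-linear slope (within 1e-10) is declared
  non-decaying with $p_{T_2} = 1$; zero-residual exact fits get $p = 0$
  rather than NaN; an all-zero background estimates $\sigma = 0$ with a
  warning; empty ROIs and mismatched grids are errors.
* Validation problem sizes (the package's own choice of scale): 500
  Monte-Carlo voxels per tissue class for parameter-recovery checks, 10^4
  draws for classifier calibration, 1500 pure-noise voxels for the
  false-acceptance rate, 100 random series against the grid-search
  oracle, and the default 96×96 phantom (~1600 wall voxels) end to end.
* Coordinates are 1-based `(row, col)` with pixel centers at integer
  positions — the idiomatic R convention, applied consistently across
  masks, training tables and label maps.
* Image I/O is NIfTI with the TE vector (and noise SD) in a JSON sidecar
  keyed `te_ms`: volumetric headers carry echo timing too inconsistently
  across dialects to be the canonical path. Label maps use a documented
  integer code table (`label_codes()`); masks are written as 8-bit
  volumes.

## Known limitations

* **Classified means are biased estimators of tissue T2.** Averaging
  voxels *as classified* truncates each class's distribution at the MAP
  boundaries and admits leakage from neighbouring classes. For the middle
  (fibrous) class the two effects largely cancel; for a rare long-T2
  class such as recent IPH the boundary truncation alone shifts the
  classified mean upward by several ms (for $N(107, 25^2)$ truncated at
  73.6 ms, +4.5 ms) while leakage from the far more abundant fibrous
  class pulls it down by a composition-dependent amount — classified IPH
  means several ms away from the generating 107 ms are therefore expected
  behaviour of the procedure, not a pipeline defect. The same phenomenon
  appears in vivo as sparse, spuriously IPH-labelled voxels with
  intermediate T2.
* The estimator inherits mono-exponential assumptions: multi-compartment
  decay, stimulated-echo $T_1$ contamination and short-$T_2$ species
  sampled only from the second echo onward all bias $T_2$ in real
  acquisitions in ways the phantom cannot reveal.
* The calcification rule is a one-threshold classifier on a noisy
  quantity; its ~10% miss rate on truly signal-free pixels at SNR 30 is
  intrinsic (see above), and partially calcified voxels with residual
  signal will evade it entirely.
* Cohen's kappa is reported unweighted by default (the conventional form
  for AHA plaque-type tables; linear and quadratic weights are available
  as options). With 37 paired readings its sampling uncertainty is
  substantial; the package reports the point statistic only.
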
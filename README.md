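# carotidT2

Quantitative T2 mapping and Bayesian segmentation of carotid
atherosclerotic plaque from black-blood multi-echo spin-echo (Multi-SE /
CPMG) image series.

Multicontrast vessel-wall CMR characterizes plaque components (lipid-rich
necrotic core, fibrous tissue, intraplaque haemorrhage, calcification) from
*relative* signal intensities, which vary across scanners and depend on a
muscle reference and on coil shading. A quantitative T2 map replaces that
with an absolute physical measurement per voxel. `carotidT2` implements the
full analysis chain for such maps, for imaging scientists and
cardiovascular researchers working with (or simulating) carotid
relaxometry:

1. **Voxelwise T2 estimation.** Each voxel's multi-echo magnitude signal
   follows a mono-exponential decay,

   ```
   SI(TE) = beta * exp(-TE / T2)
   ```

   The first echo is always discarded (it is the only pure primary echo;
   later echoes also carry stimulated-echo signal), and trailing echoes
   with SNR < 2 are dropped. A robust IRLS log-linear fit of `ln SI`
   against TE (Tukey bisquare weights, c = 4.685, MAD scale) initializes a
   Levenberg–Marquardt nonlinear least-squares fit; standard errors come
   from the Gauss–Newton covariance `s^2 (J'J)^-1`, and a voxel enters the
   T2 map only when both `beta` and `T2` are significant (two-tailed
   t-test, p < 0.05).
2. **Plaque segmentation.** Calcification is detected on a synthetic
   proton-density-weighted image (the fitted curve evaluated at TE = 14 ms)
   by an SNR < 2 rule; remaining accepted wall voxels are assigned by a
   Gaussian naive-Bayes classifier with the maximum-a-posteriori rule,
   `P(C_i | T2) ∝ P(C_i) P(T2 | C_i)`, to lipid-rich necrotic core
   (~37 ± 5 ms at 3 T), fibrous tissue (~56 ± 9 ms) or recent intraplaque
   haemorrhage (~107 ± 25 ms), with equal priors and class Gaussians
   trained from ~100 labelled voxels per class.
3. **Statistics.** Per-class voxel counts and T2 mean ± SD, and
   inter-reader agreement over ordered AHA plaque-type categories (percent
   agreement and Cohen's kappa).
4. **A digital carotid phantom** (annular wall, component blobs, suppressed
   lumen, Rician magnitude noise, first-echo amplitude anomaly, optional
   coil shading) so every stage is testable without patient data.

All results are tidy tibbles (`tidy()`, `glance()`) with `autoplot()`
methods; images are plain R matrices/arrays read and written as NIfTI with
a JSON TE sidecar. Coordinates are 1-based `(row, col)` with pixel centers
at integer positions.

## Worked example

```r
library(carotidT2)
set.seed(7)

# a diseased-artery phantom at the study's acquisition settings:
# TE = 12.9 * (1..8) ms, first-echo SNR ~ 30 on the fibrous wall
spec  <- phantom_spec(seed = 7L)
ph    <- build_phantom(spec)
ser   <- simulate_series(ph)
masks <- phantom_masks(ph)

map <- fit_t2_map(ser, masks$wall, spec$noise_sd)
map
#> T2 map: 1596 ROI voxels, 1568 accepted (98.2%), noise SD 11.2
#>   accepted T2: median 54.0 ms (IQR 44.7-63.8)

training <- tibble::tibble(
  class = rep(c("LRNC", "fibrous", "recent_IPH"), each = 100),
  t2_ms = c(rnorm(100, 37, 5), rnorm(100, 56, 9), rnorm(100, 107, 25)))
model <- train_class_model(training)
seg   <- segment_plaque(map, masks$wall, model)
tidy(seg)
#> # A tibble: 5 x 2
#>   class         n_voxels
#> 1 LRNC               426
#> 2 fibrous            954
#> 3 recent_IPH         188
#> 4 calcification       22
#> 5 rejected             6

class_summary(seg, map)
#> # A tibble: 4 x 4
#>   class         n_voxels mean_ms sd_ms
#> 1 LRNC               426    38.3  4.77
#> 2 fibrous            954    57.4  7.08
#> 3 recent_IPH         188   108.   26.6
#> 4 calcification       22    NA    NA
```

98.2% of wall voxels pass the dual significance gate; the segmented class
means land close to the generating tissue distributions (LRNC 37 ± 5,
fibrous 56 ± 9, recent IPH 107 ± 25 ms — classification truncation biases
class means by a millisecond or two, see the methods vignette). The
signal-free calcification blob is caught by the synthetic-PDW rule.

Inter-reader agreement on a 6-category AHA plaque-type table:

```r
agreement_stats(carotid_aha_table())
#> # A tibble: 1 x 3
#>       n percent_agreement kappa
#> 1    37              75.7 0.681
```

`autoplot(map)`, `autoplot(seg)`, `autoplot(model)` and
`autoplot(fit_monoexponential(...))` draw the T2 map, the label map, the
class densities with MAP boundaries, and a single-voxel decay fit with its
95% confidence band.

## Command line

A thin CLI wraps the same functions (installed at
`inst/scripts/t2map`):

```sh
t2map simulate  --config spec.json --out sim/ --seed 7
t2map fit       --series sim/series.nii --roi sim/wall_mask.nii --out fit/
t2map segment   --series sim/series.nii --wall sim/wall_mask.nii \
                --training train.csv --out seg/
t2map summarize --fit fit/ --seg seg/ --out sum/
t2map agree     --table inst/extdata/aha_reader_table.csv
```

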
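# hamfrac

Multifractal image analysis of fat marbling in tissue slices.

Photographs of hand-cut dry-cured ham (and similar marbled tissue) can be
segmented into a binary fat/muscle mask whose spatial organization carries
quality information: the amount and arrangement of intramuscular fat. This
package is for researchers who want to turn such photographs — or fully
synthetic stand-ins with known ground truth — into generalized (Rényi)
fractal dimensions of the fat phase, and to compare segmentation with and
without high-pass illumination correction.

## What it computes

**Segmentation.** Two paths from a square RGB crop (default 512 × 512 px)
to a fat/muscle mask:

* *unfiltered*: Rec. 601 grayscale, fixed threshold 175 (≥ 175 → fat);
* *high-pass* (`hp25`/`hp50`): grayscale, Gaussian high-pass
  `g − G_σ∗g + 128` with σ = radius/3 (radius 25 or 50 px), Overlay blend
  of that layer back onto the grayscale original, threshold 150. Smooth
  illumination/color heterogeneity maps to neutral mid-gray and is removed
  before thresholding.

Masks export to a three-column coordinate table (horizontal position,
vertical position, code 1 = fat / 2 = muscle) as headerless CSV.

**Sandbox dimensions.** With `M_i(r)` the fat mass in a disc of radius `r`
centered on a random fat pixel and `M₀` the total fat mass, the order-q
statistic

    y_q(r) = 1/(q−1) · ln⟨(M_i(r)/M₀)^(q−1)⟩      (q ≠ 1)
    y_1(r) = ⟨ln(M_i(r)/M₀)⟩                       (entropy limit)

is regressed on `ln(r/L)`; the OLS slope estimates `D_q`, reported with its
regression standard error and R². Defaults: 1000 centers, 12 geometric
radii in [5, L/4] px, q = 0, 1, 2 (capacity, information and correlation
dimensions; `D_q` is non-increasing in q).

**Synthetic data.** `make_slice()` generates marbled slices (dark-red lean
matrix, white fat streaks and clusters at a controllable area fraction)
under a smooth multiplicative shading field of chosen amplitude and
correlation length, returning the image together with its ground-truth
mask; benchmark fractals (Sierpinski carpet, filled square, line) provide
analytic oracles. `run_batch()` orchestrates whole experiments
deterministically from one seed.

## Worked example

```r
library(hamfrac)

# a 512 px synthetic slice: 20 % fat under strong (amplitude 0.3) shading
sl <- make_slice(slice_params(fat_fraction_target = 0.2,
                              illumination_amplitude = 0.3, seed = 42))
sl$realized_fat_fraction
#> 0.2006

mask <- run_highpass(sl$image, filter_config(radius_px = 25))
mean(mask == sl$mask)          # pixel agreement with ground truth
#> 1

analyze_mask(mask, sandbox_config(seed = 7))
#> sandbox multifractal analysis
#>   fat fraction: 0.2006
#>   D_0 = 1.7639 (se 0.0336, R^2 0.9964)
#>   D_1 = 1.7203 (se 0.0286, R^2 0.9973)
#>   D_2 = 1.6861 (se 0.0235, R^2 0.9981)
```

The high-pass path recovers the ground-truth mask perfectly despite the
shading, and the fat phase shows a genuinely multifractal signature
(D0 > D1 > D2, each with regression SE well below 0.1). On an analytic
oracle the estimator lands close to the known value:

```r
analyze_mask(make_sierpinski_carpet(5)$mask, sandbox_config(seed = 7))
#> sandbox multifractal analysis
#>   fat fraction: 0.5549
#>   D_0 = 1.8617 (se 0.0150, R^2 0.9994)
#>   D_1 = 1.8579 (se 0.0150, R^2 0.9994)
#>   D_2 = 1.8548 (se 0.0151, R^2 0.9993)
```

(analytic value log 8 / log 3 ≈ 1.8928 for all three).

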
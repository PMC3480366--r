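---
title: "Texture signatures as diversity proxies: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture signatures as diversity proxies: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texdiv)
```

## The model

`texdiv` treats a windowed satellite band as a *texture*: a field whose
intensity fluctuations are stochastic and multiscale. An orthogonal 2-D
wavelet decomposition separates those fluctuations by scale and orientation
into `3L` detail subbands; within each subband the coefficients are modelled
as i.i.d. zero-mean generalized Gaussian (GGD) samples

$$p(x) = \frac{\beta}{2\alpha\Gamma(1/\beta)}
         \exp\!\left\{-\left(\frac{|x|}{\alpha}\right)^{\beta}\right\},$$

a two-parameter family spanning heavy-tailed ($\beta < 1$), Laplacian
($\beta = 1$), Gaussian ($\beta = 2$) and near-uniform ($\beta \to \infty$)
behavior. The zero-mean assumption is structural: detail coefficients are
outputs of high-pass filters. The joint window model is the product of the
per-subband densities — independence across subbands is knowingly an
approximation, adopted because it keeps the divergence additive and the
computation closed-form while preserving discrimination power.

Two windows are compared by the symmetrized Kullback–Leibler divergence,
summed over subbands with non-negative weights (all 1 by default). We use
the *sum* of the two directed divergences (Kullback's J, the discriminant
information); the averaged convention differs only by a factor of two and
can be obtained by halving. Since each directed KL between two GGDs has a
closed form, a signature comparison costs microseconds regardless of window
size.

The ecological reading: pixel-intensity Shannon entropy of the green band is
a first-order diversity index (a richness proxy, to be calibrated against
measured α diversity before being read in species units), while the
signature divergence is a second-order index that captures pairwise
community change in time (a turnover proxy for β diversity, measured on the
occurrence side as 1 − Jaccard per pixel).

## Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `wavelet` | `"d4"` | 4-tap orthogonal Daubechies filter. Orthogonality makes the transform energy-preserving (testable via Parseval) and keeps subband models comparable; `haar` and `d8` are available, and the choice is deliberately a configuration, not a claim. |
| `levels` | 3 | 9 subbands; deeper levels need windows ≥ `16 · 2^L` per side so the coarsest subband keeps ≥ 16×16 coefficients for a stable fit. |
| `method` | `"mle"` | per-subband profile maximum likelihood, initialized from moment matching; falls back to the moment estimate (flagged, still used) if the profile score has no bracketed root. |
| shape bracket | `[0.15, 10]` | root-finding bracket for β, geometrically expanded up to 4 times; covers heavy-tailed to near-uniform textures while keeping `Γ(1/β)` representable (all Γ ratios are computed in log space). |
| min samples per fit | 64 | below this, shape estimates are unstable. |
| `max_cloud_frac` | 0.20 | *strict* upper bound on the masked fraction of a candidate window (`< 0.20`, not ≤). |
| `stride` | 16 px | moving-window scan step; stride 1 is exhaustive and is what the tests compare against brute force. |
| `n_bins`, `log_base` | 256, 2 | entropy histogram over 8-bit DN, reported in bits (maximum 8); both configurable. |
| `resolution` | 30 m | occurrence gridding cell, matching the imagery. |
| `n_boot` | 1000 | bootstrap resamples for the 95% slope interval; jackknife available. |

Conventions: pixel indices are 0-based `(row, col)` with half-open window
bounds; boundary-equidistant occurrence records go to the smaller index;
divergences are in nats (divide by `log(2)` for bits); masked pixels are
excluded from the entropy histogram but replaced by the window median before
decomposition (entropy tolerates gaps, the transform needs a complete grid);
window dimensions are cropped down to multiples of `2^L`.

## What the synthetic generators emulate

`synth_texture` draws each subband's coefficients from prescribed GGD
parameters, fixes the approximation band at a constant DC level, inverts the
transform, and min-max rescales to 8-bit DN — emulating quantized imagery,
including the mild nonlinearity that quantization induces. With
`quantization = 0` the raw real-valued reconstruction is returned; this is
used where exact control of subband scales matters (see below).
`synth_cloud_mask` grows random disks to a requested coverage (trimmed to
within one pixel). `synth_occurrences` generates multi-period communities by
per-species i.i.d. replacement at rate τ — the simplest process with a
tunable closed-form expected Jaccard, `(1−τ)/(1+τ)` for large pools at
constant richness — and scatters records uniformly in the domain box.

What they do **not** emulate: sensor radiometry and atmospheric effects,
spatially clustered species distributions, seasonal phenology, or
cross-subband dependence. Passing tests therefore demonstrate that the
estimators and the pipeline are correct and discriminating under the stated
model, not that the proxies are ecologically valid for any particular
landscape — that validation requires real imagery and occurrence data.

## Numerical choices

- **Γ ratios in log space** throughout (`lgamma`); `Γ(1/β)` overflows for
  small β long before the ratios do.
- **Exact GG sampling** via `x = sign · α · G^{1/β}`, `G ~ Gamma(1/β, 1)`:
  no rejection, so sample streams are reproducible and cheap.
- **Identical parameters short-circuit the KL to exactly 0**, so divergence
  matrices of identical inputs are exactly zero rather than ~1e−16.
- **Degenerate subbands** (constant coefficient sets, e.g. from constant
  windows) are kept in the signature but flagged, and the divergence refuses
  them rather than inventing parameters.
- **Window selection** maximizes area under the cloud cap using an integral
  image (O(1) masked-count per candidate); ties break to the smallest
  `(row0, col0)`, then smallest height and width. The tests verify stride-1
  agreement with two independent exhaustive searches.
- **Moment ratio range**: `(E|x|)² / E(x²)` must lie in (0, 3/4); values at
  or beyond the uniform limit are reported as fit failures rather than
  clamped.

## Design decisions taken where the design was open

- *Symmetrization*: the sum (J divergence) rather than the average, matching
  the discriminant-information reading; matrices under the two conventions
  are proportional.
- *Quantization and scale*: min-max DN rescaling makes the intensity
  histogram — and hence the entropy — invariant to a common scaling of all
  subband widths; what differentiates entropies of synthetic textures is the
  *shape* of the coefficient law (heavy tails compress the bulk into few DN
  bins). Tests that need an exact, scale-sensitive divergence target
  therefore standardize unquantized windows to unit variance, where
  consecutive-window model divergences can be solved for exactly.
- *Minimum window side* `16 · 2^L`: chosen so every subband clears the
  64-sample fit floor with a wide margin.
- *Entropy on raw DN* (not calibrated reflectance), in bits with 256 bins:
  green-band entropies near 6 on an 8-bit scale are then directly
  interpretable against the maximum of 8.
- *Occurrence downscaling*: a deterministic nearest-pixel-center assignment
  (with a lexicographic tie-break) stands in for stochastic point-process
  downscaling; `regrid` coarse-grains by set union (coarsening) or
  replication (refining), both of which preserve γ exactly.
- *Entropy-to-species rescaling*: both a linear calibration against measured
  α (`calibrate_linear`, optionally on min-max-normalized entropy) and the
  Hill order-1 effective number (`diversity_number`, `base^H`) are exposed;
  the package deliberately does not hard-wire one conversion, because the
  two can disagree and the right choice is an empirical calibration.
- *Anomaly rule*: rows of the divergence matrix whose mean off-diagonal
  divergence exceeds `median + 3·MAD` are flagged — a robust rule that
  reproduces the "one clouded year lights up a full row and column" pattern
  and usefully ranks acquisitions for exclusion.

## Problem sizes used by the test suite

Closed-form oracles run on a 20-point `(α, β)` grid against adaptive
quadrature (tolerance 1e−6). Estimator recovery uses 50 seeded replicates at
n = 10⁴ (with monotonicity checked across 10³–10⁵). Closed-loop
discrimination uses 10 + 10 textures of 256×256 at shapes 1.2 vs 1.7.
Turnover recovery uses 200 replicate 2-period landscapes (richness 30, pool
300) per τ ∈ {0, 0.2, 1}, compared with an independent set-process
simulation. Calibration coverage uses 500 noisy-line datasets with 500
bootstrap resamples each. Window-selection oracles run exhaustively at
stride 1 on 128×128 and 40×40 fixtures.

## Known limitations

- Independence across subbands is an approximation; strongly oriented or
  periodic textures violate it most.
- The entropy proxy saturates: once a window occupies all 256 DN bins,
  additional heterogeneity is invisible.
- Windows are rectangles; a landscape whose clear area is L-shaped will be
  under-covered.
- The β estimate is biased upward slightly by DN quantization for very
  heavy-tailed textures (the closed-loop tolerance of 10% accounts for it).
- The replacement-process landscape has no spatial community structure, so
  per-pixel and community-level Jaccard coincide only in the
  single-cell/community limit used by the recovery tests.
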
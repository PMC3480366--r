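# texdiv

Multiresolution texture signatures for monitoring plant species richness and
turnover from satellite imagery.

## The problem

Field campaigns that measure wetland biodiversity are expensive, slow, and
cover only a sliver of the landscape. Decades of medium-resolution satellite
imagery (Landsat-like, 30 m, 8-bit digital numbers) are freely available for
the same landscapes. `texdiv` implements a statistical texture method that
reads two classical diversity quantities out of a single image band:

- **Species richness (α diversity)** is proxied by the pixel-intensity
  Shannon entropy of a representative window: the more distinct reflectance
  levels healthy vegetation produces in the green band, the more plant types
  are plausibly present.
- **Species turnover (β diversity)** between two dates is proxied by a
  divergence between the *textures* of the two images, computed from a
  wavelet decomposition rather than from raw intensities, so that it is
  sensitive to multiscale spatial structure and to pairwise community change
  that an entropy difference cannot see.

The package also implements the occurrence-data side needed to validate such
proxies — gridding species records onto pixels, Jaccard turnover in time,
linear calibration with bootstrap/jackknife intervals — and seeded synthetic
generators so the entire pipeline is testable without any external data.

## The model

A window is decomposed by an `L`-level orthogonal 2-D wavelet transform
(periodized Daubechies filters; default `d4`, `L = 3`), giving `3L` detail
subbands. The coefficients `x` of each subband `s` are modelled as i.i.d.
draws from a zero-mean generalized Gaussian density

```
p_s(x) = β_s / (2 α_s Γ(1/β_s)) · exp( − (|x| / α_s)^β_s )
```

with width factor `α_s` and shape `β_s` (`β = 2` Gaussian, `β = 1`
Laplacian, `β → ∞` uniform). Parameters are estimated per subband by profile
maximum likelihood (moment matching as starting point and fallback). The
ordered set of `(α_s, β_s)` pairs is the window's **texture signature**; the
joint model is the product over subbands.

Two GGDs have a closed-form Kullback–Leibler divergence

```
KL(p1 ‖ p2) = log( β1 α2 Γ(1/β2) / (β2 α1 Γ(1/β1)) )
            + (α1/α2)^{β2} · Γ((β2+1)/β1) / Γ(1/β1)  −  1/β1 ,
```

and two signatures are compared by the symmetrized, weighted sum over
subbands (Kullback's J divergence),

```
D(a, b) = Σ_s w_s · [ KL(p_s^a ‖ p_s^b) + KL(p_s^b ‖ p_s^a) ] ,
```

with unit weights by default. A series of dated signatures yields a
symmetric, zero-diagonal **divergence matrix** whose anomalous rows (mean
off-diagonal divergence above `median + 3·MAD`) expose unusable
acquisitions, such as heavily clouded scenes.

On the occurrence side, records are assigned to the nearest 30 m pixel
center; per-pixel α is the number of unique species, γ the domain-wide
count, and turnover between two dates is `1 − Jaccard` of the per-pixel
species sets.

## Worked example

Generate a texture with a known per-subband law, fit its signature, and
compare it against a same-class and a different-class texture:

```r
library(texdiv)

pars <- c(lapply(c(8, 8, 6),   function(a) ggd_params(a, 1.2)),
          lapply(c(13, 13, 10), function(a) ggd_params(a, 1.2)),
          lapply(c(20, 20, 15), function(a) ggd_params(a, 1.2)))
spec <- texture_spec(c(256, 256), wavelet = "d4", levels = 3,
                     subband_params = pars)
img <- synth_texture(spec, seed = 42)

w <- analysis_window(img, season = "dry", year = 1999)
intensity_entropy(w)
#> [1] 6.739566

sig <- fit_signature(w, wavelet = "d4", levels = 3, method = "mle")
sig
#> Texture signature: d4 wavelet, 3 levels, 9 subbands
#>  level orientation     n    alpha     beta method fallback degenerate
#>      1  horizontal 16384 20.59419 1.170617    mle    FALSE      FALSE
#>      1    vertical 16384 21.90930 1.240199    mle    FALSE      FALSE
#>      1    diagonal 16384 15.39436 1.186991    mle    FALSE      FALSE
#>      2  horizontal  4096 33.97619 1.211900    mle    FALSE      FALSE
#>      ...

# same texture class, different seed: small divergence
other <- fit_signature(synth_texture(spec, seed = 43), "d4", 3)
kl_signature(sig, other)
#> [1] 0.01465582

# different shape class (beta 1.8 instead of 1.2): ~30x larger divergence
shifted <- texture_spec(c(256, 256), "d4", 3,
                        lapply(pars, function(p) ggd_params(p$alpha, 1.8)))
kl_signature(sig, fit_signature(synth_texture(shifted, seed = 44), "d4", 3))
#> [1] 0.4101712
```

The entropy (6.74 bits on an 8-bit scale) plays the role of the richness
proxy; the signature's fitted shapes recover the generating `β = 1.2` within
a few percent, and the divergence separates texture classes cleanly from
within-class estimation noise. (Fitted `α` are on the quantized DN scale,
hence larger than the generator's; divergences depend only on ratios.)

For full series, `run_entropy_series()`, `run_divergence_matrix()` and
`run_validation()` orchestrate window selection, signature fitting, matrix
construction (CSV + heatmap with the lower triangle rendered), anomaly
flagging, and calibration of entropy/divergence against occurrence-derived
α and β. A thin command-line wrapper is installed at
`inst/scripts/texdiv.R` (`entropy`, `matrix`, `validate`, `simulate`
subcommands).

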
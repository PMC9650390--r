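---
title: "Local extreme map guided fusion: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local extreme map guided fusion: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemfuse)
```

## The filtering model

A guided filter fits, inside every $r \times r$ window $k$, a linear
model between a guidance image $I$ and an input $p$:

$$a_k = \frac{\mathrm{cov}(I, p)_k}{\mathrm{var}(I)_k + \epsilon},
\qquad b_k = \bar p_k - a_k \bar I_k,$$

and outputs $q = \bar a \odot I + \bar b$ with the coefficients averaged
over all windows covering each pixel. Structure present in the guidance
survives; structure absent from it is smoothed away. The usual choice
$I = p$ therefore *preserves* salient features — which is the wrong
behavior when the goal is to move those features into detail layers.

The filter at the heart of this package replaces the guidance with
morphological local extreme maps under a flat disk of radius $k$:

1. a pass guided by the local minimum map $\mathrm{erode}(I, se)$, whose
   construction removes every salient bright structure narrower than the
   disk, so the filter removes them too;
2. a pass guided by the local maximum map of the *once-filtered* image,
   $\mathrm{dilate}(I_f', se)$, which analogously removes salient dark
   structures.

The second pass takes its extreme map from the intermediate image, not
from the original input: dilating the original would re-inject the
bright features the first pass just removed. `legf_filter()` implements
this literally, and its `guidance` argument exposes the `"min"`-only,
`"max"`-only and `"self"`-guided variants so the ablation (the extreme
variant leaves strictly more residual detail energy, with the polarity
of each single variant matching the features it cannot remove) is a
plain function call; the test suite asserts it on an impulse phantom.
The `"self"` variant runs two self-guided passes so that its smoothing
budget matches the two-pass extreme variant structurally.

## Multi-scale decomposition and fusion

With $I_f^0 = I$, scale $i$ filters $I_f^{i-1}$ using window $r_i$ and
disk radius $k_i$; bright and dark maps are the positive and negative
parts of $I_f^{i-1} - I_f^i$, and the final smooth image is the base.
Because each scale's maps sum exactly to the difference of consecutive
filtered images, the full stack telescopes back to the input — an
identity the tests assert to below $10^{-9}$ on the 0–255 scale across
phantom sizes 32–256.

Fusion of two decompositions uses elementwise max on bright maps, min on
dark maps (keeping whichever source has the stronger feature), and max
on bases. Each fused scale is then weighted by its Shannon entropy
divided by the minimum entropy across scales, so the least informative
scale keeps weight exactly 1 and every other scale is enhanced. Dark
maps are negated before the entropy is taken. Two consequences are
useful as end-to-end probes and are part of the test suite: fusing an
image with itself (weights disabled) reproduces it to float tolerance,
and the pipeline is exactly symmetric in its two arguments.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `n_scales` | 5 | number of decomposition scales |
| `window_sizes` | 3, 5, 7, 9, 11 | guided-filter window side length per scale ($2i+1$) |
| `disk_radii` | = `window_sizes` | flat-disk radius of the extreme maps |
| `gf_epsilon` | 0.01 | guided-filter regularizer on 0–1 normalized intensities |
| `entropy_bins` | 256 | histogram bins over \[0, 255\] for the weights |
| `enhance_weights` | TRUE | entropy-based detail enhancement on/off |

The scale schedule is the published setting. Two points are
interpretation choices rather than published facts and are pinned here:

* **$r$ is the window side length**, so the schedule means 3×3 … 11×11
  windows. "Size of the local window" reads most plainly as side length,
  and $2i+1$ is odd by construction, which a side length must be.
* **$\epsilon$ acts on the 0–1 scale.** The regularizer's magnitude only
  makes sense relative to the intensity range; dividing by 255 before
  the fit follows the original guided-filter practice, and 0.01 is that
  literature's customary default. Nothing in the fusion method depends
  delicately on it: the reconstruction identity holds for every
  $\epsilon$, since the feature maps absorb whatever the filter leaves.

## Numerical conventions

* All computation is double precision on the 0–255 scale; 16-bit input
  is linearly rescaled at load (the entropy binning and metric
  conventions assume 8-bit dynamic range). Intermediate feature maps are
  signed and unclipped; clipping and half-to-even rounding happen only
  at 8-bit export.
* Disk membership is the closed disk $di^2 + dj^2 \le k^2$; toolbox
  disc approximations differ, so the footprint is pinned by enumeration
  tests.
* Morphology and box means replicate edge pixels / renormalize by the
  in-bounds count at borders, avoiding the spurious border extrema that
  zero-padding would create.
* Zero-variance windows with $\epsilon = 0$ use the limit convention
  $a = 0$, $b = $ window mean; with the default $\epsilon > 0$ this
  never triggers.
* Entropy weights divide by the minimum entropy, which is 0 for blank
  feature maps (possible on constant or synthetic inputs); the fallback
  is all-unit weights with a warning, preserving the weighted-sum
  semantics in the limit.
* Values above 255 are clipped into the top histogram bin for entropy
  purposes only. The final fused image can exceed 255 where enhanced
  features stack; it is clipped at export and kept unclipped in memory.
* Color fusion uses full-range BT.601 ($Y = 0.299R + 0.587G + 0.114B$,
  $Cb = 128 + 0.564(B-Y)$, $Cr = 128 + 0.713(R-Y)$), invertible over
  \[0, 255\] to within one intensity level; the chroma planes bypass the
  fusion entirely.
* The average-gradient metric uses
  $\mathrm{mean}\sqrt{(\Delta_x^2+\Delta_y^2)/2}$ over forward
  differences; conventions vary across the fusion literature, so scores
  are comparable within this package, not across papers.

## What the phantoms emulate — and what they do not

`make_ct_like()` builds a sharp bright skull annulus around an exactly
homogeneous dim interior, with mild bounded noise on the exterior
background; `make_mr_like()` builds textured soft tissue (smooth blobs
plus band-limited noise) with bright and dark lesions written exactly
60 levels off their local background at known loci;
`make_pet_like()` builds smooth pseudo-color activity blobs with
genuinely non-neutral chroma. All randomness sits behind one seed, the
caller's RNG state is restored, and ground-truth masks are returned so
tests can assert at known pixels.

The CT interior is deliberately feature-free. The fusion rules guarantee
`fused >= source - (partner's cumulative dark features)` at any pixel,
so ground-truth transfer statements are *exact* only where the partner
contributes no dark detail. Edge influence propagates roughly
$2\sum_i (k_i + r_i - 1)$ pixels across the five scales, which is why
the exact transfer check runs at the full 256 px working size (where
the lesion ring lies outside the skull's reach) while smaller sizes
assert the transfer with a few-level margin and a salience bound.

Consequences for interpretation: passing these tests shows the
decomposition, fusion rules and weights behave as specified, and that
known features survive fusion. It does **not** show robustness to the
things real atlas pairs add — registration error, modality-dependent
noise *inside* the tissue, intensity non-standardization, or partial
volume effects. In particular, on real data the min-rule will pull the
fused image a few levels below a source wherever the *other* modality
carries dark texture, exactly as the bound above predicts; that is the
method's intended behavior, not an artifact.

## Problem sizes in the shipped checks

The test suite exercises oracle equivalences on 8–16 px images (where
brute-force per-window references are exact and cheap), property checks
on 32–96 px phantoms, and the reconstruction, transfer, determinism and
throughput checks up to the full 256 px working size, the standard
whole-brain atlas slice size. The acceptance script fuses one 256 px
pair per run and recomputes every reported number from scratch.

## Known limitations

* Exactly two source images; decision-map and more-than-two-source
  fusion schemes are out of scope.
* Gray guidance only (the color pathway fuses luminance); no 3-channel
  guidance matrix inversion, and no fast-guided-filter subsampling.
* No registration, resampling or denoising: inputs must be aligned and
  the same size, and the method will faithfully fuse artifacts it is
  given.
* Reference-based quality metrics from the wider literature (Qabf,
  VIFF, structural-similarity families) are not computed; the report
  schema reserves their keys.
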
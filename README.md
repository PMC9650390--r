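# lemfuse

Multi-scale fusion of co-registered multi-modal brain images (CT/MR gray
pairs, or PET/SPECT pseudo-color with gray MR) built on a **local extreme
map guided image filter**.

## The problem and the method

Different brain imaging modalities capture complementary information: CT
shows dense structure (bone), MR shows soft tissue, PET/SPECT show
function. Clinicians often need one image that keeps the salient content
of both sources. The difficulty is that "salient content" is exactly what
a good edge-preserving smoother refuses to remove — so base/detail
decompositions built on ordinary filters leave the most important
features stuck in the base layer.

The core primitive here steers a guided filter with *morphological local
extreme maps* instead of the image itself. For an image *I* with a
flat-disk structuring element *se* of radius *k* and window size *r*:

1. `I_f' = guidedfilter(I, I_min, r)` with `I_min = erode(I, se)` — the
   local minimum map contains no salient bright features, so the filter
   removes them;
2. `I_f = guidedfilter(I_f', I_max, r)` with `I_max = dilate(I_f', se)` —
   the local maximum map of the once-filtered image likewise removes the
   salient dark features.

Applying this filter over an increasing schedule of scales (defaults:
n = 5, windows r_i = 2i + 1 = 3, 5, 7, 9, 11, disk radii k_i = r_i)
yields per-scale **bright** and **dark feature maps**

    F_b,i = max(I_f^(i-1) − I_f^i, 0),   F_d,i = min(I_f^(i-1) − I_f^i, 0)

and a base image I_base = I_f^n, with the exact telescoping identity
Σᵢ(F_b,i + F_d,i) + I_base = I. Two images are fused by

* per-scale elementwise **max** on bright maps, **min** on dark maps,
* entropy weights w_i = e_i / min_j(e_j) (≥ 1, anchored at 1) that
  enhance the more informative scales,
* elementwise **max** on the base images,
* and summing the three parts: I_fuse = F_b^fuse + F_d^fuse + I_base^fuse.

Pseudo-color sources are fused on their BT.601 luminance channel; chroma
passes through untouched. No-reference quality metrics (spatial
frequency SF, average gradient AbG, standard deviation STD, entropy E)
are included, along with a seeded phantom-pair generator so the entire
pipeline is testable offline.

## Worked example

```r
library(lemfuse)

ct <- make_ct_like(256, seed = 1)   # dense skull, homogeneous interior
mr <- make_mr_like(256, seed = 2)   # soft tissue, bright/dark lesions

fused <- fuse_pair(ct$image, mr$image, fusion_config())
metric_report(clip_to_uint8(fused))
#> Fusion quality metrics
#>   SF   37.0607
#>   AbG  7.3374
#>   STD  70.9036
#>   E    6.6174
```

The fused image scores higher than either source on every detail metric
(CT alone: SF 33.06, AbG 4.43, E 2.60; MR alone: SF 9.07, AbG 2.00,
E 4.09): the sharp skull and the textured tissue with its lesions both
survive into one image. The entropy weights that produced it are
recoverable via `fuse_pair(..., details = TRUE)`:

```r
det <- fuse_pair(ct$image, mr$image, fusion_config(), details = TRUE)
round(det$weights_bright, 3)
#> [1] 1.288 1.000 1.091 1.185 1.247
```

The minimum weight is exactly 1 by construction; all other scales are
enhanced in proportion to their information content.

### Command line

```sh
Rscript exec/lemfuse synth --kind ct --size 256 --seed 1 -o ct.png
Rscript exec/lemfuse synth --kind mr --size 256 --seed 2 -o mr.png
Rscript exec/lemfuse fuse ct.png mr.png -o fused.png --metrics report.json
Rscript exec/lemfuse metrics fused.png -o metrics.json
```

`fuse` auto-detects color+gray pairs and routes them through the
luminance protocol; `--scales`, `--eps`, `--no-enhance`, `--config
cfg.yaml` and `--dump-maps dir/` expose the pipeline's knobs and
internals (per-scale feature maps, dark maps exported as absolute
values).

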
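# Fusion rules: per-scale elementwise max/min on feature maps,
# entropy-derived enhancement weights, elementwise max on the bases.

#' Fuse one scale of bright and dark feature maps
#'
#' Bright maps are fused by elementwise maximum (keep the stronger bright
#' feature), dark maps by elementwise minimum (keep the stronger dark
#' feature, which is the more negative value).
#'
#' @param b1,b2 bright maps (>= 0), same size.
#' @param d1,d2 dark maps (<= 0), same size.
#' @return list with matrices `bright` and `dark`.
#' @export
fuse_feature_scale <- function(b1, b2, d1, d2) {
  validate_pair(b1, b2); validate_pair(d1, d2); validate_pair(b1, d1)
  list(bright = pmax(b1, b2), dark = pmin(d1, d2))
}

#' Shannon entropy of an intensity map
#'
#' Histogram entropy in bits: values are clipped into \[0, 255\] (feature
#' sums can exceed 255; anything above lands in the top bin, for the
#' histogram only), quantized into `bins` equal-width bins, and
#' \eqn{-\sum p \log_2 p} is taken over occupied bins.
#'
#' @param img numeric matrix with nonnegative values (negate dark maps
#'   before calling).
#' @param bins number of histogram bins over \[0, 255\].
#' @return entropy in bits, >= 0.
#' @export
#' @examples
#' shannon_entropy(matrix(c(0, 0, 255, 255), 2))  # 1 bit
shannon_entropy <- function(img, bins = 256L) {
  img <- validate_image(img)
  if (any(img < 0))
    .stop_lemfuse("shannon_entropy expects nonnegative values; negate dark maps first",
                  "lemfuse_option_error")
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 1L)
    .stop_lemfuse("bins must be a positive integer", "lemfuse_option_error")
  idx <- pmin(floor(pmin(img, 255) / 255 * bins) + 1L, bins)
  p <- tabulate(idx, nbins = bins)
  p <- p[p > 0] / length(img)
  -sum(p * log2(p))
}

#' Entropy-derived enhancement weights
#'
#' Weight of scale i is its entropy divided by the minimum entropy over
#' scales, so the least informative scale has weight exactly 1 and every
#' other scale is enhanced (weight >= 1) in proportion to its information
#' amount.  Dark maps are negated before the entropy is taken.  If the
#' minimum entropy is 0 (blank feature map, possible on synthetic or
#' constant inputs) the ratio is undefined and all weights fall back to 1
#' with a warning.
#'
#' @param fused_maps list of fused feature maps (one per scale).
#' @param polarity `"bright"` or `"dark"`.
#' @param bins histogram bins for the entropy.
#' @return numeric vector of weights, `min(weights) == 1`.
#' @export
compute_weights <- function(fused_maps, polarity = c("bright", "dark"),
                            bins = 256L) {
  polarity <- match.arg(polarity)
  if (!is.list(fused_maps) || length(fused_maps) < 1L)
    .stop_lemfuse("fused_maps must be a non-empty list",
                  "lemfuse_option_error")
  e <- vapply(fused_maps, function(m) {
    if (polarity == "dark") m <- -m
    shannon_entropy(m, bins)
  }, numeric(1))
  if (min(e) == 0) {
    warning("zero minimum entropy among ", polarity,
            " feature maps; falling back to unit weights")
    return(rep(1, length(e)))
  }
  e / min(e)
}

#' Weighted sum of per-scale feature maps
#'
#' @param fused_maps list of n matrices.
#' @param weights numeric vector of length n.
#' @return single matrix, \eqn{\sum_i w_i F_i}.
#' @export
integrate_features <- function(fused_maps, weights) {
  if (length(fused_maps) != length(weights))
    .stop_lemfuse("fused_maps and weights lengths differ",
                  "lemfuse_option_error")
  out <- fused_maps[[1L]] * weights[1L]
  for (i in seq_along(fused_maps)[-1L])
    out <- out + fused_maps[[i]] * weights[i]
  out
}

#' Fuse two base images
#'
#' Elementwise maximum, preserving the brighter low-frequency content of
#' either source at each pixel.
#'
#' @param base1,base2 matrices of the same size.
#' @return elementwise maximum.
#' @export
fuse_base <- function(base1, base2) {
  chk <- validate_pair(base1, base2)
  pmax(chk$a, chk$b)
}

#' Fuse two co-registered grayscale images
#'
#' Runs the full pipeline: decompose both sources over the scale schedule
#' in `cfg`, fuse bright/dark maps per scale by max/min, weight each
#' fused scale by its entropy ratio (unless `cfg$enhance_weights` is
#' off), sum the weighted maps, fuse the bases by elementwise max, and
#' add the three parts.  The returned image is the unclipped
#' floating-point fusion; clipping to \[0, 255\] happens only in
#' [write_image()] / [clip_to_uint8()].
#'
#' @param img1,img2 numeric matrices of identical size on the 0-255
#'   scale.
#' @param cfg a [fusion_config()].
#' @param details if `TRUE`, also return the per-stage internals.
#' @return the fused matrix; with `details = TRUE` a list with `image`,
#'   `fused_bright`, `fused_dark` (per-scale lists), `weights_bright`,
#'   `weights_dark`, `base`, and both decompositions.
#' @export
#' @examples
#' a <- make_ct_like(32, seed = 1)$image
#' b <- make_mr_like(32, seed = 2)$image
#' f <- fuse_pair(a, b)
#' range(f)
fuse_pair <- function(img1, img2, cfg = fusion_config(), details = FALSE) {
  chk <- validate_pair(img1, img2)
  stopifnot(inherits(cfg, "fusion_config"))
  d1 <- decompose_image(chk$a, cfg)
  d2 <- decompose_image(chk$b, cfg)
  n <- cfg$n_scales
  fb <- vector("list", n)
  fd <- vector("list", n)
  for (i in seq_len(n)) {
    s <- fuse_feature_scale(d1$bright[[i]], d2$bright[[i]],
                            d1$dark[[i]], d2$dark[[i]])
    fb[[i]] <- s$bright
    fd[[i]] <- s$dark
  }
  if (cfg$enhance_weights) {
    wb <- compute_weights(fb, "bright", cfg$entropy_bins)
    wd <- compute_weights(fd, "dark", cfg$entropy_bins)
  } else {
    wb <- wd <- rep(1, n)
  }
  base <- fuse_base(d1$base, d2$base)
  fused <- integrate_features(fb, wb) + integrate_features(fd, wd) + base
  if (!details) return(fused)
  list(image = fused, fused_bright = fb, fused_dark = fd,
       weights_bright = wb, weights_dark = wd, base = base,
       decomposition1 = d1, decomposition2 = d2)
}
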
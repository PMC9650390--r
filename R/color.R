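# Color protocol for PET/SPECT-like pseudo-color sources: fusion runs on
# the luminance channel only; chroma passes through untouched.  Full-range
# BT.601 is pinned here (no 16-235 footroom/headroom) — the common
# convention in image fusion, and invertible over [0, 255].

#' RGB to full-range BT.601 YCbCr
#'
#' @param img H x W x 3 array with values in \[0, 255\].
#' @return list of matrices `Y`, `Cb`, `Cr` on the 0-255 scale
#'   (neutral chroma is 128).
#' @export
#' @examples
#' rgb_to_ycbcr(array(128, c(2, 2, 3)))  # Y = 128, Cb = Cr = 128
rgb_to_ycbcr <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    .stop_lemfuse("expected an H x W x 3 RGB array",
                  "lemfuse_option_error")
  R <- img[, , 1L]; G <- img[, , 2L]; B <- img[, , 3L]
  Y <- 0.299 * R + 0.587 * G + 0.114 * B
  list(Y = Y,
       Cb = 128 + (B - Y) * 0.564,
       Cr = 128 + (R - Y) * 0.713)
}

#' Full-range BT.601 YCbCr to RGB
#'
#' Exact inverse of [rgb_to_ycbcr()] up to floating point; out-of-gamut
#' combinations are clipped to \[0, 255\] rather than raising an error.
#'
#' @param Y,Cb,Cr matrices of identical size.
#' @return H x W x 3 RGB array, values in \[0, 255\].
#' @export
ycbcr_to_rgb <- function(Y, Cb, Cr) {
  validate_pair(Y, Cb); validate_pair(Y, Cr)
  R <- Y + (Cr - 128) / 0.713
  B <- Y + (Cb - 128) / 0.564
  G <- (Y - 0.299 * R - 0.114 * B) / 0.587
  out <- array(0, c(nrow(Y), ncol(Y), 3L))
  out[, , 1L] <- R; out[, , 2L] <- G; out[, , 3L] <- B
  pmin(pmax(out, 0), 255)
}

#' Fuse a pseudo-color image with a grayscale image
#'
#' The color source (PET/SPECT-like functional map) is converted to
#' YCbCr; its luminance is fused with the grayscale image through
#' [fuse_pair()]; the fused luminance is recombined with the color
#' source's original Cb/Cr and converted back to RGB.  Chroma is never
#' touched by the fusion.
#'
#' @param color_img H x W x 3 array in \[0, 255\].
#' @param gray_img matrix of matching height/width.
#' @param cfg a [fusion_config()].
#' @param details if `TRUE`, return internals (fused Y before clipping,
#'   chroma, and the [fuse_pair()] details).
#' @return H x W x 3 fused RGB array; or a list when `details = TRUE`.
#' @export
fuse_color_gray <- function(color_img, gray_img, cfg = fusion_config(),
                            details = FALSE) {
  ycc <- rgb_to_ycbcr(color_img)
  validate_pair(ycc$Y, gray_img)
  fd <- fuse_pair(ycc$Y, gray_img, cfg, details = TRUE)
  rgb <- ycbcr_to_rgb(fd$image, ycc$Cb, ycc$Cr)
  if (!details) return(rgb)
  list(image = rgb, Y_fused = fd$image, Cb = ycc$Cb, Cr = ycc$Cr,
       fuse = fd)
}
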
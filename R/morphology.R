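# Flat-disk grayscale morphology.  These erosions/dilations produce the
# local minimum and maximum maps that guide the filter; exact closed-disk
# footprints and replicate borders are part of the method's definition
# here, which is why this is implemented in-package rather than through a
# toolbox whose disc approximation and padding differ.

#' Flat disk structuring element
#'
#' Builds the (2k+1) x (2k+1) boolean footprint of the closed disk of
#' radius `k`: cell (di, dj) is a member iff di^2 + dj^2 <= k^2.
#'
#' @param k disk radius, positive integer.
#' @return object of class `structuring_element` with fields `radius` and
#'   `footprint` (logical matrix).
#' @export
#' @examples
#' make_disk(1)$footprint   # 3x3 plus shape, 5 member cells
make_disk <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L)
    .stop_lemfuse("disk radius k must be a positive integer",
                  "lemfuse_option_error")
  d <- -k:k
  fp <- outer(d^2, d^2, "+") <= k^2
  structure(list(radius = k, footprint = fp), class = "structuring_element")
}

# Replicate-pad a matrix by `k` pixels on every side.
.pad_replicate <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  img[c(rep(1L, k), seq_len(h), rep(h, k)),
      c(rep(1L, k), seq_len(w), rep(w, k)), drop = FALSE]
}

# Sliding extremum over the disk footprint.  Vectorized over pixels: one
# pmin/pmax per footprint offset against a shifted view of the padded
# image.  Border policy is edge replication, which for a flat SE equals
# taking the extremum over the in-bounds part of the footprint.
.morph <- function(img, se, op) {
  img <- validate_image(img)
  if (!inherits(se, "structuring_element"))
    .stop_lemfuse("se must be a structuring_element (see make_disk)",
                  "lemfuse_option_error")
  k <- se$radius
  h <- nrow(img); w <- ncol(img)
  pad <- .pad_replicate(img, k)
  off <- which(se$footprint, arr.ind = TRUE) - (k + 1L)  # offsets in -k..k
  out <- NULL
  for (m in seq_len(nrow(off))) {
    di <- off[m, 1L]; dj <- off[m, 2L]
    view <- pad[(1L + k + di):(h + k + di), (1L + k + dj):(w + k + dj),
                drop = FALSE]
    out <- if (is.null(out)) view else op(out, view)
  }
  out
}

#' Grayscale erosion under a flat disk
#'
#' Each output pixel is the minimum of the input over the disk footprint
#' centered there (the local minimum map).  Borders replicate edge
#' pixels, so no spurious extrema are introduced at the image frame.
#'
#' @param img numeric matrix.
#' @param se structuring element from [make_disk()].
#' @return matrix of the same size, elementwise `<= img`.
#' @export
erode <- function(img, se) .morph(img, se, pmin)

#' Grayscale dilation under a flat disk
#'
#' Per-pixel maximum over the footprint (the local maximum map); the
#' exact dual of [erode()]: `dilate(img, se) == -erode(-img, se)`.
#'
#' @inheritParams erode
#' @return matrix of the same size, elementwise `>= img`.
#' @export
dilate <- function(img, se) .morph(img, se, pmax)
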
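#' @keywords internal
"_PACKAGE"

# All computation runs in double precision on the 0-255 intensity scale.
# Source images satisfy 0 <= v <= 255 after loading; intermediate feature
# maps may be negative (dark features) or exceed 255 (enhanced sums), so
# images are only clipped at export time.

.stop_lemfuse <- function(msg, class) {
  stop(structure(class = c(class, "lemfuse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Validate a single-channel image
#'
#' Checks that `img` is a numeric matrix with positive dimensions and only
#' finite values.  Returns the matrix (as storage-mode double) invisibly
#' usable in a pipeline.
#'
#' @param img numeric matrix on the 0-255 scale (intermediate maps may lie
#'   outside that range).
#' @param name label used in error messages.
#' @return the validated matrix, storage mode double.
#' @export
validate_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    .stop_lemfuse(sprintf("%s must be a numeric matrix", name),
                  "lemfuse_option_error")
  if (nrow(img) < 1L || ncol(img) < 1L)
    .stop_lemfuse(sprintf("%s has degenerate dimensions %dx%d", name,
                          nrow(img), ncol(img)), "lemfuse_option_error")
  bad <- which(!is.finite(img))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(img))
    .stop_lemfuse(sprintf("%s contains a non-finite value at (%d, %d)",
                          name, ij[1L], ij[2L]), "lemfuse_nonfinite_error")
  }
  storage.mode(img) <- "double"
  img
}

#' Validate a pair of images for fusion
#'
#' The two sources must share dimensions exactly (the method assumes prior
#' spatial registration) and contain only finite values.
#'
#' @param a,b numeric matrices.
#' @return list with elements `a` and `b`, unchanged.
#' @export
#' @examples
#' validate_pair(matrix(0, 4, 4), matrix(255, 4, 4))
validate_pair <- function(a, b) {
  a <- validate_image(a, "first image")
  b <- validate_image(b, "second image")
  if (!identical(dim(a), dim(b)))
    .stop_lemfuse(sprintf("image shapes differ: %dx%d vs %dx%d",
                          nrow(a), ncol(a), nrow(b), ncol(b)),
                  "lemfuse_shape_error")
  list(a = a, b = b)
}

.ext_of <- function(path) tolower(tools::file_ext(path))

#' Read an image from disk onto the 0-255 working scale
#'
#' PNG, TIFF and JPEG are supported.  Grayscale files yield a matrix;
#' color files yield an H x W x 3 array (an alpha channel, if present, is
#' dropped).  8-bit and 16-bit inputs are both mapped linearly onto
#' 0-255, so 16-bit dynamic range is rescaled at load.
#'
#' @param path file path; format chosen by extension.
#' @return numeric matrix (grayscale) or H x W x 3 array, values in
#'   \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    .stop_lemfuse(sprintf("cannot read image file '%s'", path),
                  "lemfuse_io_error")
  ext <- .ext_of(path)
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    .stop_lemfuse(sprintf("unsupported image format '.%s' (%s)", ext, path),
                  "lemfuse_io_error"))
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3L]
    if (nc == 2L) raw <- raw[, , 1L]           # gray + alpha
    else if (nc >= 3L) raw <- raw[, , 1:3]     # drop alpha if RGBA
  }
  raw * 255
}

#' Quantize an image to 8-bit levels
#'
#' Clips to \[0, 255\] and rounds half-to-even, the convention used for all
#' 8-bit export in this package.
#'
#' @param img numeric matrix or array.
#' @return same shape, integral values in \[0, 255\].
#' @export
clip_to_uint8 <- function(img) round(pmin(pmax(img, 0), 255))

#' Write an image to disk as 8-bit PNG or TIFF
#'
#' The floating-point image is clipped to \[0, 255\] and rounded
#' half-to-even before encoding; the in-memory value the pipeline computed
#' is never clipped.
#'
#' @param img matrix or H x W x 3 array on the 0-255 scale.
#' @param path output path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  v <- clip_to_uint8(img) / 255
  ext <- .ext_of(path)
  switch(ext,
    png  = png::writePNG(v, path),
    tif  = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    .stop_lemfuse(sprintf("unsupported output format '.%s' (%s)", ext, path),
                  "lemfuse_io_error"))
  invisible(path)
}
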
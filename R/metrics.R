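# No-reference fusion quality metrics.  Conventions (pinned here, since
# several variants circulate in the literature): SF uses the RMS of first
# differences over valid pixels; AbG averages sqrt((dx^2 + dy^2)/2) of
# forward differences over the (H-1) x (W-1) interior; STD is the
# population standard deviation; E reuses the 256-bin Shannon entropy on
# values clipped to [0, 255].

#' Spatial frequency
#'
#' \eqn{SF = \sqrt{RF^2 + CF^2}} with
#' \eqn{RF = \sqrt{\mathrm{mean}\,(I_{i,j} - I_{i,j-1})^2}} over all
#' horizontal neighbor pairs and CF the analogue over vertical pairs.
#' Higher values indicate more retained detail.
#'
#' @param img numeric matrix, at least 2 x 2.
#' @return nonnegative scalar.
#' @export
spatial_frequency <- function(img) {
  img <- validate_image(img)
  if (nrow(img) < 2L || ncol(img) < 2L)
    .stop_lemfuse("spatial_frequency needs at least a 2x2 image",
                  "lemfuse_option_error")
  rf2 <- mean((img[, -1L, drop = FALSE] - img[, -ncol(img), drop = FALSE])^2)
  cf2 <- mean((img[-1L, , drop = FALSE] - img[-nrow(img), , drop = FALSE])^2)
  sqrt(rf2 + cf2)
}

#' Average absolute gradient
#'
#' Mean over the forward-difference interior of
#' \eqn{\sqrt{(\Delta_x^2 + \Delta_y^2)/2}}.  A ramp of unit slope scores
#' \eqn{\sqrt{1/2}}.
#'
#' @param img numeric matrix, at least 2 x 2.
#' @return nonnegative scalar.
#' @export
average_gradient <- function(img) {
  img <- validate_image(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 2L || w < 2L)
    .stop_lemfuse("average_gradient needs at least a 2x2 image",
                  "lemfuse_option_error")
  core <- img[-h, -w, drop = FALSE]
  dx <- img[-h, -1L, drop = FALSE] - core   # along columns
  dy <- img[-1L, -w, drop = FALSE] - core   # along rows
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Intensity standard deviation (population)
#'
#' @param img numeric matrix.
#' @return nonnegative scalar.
#' @export
std_metric <- function(img) {
  img <- validate_image(img)
  sqrt(mean((img - mean(img))^2))
}

#' Image entropy
#'
#' 256-bin Shannon entropy (bits) of the intensities clipped to
#' \[0, 255\]; see [shannon_entropy()].
#'
#' @param img numeric matrix.
#' @return nonnegative scalar.
#' @export
entropy_metric <- function(img) {
  img <- validate_image(img)
  shannon_entropy(pmin(pmax(img, 0), 255), 256L)
}

#' Quality report of a fused image
#'
#' Computes the four in-scope no-reference scores.  For a color image the
#' metrics are evaluated on the Y channel.  Keys for the cited
#' reference-based metrics (PS, QCB, VIFF, Qabf, QGS, WSSIM, MSSIM) are
#' reserved in the schema but not computed.
#'
#' @param img matrix, or H x W x 3 RGB array (routed through luminance).
#' @return object of class `metric_report`: named list with `SF`, `AbG`,
#'   `STD`, `E`.
#' @export
#' @examples
#' metric_report(make_mr_like(64, seed = 1)$image)
metric_report <- function(img) {
  if (length(dim(img)) == 3L) img <- rgb_to_ycbcr(img)$Y
  structure(list(SF = spatial_frequency(img),
                 AbG = average_gradient(img),
                 STD = std_metric(img),
                 E = entropy_metric(img)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Fusion quality metrics\n")
  for (k in names(x)) cat(sprintf("  %-4s %.4f\n", k, x[[k]]))
  invisible(x)
}

#' Write a metric report to disk
#'
#' @param report a `metric_report`.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.table(data.frame(metric = names(report),
                                  value = unlist(report, use.names = FALSE)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
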
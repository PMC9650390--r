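#' Fusion configuration
#'
#' Bundles the tunable parameters of the multi-scale decomposition and
#' fusion pipeline.  The defaults reproduce the published setting: five
#' scales with window sizes \eqn{r_i = 2i + 1} (i.e. 3, 5, 7, 9, 11) and
#' structuring-element disk radii \eqn{k_i = r_i}.
#'
#' @param n_scales number of decomposition scales (default 5).
#' @param window_sizes odd guided-filter window side lengths, one per
#'   scale; default `2 * (1:n_scales) + 1`.
#' @param disk_radii flat-disk radii of the structuring elements used for
#'   the local extreme maps; default equal to `window_sizes`.
#' @param gf_epsilon guided-filter regularizer, applied on intensities
#'   normalized to \[0, 1\] (default 0.01).
#' @param entropy_bins number of equal-width histogram bins over \[0, 255\]
#'   used by the entropy weights (default 256).
#' @param enhance_weights logical; `FALSE` forces all fusion weights to 1
#'   (no entropy-based detail enhancement).
#' @return an object of class `fusion_config`.
#' @export
#' @examples
#' fusion_config()                 # published defaults
#' fusion_config(n_scales = 3)     # windows 3, 5, 7
fusion_config <- function(n_scales = 5L,
                          window_sizes = 2L * seq_len(n_scales) + 1L,
                          disk_radii = window_sizes,
                          gf_epsilon = 0.01,
                          entropy_bins = 256L,
                          enhance_weights = TRUE) {
  n_scales <- as.integer(n_scales)
  if (is.na(n_scales) || n_scales < 1L)
    .stop_lemfuse("n_scales must be a positive integer",
                  "lemfuse_option_error")
  window_sizes <- as.integer(window_sizes)
  disk_radii <- as.integer(disk_radii)
  if (length(window_sizes) != n_scales || length(disk_radii) != n_scales)
    .stop_lemfuse("window_sizes and disk_radii must each have n_scales entries",
                  "lemfuse_option_error")
  if (any(window_sizes < 3L) || any(window_sizes %% 2L == 0L))
    .stop_lemfuse("window_sizes must be odd integers >= 3",
                  "lemfuse_option_error")
  if (any(disk_radii < 1L))
    .stop_lemfuse("disk_radii must be positive integers",
                  "lemfuse_option_error")
  if (!is.numeric(gf_epsilon) || gf_epsilon < 0)
    .stop_lemfuse("gf_epsilon must be nonnegative", "lemfuse_option_error")
  entropy_bins <- as.integer(entropy_bins)
  if (is.na(entropy_bins) || entropy_bins < 1L)
    .stop_lemfuse("entropy_bins must be a positive integer",
                  "lemfuse_option_error")
  structure(list(n_scales = n_scales,
                 window_sizes = window_sizes,
                 disk_radii = disk_radii,
                 gf_epsilon = as.numeric(gf_epsilon),
                 entropy_bins = entropy_bins,
                 enhance_weights = isTRUE(enhance_weights)),
            class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("Fusion configuration\n")
  cat("  scales        :", x$n_scales, "\n")
  cat("  window sizes  :", paste(x$window_sizes, collapse = ", "), "\n")
  cat("  disk radii    :", paste(x$disk_radii, collapse = ", "), "\n")
  cat("  gf epsilon    :", format(x$gf_epsilon), "(on 0-1 scale)\n")
  cat("  entropy bins  :", x$entropy_bins, "\n")
  cat("  enhance       :", x$enhance_weights, "\n")
  invisible(x)
}
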
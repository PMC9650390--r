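# He-style guided filter built on integral-image box means with
# border-aware normalization (each window mean divides by the in-bounds
# pixel count, as in the reference implementation).

# Running window sum of length 2*rad+1 along the rows of m, clipped at
# the borders.  O(HW) via cumulative sums.
.run_sum_rows <- function(m, rad) {
  h <- nrow(m)
  cs <- rbind(0, apply(m, 2L, cumsum))
  i <- seq_len(h)
  cs[pmin(i + rad, h) + 1L, , drop = FALSE] -
    cs[pmax(i - rad, 1L), , drop = FALSE]
}

.box_sum <- function(m, rad) t(.run_sum_rows(t(.run_sum_rows(m, rad)), rad))

.box_count <- function(h, w, rad) {
  i <- seq_len(h); j <- seq_len(w)
  outer(pmin(i + rad, h) - pmax(i - rad, 1L) + 1L,
        pmin(j + rad, w) - pmax(j - rad, 1L) + 1L)
}

#' Border-aware box mean
#'
#' Mean over the r x r window centered at each pixel, intersected with
#' the image (the divisor is the in-bounds pixel count, so border means
#' are unbiased).
#'
#' @param img numeric matrix.
#' @param r odd window side length.
#' @return matrix of window means, same size as `img`.
#' @export
#' @examples
#' box_mean(matrix(1:9, 3, 3, byrow = TRUE), 3)[2, 2]  # 5
box_mean <- function(img, r) {
  img <- validate_image(img)
  r <- as.integer(r)
  if (is.na(r) || r < 1L || r %% 2L == 0L)
    .stop_lemfuse("window size r must be an odd positive integer",
                  "lemfuse_option_error")
  rad <- (r - 1L) %/% 2L
  .box_sum(img, rad) / .box_count(nrow(img), ncol(img), rad)
}

#' Guided image filter
#'
#' Smooths `input` under the structure of `guidance` by fitting, in every
#' r x r window k, the local linear model
#' \deqn{a_k = \mathrm{cov}(I, p)_k / (\mathrm{var}(I)_k + \epsilon),
#'       \quad b_k = \bar p_k - a_k \bar I_k,}
#' then averaging the coefficients over all windows covering each pixel:
#' \eqn{q = \bar a \odot I + \bar b}.  Edges present in the guidance are
#' preserved; structure absent from the guidance is smoothed away.
#'
#' Intensities are divided by 255 before the fit, so `epsilon` acts on
#' the conventional \[0, 1\] scale; the output is returned on 0-255.
#' Windows of exactly zero variance with `epsilon = 0` take the limit
#' convention a = 0, b = window mean.
#'
#' @param input numeric matrix to be smoothed (the "p" image).
#' @param guidance numeric matrix steering the filter (the "I" image),
#'   same size as `input`.
#' @param r odd window side length (the window is r x r; the schedule
#'   3, 5, 7, 9, 11 therefore means 3x3 through 11x11 windows).
#' @param epsilon nonnegative regularizer on the 0-1 intensity scale.
#' @return filtered matrix on the 0-255 scale.
#' @export
guided_filter <- function(input, guidance, r, epsilon = 0.01) {
  chk <- validate_pair(input, guidance)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    .stop_lemfuse("epsilon must be a single nonnegative number",
                  "lemfuse_option_error")
  p <- chk$a / 255
  I <- chk$b / 255
  r <- as.integer(r)
  if (is.na(r) || r < 1L || r %% 2L == 0L)
    .stop_lemfuse("window size r must be an odd positive integer",
                  "lemfuse_option_error")
  rad <- (r - 1L) %/% 2L
  cnt <- .box_count(nrow(p), ncol(p), rad)
  mean_I <- .box_sum(I, rad) / cnt
  mean_p <- .box_sum(p, rad) / cnt
  corr_I <- .box_sum(I * I, rad) / cnt
  corr_Ip <- .box_sum(I * p, rad) / cnt
  var_I <- corr_I - mean_I * mean_I
  cov_Ip <- corr_Ip - mean_I * mean_p
  denom <- var_I + epsilon
  a <- cov_Ip / denom
  a[denom == 0] <- 0          # zero-variance window, epsilon = 0
  b <- mean_p - a * mean_I
  q <- (.box_sum(a, rad) / cnt) * I + .box_sum(b, rad) / cnt
  q * 255
}
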
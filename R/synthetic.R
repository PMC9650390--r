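# Seeded phantom-pair generators emulating the structure of co-registered
# multi-modal brain pairs: a CT-like image (dense, sharp skull annulus,
# bland interior), an MR-like image (textured soft tissue with bright and
# dark lesions at known loci), and a PET-like pseudo-color activity map.
# Each generator returns ground-truth masks alongside the image so
# feature-transfer assertions can be made against known pixels.  All
# randomness sits behind one explicit seed and the caller's RNG state is
# left untouched.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.check_size <- function(size) {
  size <- as.integer(size)
  if (is.na(size) || size < 32L)
    .stop_lemfuse("phantom size must be an integer >= 32",
                  "lemfuse_option_error")
  size
}

# Normalized elliptical radius^2 field centered on the image.
.ellipse_r2 <- function(size, ax = 0.40, ay = 0.44) {
  c0 <- (size + 1) / 2
  x <- (seq_len(size) - c0) / (ax * size)
  y <- (seq_len(size) - c0) / (ay * size)
  outer(x^2, y^2, "+")
}

# Mild truncated Gaussian noise: zero-mean, sd `sd`, hard-bounded so the
# generator's intensity guarantees hold deterministically.
.trunc_noise <- function(h, w, sd, bound = 4 * sd) {
  pmin(pmax(matrix(stats::rnorm(h * w, sd = sd), h, w), -bound), bound)
}

.disk_mask <- function(size, ci, cj, radius) {
  outer((seq_len(size) - ci)^2, (seq_len(size) - cj)^2, "+") <= radius^2
}

#' CT-like phantom
#'
#' A bright elliptical "skull" annulus with sharp edges (intensity 235,
#' guaranteed >= 200), an exactly homogeneous dim interior (mean <= 80)
#' and a dark exterior carrying mild seeded noise.  Emulates a CT slice,
#' which mainly captures dense structure: all of its detail energy lives
#' at the skull.  The interior is deliberately feature-free so that
#' ground-truth transfer assertions against a partner image are exact
#' there (soft-tissue texture belongs to the MR phantom).
#'
#' @param size image side, >= 32.
#' @param seed integer seed; output is bit-reproducible.
#' @return list: `image` (size x size matrix, values in \[0, 255\]) and
#'   `masks` (logical matrices `skull`, `interior`).
#' @export
make_ct_like <- function(size, seed = 1L) {
  size <- .check_size(size)
  .with_seed(seed, {
    r2 <- .ellipse_r2(size, ax = 0.42, ay = 0.45)
    skull <- r2 <= 1 & r2 >= 0.84
    interior <- r2 < 0.84
    outside <- !skull & !interior
    img <- matrix(12, size, size)
    img[interior] <- 55
    img[skull] <- 235
    noise <- .trunc_noise(size, size, sd = 2, bound = 8)
    img[outside] <- img[outside] + noise[outside]
    img <- pmin(pmax(img, 0), 255)
    list(image = img, masks = list(skull = skull, interior = interior))
  })
}

#' MR-like phantom
#'
#' Textured soft-tissue interior (smooth blobs plus band-limited noise),
#' a faint rim, and bright and dark lesions at known loci: lesion pixels
#' sit exactly 60 levels above (bright) or below (dark) the local
#' background, so they exceed it by well over 40 levels.
#'
#' @inheritParams make_ct_like
#' @return list: `image`, and `masks` with logical matrices
#'   `bright_lesions`, `dark_lesions`, `interior`.
#' @export
make_mr_like <- function(size, seed = 1L) {
  size <- .check_size(size)
  .with_seed(seed, {
    r2 <- .ellipse_r2(size)
    rim <- r2 <= 1 & r2 >= 0.86
    interior <- r2 < 0.86
    img <- matrix(8, size, size)
    img[interior] <- 110
    img[rim] <- 60
    # smooth tissue blobs
    g <- function(ci, cj, s, amp) {
      amp * exp(-outer((seq_len(size) - ci)^2, (seq_len(size) - cj)^2,
                       "+") / (2 * s^2))
    }
    tex <- g(size * 0.38, size * 0.40, size * 0.12, 30) +
      g(size * 0.62, size * 0.58, size * 0.15, -25) +
      g(size * 0.50, size * 0.30, size * 0.08, 18)
    # band-limited noise: smoothed white noise, rescaled
    bn <- box_mean(matrix(stats::rnorm(size * size), size, size), 5L)
    bn <- bn / stats::sd(bn) * 4
    img <- img + (tex + pmin(pmax(bn, -12), 12)) * interior
    img <- pmin(pmax(img, 0), 255)
    # lesions sit on a ring of normalized radius 0.10 around the image
    # center, well inside the interior at every size
    lesion_r <- max(1, round(size / 42))
    bright <- .disk_mask(size, size * 0.571, size * 0.571, lesion_r) |
      .disk_mask(size, size * 0.429, size * 0.429, lesion_r)
    dark <- .disk_mask(size, size * 0.429, size * 0.571, lesion_r) |
      .disk_mask(size, size * 0.571, size * 0.429, lesion_r)
    bright <- bright & interior
    dark <- dark & interior
    img[bright] <- pmin(img[bright] + 60, 255)
    img[dark] <- pmax(img[dark] - 60, 0)
    list(image = img,
         masks = list(bright_lesions = bright, dark_lesions = dark,
                      interior = interior))
  })
}

#' PET-like pseudo-color phantom
#'
#' Smooth low-resolution "activity" blobs rendered in a hot colormap on a
#' neutral gray background.  On the blob cores the chroma deviates from
#' neutral (128) by more than 20 levels, so the color pathway is
#' exercised nontrivially.
#'
#' @inheritParams make_ct_like
#' @return list: `image` (size x size x 3 RGB array in \[0, 255\]) and
#'   `masks` (logical matrix `blobs` marking activity cores).
#' @export
make_pet_like <- function(size, seed = 1L) {
  size <- .check_size(size)
  .with_seed(seed, {
    g <- function(ci, cj, s) {
      exp(-outer((seq_len(size) - ci)^2, (seq_len(size) - cj)^2,
                 "+") / (2 * s^2))
    }
    a <- pmin(g(size * 0.40, size * 0.45, size * 0.09) +
                g(size * 0.62, size * 0.60, size * 0.07) +
                g(size * 0.48, size * 0.68, size * 0.05), 1)
    a <- a + .trunc_noise(size, size, sd = 0.01, bound = 0.03)
    a <- pmin(pmax(a, 0), 1)
    img <- array(0, c(size, size, 3L))
    img[, , 1L] <- 60 + 170 * a     # activity pushes red
    img[, , 2L] <- 60 + 45 * a
    img[, , 3L] <- 60
    list(image = img, masks = list(blobs = a >= 0.5))
  })
}
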
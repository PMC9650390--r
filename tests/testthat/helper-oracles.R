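# Independent brute-force oracles.  Deliberately naive (explicit loops,
# O(HW * |window|)) and kept free of any code path they are used to check.

# Disk membership by direct enumeration.
oracle_disk <- function(k) {
  fp <- matrix(FALSE, 2 * k + 1, 2 * k + 1)
  for (di in -k:k) for (dj in -k:k)
    fp[di + k + 1, dj + k + 1] <- (di^2 + dj^2) <= k^2
  fp
}

# Sliding extremum over a disk footprint with edge replication.
oracle_morph <- function(img, k, stat) {
  h <- nrow(img); w <- ncol(img)
  fp <- oracle_disk(k)
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- c()
    for (di in -k:k) for (dj in -k:k) {
      if (!fp[di + k + 1, dj + k + 1]) next
      ii <- min(max(i + di, 1), h)
      jj <- min(max(j + dj, 1), w)
      vals <- c(vals, img[ii, jj])
    }
    out[i, j] <- stat(vals)
  }
  out
}

# Border-clipped window mean by double loop.
oracle_box_mean <- function(img, r) {
  rad <- (r - 1) / 2
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- max(1, i - rad):min(h, i + rad)
    rj <- max(1, j - rad):min(w, j + rad)
    out[i, j] <- mean(img[ri, rj])
  }
  out
}

# Literal per-window guided filter: fit (a_k, b_k) window by window on
# 0-1 normalized intensities, then average the coefficients of every
# window covering each pixel.  Works on the 0-255 scale like the real one.
oracle_guided_filter <- function(p, I, r, eps) {
  p <- p / 255; I <- I / 255
  rad <- (r - 1) / 2
  h <- nrow(p); w <- ncol(p)
  a <- matrix(NA_real_, h, w)
  b <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- max(1, i - rad):min(h, i + rad)
    rj <- max(1, j - rad):min(w, j + rad)
    Iw <- I[ri, rj]; pw <- p[ri, rj]
    vI <- mean(Iw^2) - mean(Iw)^2
    cIp <- mean(Iw * pw) - mean(Iw) * mean(pw)
    den <- vI + eps
    a[i, j] <- if (den == 0) 0 else cIp / den
    b[i, j] <- mean(pw) - a[i, j] * mean(Iw)
  }
  q <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- max(1, i - rad):min(h, i + rad)
    rj <- max(1, j - rad):min(w, j + rad)
    q[i, j] <- mean(a[ri, rj]) * I[i, j] + mean(b[ri, rj])
  }
  q * 255
}

rand_img <- function(h, w = h, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(h * w, 0, 255), h, w)
}
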
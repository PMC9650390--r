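test_that("extreme-map filtering equals its step-by-step composition", {
  img <- rand_img(16, seed = 51)
  se <- make_disk(2)
  # compositional oracle: erode -> naive GF -> dilate -> naive GF
  mid <- oracle_guided_filter(img, oracle_morph(img, 2, min), 3, 0.01)
  expected <- oracle_guided_filter(mid, oracle_morph(mid, 2, max), 3, 0.01)
  expect_equal(legf_filter(img, se, 3, 0.01), expected, tolerance = 1e-8)
})

test_that("extreme-map filtering preserves constants", {
  const <- matrix(123, 12, 12)
  expect_equal(legf_filter(const, make_disk(3), 5, 0.01), const,
               tolerance = 1e-9)
})

test_that("extreme-map guidance suppresses an impulse more than self-guidance", {
  img <- matrix(40, 21, 21)
  img[11, 11] <- 255
  f_ext <- legf_filter(img, make_disk(2), 5, 0.01)
  f_self <- legf_filter(img, make_disk(2), 5, 0.01, guidance = "self")
  # residual peak left behind by the filter: smaller is stronger smoothing
  peak_ext <- abs(f_ext[11, 11] - 40)
  peak_self <- abs(f_self[11, 11] - 40)
  expect_lt(peak_ext, peak_self)
})

test_that("bright/dark splitting is an exact sign decomposition", {
  img <- rand_img(10, seed = 52)
  filt <- rand_img(10, seed = 53)
  f <- extract_features(img, filt)
  expect_true(all(f$bright >= 0))
  expect_true(all(f$dark <= 0))
  expect_equal(f$bright + f$dark, img - filt, tolerance = 0)
  expect_true(all(f$bright * f$dark == 0))  # disjoint support

  same <- extract_features(img, img)
  expect_equal(same$bright, matrix(0, 10, 10))
  expect_equal(same$dark, matrix(0, 10, 10))

  d <- matrix(c(5, -3), 1, 2)
  sp <- extract_features(d, matrix(0, 1, 2))
  expect_equal(sp$bright, matrix(c(5, 0), 1, 2))
  expect_equal(sp$dark, matrix(c(0, -3), 1, 2))
})

test_that("decomposition telescopes exactly back to the input", {
  img <- make_mr_like(64, seed = 54)$image
  dec <- decompose_image(img, fusion_config())
  expect_length(dec$bright, 5)
  expect_length(dec$dark, 5)
  expect_lt(max(abs(reconstruct(dec) - img)), 1e-9)
  for (i in 1:5) {
    expect_gte(min(dec$bright[[i]]), 0)
    expect_lte(max(dec$dark[[i]]), 0)
    expect_true(all(dec$bright[[i]] * dec$dark[[i]] == 0))
  }
})

test_that("a constant image decomposes to zero features and itself as base", {
  const <- matrix(77, 40, 40)
  dec <- decompose_image(const, fusion_config())
  for (i in 1:5) {
    expect_equal(dec$bright[[i]], matrix(0, 40, 40), tolerance = 1e-10)
    expect_equal(dec$dark[[i]], matrix(0, 40, 40), tolerance = 1e-10)
  }
  expect_equal(dec$base, const, tolerance = 1e-9)
})

test_that("single-scale decomposition equals filter + split", {
  img <- rand_img(20, seed = 55)
  cfg <- fusion_config(n_scales = 1)
  dec <- decompose_image(img, cfg)
  filt <- legf_filter(img, make_disk(cfg$disk_radii[1]),
                      cfg$window_sizes[1], cfg$gf_epsilon)
  f <- extract_features(img, filt)
  expect_equal(dec$bright[[1]], f$bright)
  expect_equal(dec$dark[[1]], f$dark)
  expect_equal(dec$base, filt)
})

test_that("extreme-map guidance removes more detail energy than any single variant", {
  # phantom with both bright and dark impulses on a textured background
  set.seed(56)
  img <- matrix(100, 24, 24) + matrix(runif(576, -5, 5), 24, 24)
  img[7, 7] <- img[7, 17] <- 250
  img[17, 7] <- img[17, 17] <- 5
  res_energy <- function(g) sum((img - legf_filter(img, make_disk(2), 5,
                                                   0.01, guidance = g))^2)
  e_full <- res_energy("extreme")
  expect_gt(e_full, res_energy("self"))
  # polarity: the max-only variant does not suppress bright features,
  # the min-only variant does not suppress dark ones
  pol_energy <- function(g, part) {
    r <- img - legf_filter(img, make_disk(2), 5, 0.01, guidance = g)
    sum(part(r, 0)^2)
  }
  expect_gte(pol_energy("extreme", pmax), pol_energy("max", pmax))
  expect_gte(pol_energy("extreme", pmin), pol_energy("min", pmin))
})
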
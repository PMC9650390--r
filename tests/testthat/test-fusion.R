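test_that("per-scale fusion takes the stronger feature of each polarity", {
  b1 <- matrix(c(3, 0), 1, 2); b2 <- matrix(c(1, 4), 1, 2)
  d1 <- matrix(c(-3, 0), 1, 2); d2 <- matrix(c(-1, -4), 1, 2)
  s <- fuse_feature_scale(b1, b2, d1, d2)
  expect_equal(s$bright, matrix(c(3, 4), 1, 2))
  expect_equal(s$dark, matrix(c(-3, -4), 1, 2))
  same <- fuse_feature_scale(b1, b1, d1, d1)
  expect_equal(same$bright, b1)
  expect_equal(same$dark, d1)
})

test_that("histogram entropy reproduces closed-form cases", {
  expect_equal(shannon_entropy(matrix(50, 8, 8)), 0)
  expect_equal(shannon_entropy(matrix(c(0, 0, 255, 255), 2, 2)), 1)
  # 4 distinct, equally frequent bin values: -4 * (1/4) log2(1/4) = 2
  img <- matrix(c(0, 64, 128, 192, 0, 64, 128, 192,
                  0, 64, 128, 192, 0, 64, 128, 192), 4, 4)
  expect_equal(shannon_entropy(img), 2)
  # values above 255 fall into the top histogram bin, no error
  expect_equal(shannon_entropy(matrix(c(255, 400), 1, 2)), 0)
  expect_error(shannon_entropy(matrix(-1, 2, 2)),
               class = "lemfuse_option_error")
})

test_that("entropy weights are anchored at 1 with a zero-entropy fallback", {
  set.seed(61)
  maps <- list(matrix(runif(64, 0, 255), 8, 8),
               matrix(runif(64, 0, 255), 8, 8),
               matrix(rep(c(0, 128), each = 32), 8, 8))
  w <- compute_weights(maps, "bright")
  expect_equal(min(w), 1)
  expect_true(all(w >= 1))
  e <- vapply(maps, shannon_entropy, numeric(1))
  expect_equal(w, e / min(e))

  # identical maps: equal entropies, all weights exactly 1
  expect_equal(compute_weights(list(maps[[1]], maps[[1]]), "bright"),
               c(1, 1))

  # dark maps are negated before the entropy
  dmaps <- lapply(maps, function(m) -m)
  expect_equal(compute_weights(dmaps, "dark"), w)

  # blank maps trigger the unit-weight fallback with a warning
  blank <- list(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_warning(wz <- compute_weights(blank, "bright"), "zero minimum")
  expect_equal(wz, c(1, 1))
})

test_that("feature integration is the weighted elementwise sum", {
  set.seed(62)
  maps <- lapply(1:3, function(i) matrix(runif(36, -50, 50), 6, 6))
  w <- c(1, 2.5, 1.3)
  acc <- matrix(0, 6, 6)
  for (i in 1:3) acc <- acc + w[i] * maps[[i]]
  expect_equal(integrate_features(maps, w), acc)
  expect_equal(integrate_features(maps[1], 2.5), 2.5 * maps[[1]])
  expect_equal(integrate_features(maps, c(1, 1, 1)), Reduce(`+`, maps))
  expect_error(integrate_features(maps, c(1, 2)),
               class = "lemfuse_option_error")
})

test_that("base fusion is the elementwise maximum", {
  b1 <- matrix(c(10, 200), 1, 2); b2 <- matrix(c(50, 100), 1, 2)
  expect_equal(fuse_base(b1, b2), matrix(c(50, 200), 1, 2))
  expect_equal(fuse_base(b1, b1), b1)
  f <- fuse_base(rand_img(8, seed = 63), rand_img(8, seed = 64))
  expect_true(all(f >= rand_img(8, seed = 63) - 1e-12))
})

test_that("fusing an image with itself returns it when enhancement is off", {
  cfg <- fusion_config(enhance_weights = FALSE)
  for (seed in 65:67) {
    img <- make_mr_like(48, seed = seed)$image
    expect_lt(max(abs(fuse_pair(img, img, cfg) - img)), 1e-9)
  }
})

test_that("fusion is symmetric in its arguments", {
  a <- make_ct_like(48, seed = 71)$image
  b <- make_mr_like(48, seed = 72)$image
  expect_identical(fuse_pair(a, b), fuse_pair(b, a))
  cfg <- fusion_config(enhance_weights = FALSE)
  expect_identical(fuse_pair(a, b, cfg), fuse_pair(b, a, cfg))
})

test_that("entropy enhancement never shrinks total detail energy", {
  a <- make_ct_like(48, seed = 73)$image
  b <- make_mr_like(48, seed = 74)$image
  on <- fuse_pair(a, b, fusion_config(), details = TRUE)
  off <- fuse_pair(a, b, fusion_config(enhance_weights = FALSE),
                   details = TRUE)
  energy <- function(d) {
    sum(abs(integrate_features(d$fused_bright, d$weights_bright))) +
      sum(abs(integrate_features(d$fused_dark, d$weights_dark)))
  }
  expect_gte(energy(on), energy(off))
  expect_true(all(on$weights_bright >= 1))
  expect_true(all(on$weights_dark >= 1))
})

test_that("a blank partner contributes nothing to bright features or base", {
  img <- make_mr_like(32, seed = 75)$image
  zero <- matrix(0, 32, 32)
  cfg <- fusion_config(enhance_weights = FALSE)
  det <- fuse_pair(zero, img, cfg, details = TRUE)
  d2 <- decompose_image(img, cfg)
  dz <- decompose_image(zero, cfg)
  # the zero image decomposes to all-zero features and a zero base
  expect_equal(Reduce(max, lapply(dz$bright, max)), 0, tolerance = 1e-10)
  expect_equal(det$base, pmax(dz$base, d2$base))
  for (i in 1:5)
    expect_equal(det$fused_bright[[i]], pmax(dz$bright[[i]], d2$bright[[i]]))
})

test_that("complementary phantom features both survive fusion", {
  # at this size the partner's edge halo reaches the lesion ring, so the
  # transfer bounds carry a few-level margin; the exact 1e-6 bound holds
  # at full 256 px scale where the skull sits outside the filter's reach
  ct <- make_ct_like(64, seed = 76)
  mr <- make_mr_like(64, seed = 77)
  cfg <- fusion_config(enhance_weights = FALSE)
  fused <- fuse_pair(ct$image, mr$image, cfg)
  # MR bright lesions survive at their ground-truth pixels and stay
  # salient against their fused neighborhood
  bl <- mr$masks$bright_lesions
  expect_true(all(fused[bl] >= mr$image[bl] - 8))
  ring <- (dilate(bl * 1, make_disk(3)) > 0) & !bl
  expect_gt(mean(fused[bl]) - mean(fused[ring]), 30)
  # CT skull survives as the dominant bright annulus
  sk <- ct$masks$skull
  expect_true(all(fused[sk] >= ct$image[sk] - 70))
  expect_gt(mean(fused[sk]), 200)
})
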
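test_that("gaussian kernel is normalized and matches the pointwise formula", {
  for (v in c(0.3, 1, 2.5)) {
    k <- gaussian_kernel(v)
    expect_lt(abs(sum(k) - 1), 1e-12)
    expect_equal(nrow(k), 2 * ceiling(3 * sqrt(v)) + 1)
    # direct formula oracle
    r <- ceiling(3 * sqrt(v))
    x <- -r:r
    ref <- exp(-outer(x^2, x^2, `+`) / (2 * v))
    expect_equal(k, ref / sum(ref), tolerance = 1e-12)
  }
  # near-delta limit
  k <- gaussian_kernel(0.01)
  expect_gt(k[(nrow(k) + 1) / 2, (ncol(k) + 1) / 2], 0.999)
  expect_error(gaussian_kernel(0), class = "dftune_param_error")
})

test_that("blur preserves constants, reproduces the kernel on an impulse, and fades to identity", {
  const <- matrix(0.37, 20, 20)
  expect_equal(gaussian_blur(const, 1), const, tolerance = 1e-9)

  # impulse response: kernel replica centered at the impulse
  img <- matrix(0, 21, 21)
  img[11, 11] <- 1
  v <- 0.8
  k <- gaussian_kernel(v)
  r <- (nrow(k) - 1) / 2
  out <- gaussian_blur(img, v)
  expect_equal(out[(11 - r):(11 + r), (11 - r):(11 + r)], k, tolerance = 1e-12)

  # v -> 0 limit is the identity
  smooth <- outer(seq(0, 1, length.out = 16), seq(0, 1, length.out = 16),
                  function(a, b) (a + b) / 2)
  expect_equal(gaussian_blur(smooth, 1e-4), smooth, tolerance = 1e-6)
})

test_that("blur preserves interior mean intensity under reflect padding", {
  set.seed(3)
  img <- matrix(runif(64 * 64), 64, 64)
  sm <- gaussian_blur(img, 4)   # heaviest default variance
  r <- ceiling(3 * 2)
  inner <- (r + 1):(64 - r)
  expect_lt(abs(mean(img) - mean(sm)), 1e-3)
  expect_equal(dim(sm), dim(img))
})

test_that("gamma shift follows I' = clip(c * I^gamma)", {
  img <- matrix(runif(100), 10, 10)
  expect_equal(gamma_shift(img, 1, 1), img)
  zero <- matrix(0, 5, 5)
  expect_equal(gamma_shift(zero, 1.2, 0.7), zero)
  quarter <- matrix(0.25, 5, 5)
  expect_equal(gamma_shift(quarter, 1, 2), matrix(0.0625, 5, 5))
  expect_true(all(gamma_shift(img, 1.2, 0.7) <= 1))
  expect_error(gamma_shift(img, 0, 1), class = "dftune_param_error")
  expect_error(gamma_shift(img, 1, -1), class = "dftune_param_error")
})

test_that("small rotation is the coordinate map it claims to be", {
  img <- matrix(runif(32 * 32, 0.2, 0.8), 32, 32)
  expect_identical(rotate_small(img, 0), img)
  expect_error(rotate_small(img, 30), class = "dftune_param_error")

  # inverse symmetry on a smooth image (interior)
  smooth <- outer(seq_len(48), seq_len(48), function(a, b)
    0.5 + 0.3 * sin(a / 8) * cos(b / 9))
  back <- rotate_small(rotate_small(smooth, 12), -12)
  inner <- 9:40
  expect_lt(mean(abs(back[inner, inner] - smooth[inner, inner])), 0.02)

  # impulse moves to the rotation-matrix image of its coordinates
  img2 <- matrix(0, 41, 41)
  img2[11, 29] <- 1
  phi <- 10
  out <- rotate_small(img2, phi)
  hit <- which(out == max(out), arr.ind = TRUE)[1, ]
  th <- phi * pi / 180
  cy <- 21; cx <- 21
  # forward map of the source pixel (inverse of the sampling map)
  pred_r <- cos(th) * (11 - cy) + sin(th) * (29 - cx) + cy
  pred_c <- -sin(th) * (11 - cy) + cos(th) * (29 - cx) + cx
  expect_lt(abs(hit["row"] - pred_r), 1)
  expect_lt(abs(hit["col"] - pred_c), 1)
})

test_that("white noise has the requested moments and is seed-pure", {
  img <- matrix(0.5, 100, 100)
  expect_identical(add_white_noise(img, 0, 1), img)
  a <- add_white_noise(img, 0.05, seed = 11)
  b <- add_white_noise(img, 0.05, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, add_white_noise(img, 0.05, seed = 12)))
  resid <- a - img
  expect_lt(abs(sd(resid) - 0.05) / 0.05, 0.10)
  expect_lt(abs(mean(resid)), 0.005)
  expect_error(add_white_noise(img, -0.1, 1), class = "dftune_param_error")
})

test_that("augment_dataset emits n_target labeled, deduplicated, seeded images", {
  src <- tiny_dataset(n = 10, K = 2, side = 32)
  plan <- augmentation_plan(n_target = 100, seed = 5)
  aug <- augment_dataset(src, plan)
  expect_equal(length(aug$images), 100L)
  expect_true(all(aug$labels %in% src$labels))
  # determinism: byte-identical under the same seed
  aug2 <- augment_dataset(src, plan)
  expect_identical(aug$images, aug2$images)
  expect_identical(aug$labels, aug2$labels)
  # no exact duplicates by 8-bit content
  hashes <- vapply(aug$images, function(im) rlang::hash(as.integer(round(im * 255))),
                   character(1))
  expect_equal(anyDuplicated(hashes), 0L)
  # provenance sidecar covers every emitted image
  prov <- attr(aug, "provenance")
  expect_equal(nrow(prov), 100L)
  expect_true(all(prov$transform %in% c("blur", "gamma", "rotate", "noise")))
  # range and shape closure
  expect_true(all(vapply(aug$images, function(im)
    all(im >= 0 & im <= 1) && all(dim(im) == c(32, 32)), logical(1))))
})

test_that("identity-only registry resamples the source without duplication", {
  src <- tiny_dataset(n = 8, K = 2, side = 32)
  plan <- augmentation_plan(n_target = 8, seed = 2, transforms = "identity")
  out <- augment_dataset(src, plan)
  src_hashes <- sort(vapply(src$images, function(im)
    rlang::hash(as.integer(round(im * 255))), character(1)))
  out_hashes <- sort(vapply(out$images, function(im)
    rlang::hash(as.integer(round(im * 255))), character(1)))
  expect_identical(out_hashes, src_hashes)  # dedup forces a full resample
  expect_error(augmentation_plan(10, 1, transforms = character(0)),
               class = "dftune_input_error")
  expect_error(augment_dataset(src, augmentation_plan(4, 1)),
               class = "dftune_input_error")
})

test_that("label proportions of the emitted set track the source sampling", {
  src <- tiny_dataset(n = 40, K = 2, side = 32)
  p1 <- mean(src$labels == 1)
  aug <- augment_dataset(src, augmentation_plan(n_target = 400, seed = 9))
  phat <- mean(aug$labels == 1)
  expect_lt(abs(phat - p1), 3 * sqrt(p1 * (1 - p1) / 400) + 0.01)
})

test_that("chirality marker is idempotent, rotation-stable, and mirror-sensitive", {
  img <- tiny_dataset(n = 2, K = 2, side = 32)$images[[1]]
  marked <- chirality_marker(img, "right")
  expect_identical(chirality_marker(marked, "right"), marked)
  expect_equal(detect_chirality(marked, "right"), "unflipped")
  mirrored <- marked[, ncol(marked):1]
  expect_equal(detect_chirality(mirrored, "right"), "flipped")
  for (phi in c(-15, 15))
    expect_equal(detect_chirality(rotate_small(marked, phi), "right"), "unflipped")
})

test_that("the default registry never flips chirality", {
  src <- tiny_dataset(n = 6, K = 2, side = 32)
  src$images <- lapply(src$images, chirality_marker)
  aug <- augment_dataset(src, augmentation_plan(n_target = 60, seed = 13))
  verdicts <- vapply(aug$images, detect_chirality, character(1), expected = "right")
  expect_true(all(verdicts == "unflipped"))
})

test_that("oversample_minority equalizes class counts by resampling", {
  idx <- oversample_minority(c(0, 0, 0, 1), seed = 1)
  labs <- c(0, 0, 0, 1)[idx]
  expect_equal(as.vector(table(labs)), c(3, 3))
  # the three original majority indices all survive
  expect_true(all(1:4 %in% idx))
  # already balanced: unchanged
  expect_identical(oversample_minority(c(0, 1, 0, 1), seed = 1), 1:4)
  # single class: unchanged
  expect_identical(oversample_minority(rep(2, 5), seed = 1), 1:5)
  # added indices come from the minority class only
  set.seed(4)
  labels <- sample(0:2, 60, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  idx2 <- oversample_minority(labels, seed = 8)
  expect_true(all(as.vector(table(labels[idx2])) == max(table(labels))))
  extra <- idx2[-seq_along(labels)]
  majority <- as.integer(names(which.max(table(labels))))
  expect_true(all(labels[extra] != majority))
})
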
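test_that("split sizes follow the floor/remainder rule and cover the data", {
  labels <- rep(0:4, each = 200)
  sp <- split_dataset(labels, c(80, 15, 5), seed = 1)
  expect_equal(lengths(sp), c(train = 800L, val = 150L, test = 50L))
  all_idx <- sort(c(sp$train, sp$val, sp$test))
  expect_identical(all_idx, seq_along(labels))   # disjoint + exhaustive
  # stratification: each subset mirrors the uniform class distribution
  expect_equal(as.vector(table(labels[sp$val])), rep(30L, 5))
  expect_equal(as.vector(table(labels[sp$test])), rep(10L, 5))

  # rounding on a small set: 16/3/1
  sp20 <- split_dataset(rep(0:1, 10), c(80, 15, 5), seed = 2)
  expect_equal(lengths(sp20), c(train = 16L, val = 3L, test = 1L))
  expect_identical(sort(unlist(sp20)), 1:20, ignore_attr = TRUE)

  # determinism and seed sensitivity
  expect_identical(split_dataset(labels, seed = 7), split_dataset(labels, seed = 7))
  expect_false(identical(split_dataset(labels, seed = 7)$val,
                         split_dataset(labels, seed = 8)$val))
  expect_error(split_dataset(c(0, 1), c(80, 15, 5)), class = "dftune_input_error")
})

test_that("objective combines data loss and weight penalty", {
  expect_equal(compute_objective(c(1, 3), lambda = 0)$J, 2)
  obj <- compute_objective(c(1, 3), lambda = 0.5, omega = 4)
  expect_equal(obj$J, 4)
  expect_equal(obj$data_loss, 2)
  # omega from parameters: squared norm of W matrices, biases excluded
  params <- list(g1 = list(W = matrix(c(1, 2), 1), b = 100),
                 g2 = list(W = matrix(3, 1), b = -5))
  expect_equal(compute_objective(1, params, lambda = 1)$omega, 1 + 4 + 9)
  expect_equal(compute_objective(c(2, 4), params = list(g = list(W = matrix(0, 2, 2))),
                                 lambda = 9)$J, 3)
  expect_error(compute_objective(1, lambda = -1), class = "dftune_param_error")
})

test_that("zero-epoch training is a no-op", {
  ds <- tiny_dataset(n = 30, K = 3, side = 16)
  m <- small_cnn(3, 16, seed = 1)
  fit <- train_dft(m, ds, ds, train_config(epochs = 0, batch_size = 8, seed = 1),
                   lr_bounds(1e-3, 1e-2))
  expect_equal(nrow(fit$history), 0)
  expect_identical(fit$params, m$params)
})

test_that("training lifts a small CNN above chance on separable classes", {
  ds <- tiny_dataset(n = 150, K = 3, side = 32)
  sp <- split_dataset(ds, c(80, 15, 5), seed = 3)
  m <- small_cnn(3, 32, seed = 5)
  fit <- train_dft(m, dataset_subset(ds, sp$train), dataset_subset(ds, sp$val),
                   train_config(epochs = 3, batch_size = 16, seed = 2,
                                weight_decay = 1e-4),
                   lr_bounds(0.002, 0.02))
  expect_equal(nrow(fit$history), 3)
  expect_gt(fit$history$val_acc[3], 1 / 3)
  expect_true(all(is.finite(fit$history$train_loss)))
  # deterministic: same seeds, same history
  fit2 <- train_dft(small_cnn(3, 32, seed = 5),
                    dataset_subset(ds, sp$train), dataset_subset(ds, sp$val),
                    train_config(epochs = 3, batch_size = 16, seed = 2,
                                 weight_decay = 1e-4),
                    lr_bounds(0.002, 0.02))
  expect_identical(fit$history, fit2$history)
})

test_that("collapsed bounds with zero momentum reproduce an independent SGD loop", {
  ds <- tiny_dataset(n = 48, K = 2, side = 16)
  alpha <- 0.01
  cfg <- train_config(epochs = 2, batch_size = 16, seed = 6, weight_decay = 0)
  m <- small_cnn(2, 16, seed = 8)
  fit <- train_dft(m, ds, ds, cfg,
                   lr_bounds(alpha, alpha * (1 + 1e-12), m_min = 0, m_max = 0))

  # independent reference: plain theta <- theta - alpha * g over the same
  # seeded batch order, coded without the schedule/optimizer machinery
  params <- m$params
  n <- length(ds$images)
  for (epoch in 1:2) {
    ord <- dftune:::with_seed(dftune:::derive_seed(6L, paste0("epoch", epoch)),
                              sample.int(n))
    for (b in split(ord, ceiling(seq_len(n) / 16))) {
      lg <- m$loss_grad(params, list(x = stack_images(ds$images[b]),
                                     y = ds$labels[b]))
      for (g in names(params)) for (a in names(params[[g]]))
        params[[g]][[a]] <- params[[g]][[a]] - alpha * lg$grads[[g]][[a]]
    }
  }
  for (g in names(params))
    expect_equal(fit$final_params[[g]]$W, params[[g]]$W, tolerance = 1e-12)
})

test_that("training aborts with a diagnostic on non-finite loss", {
  ds <- tiny_dataset(n = 20, K = 2, side = 16)
  m <- small_cnn(2, 16, seed = 1)
  m$params$head$W[] <- 1e308   # overflow the softmax
  expect_error(
    train_dft(m, ds, ds, train_config(epochs = 1, batch_size = 10, seed = 1),
              lr_bounds(1e-3, 1e-2)),
    class = "dftune_contract_error")
})

test_that("evaluate reports argmax predictions through the metrics module", {
  ds <- tiny_dataset(n = 30, K = 3, side = 16)
  # constant-class predictor: scores always favor class 0
  const_clf <- structure(list(
    K = 3L, params = list(head = list(W = matrix(0, 3, 1), b = c(1, 0, 0))),
    predict = function(params, x) matrix(c(1, 0, 0), 3, dim(x)[3])),
    class = "dft_model")
  res <- evaluate(const_clf, ds)
  expect_equal(sum(res$confusion[, 1]), 30)   # one nonzero column
  expect_equal(sum(res$confusion[, -1]), 0)
  expect_equal(res$summary$accuracy, mean(ds$labels == 0))
  # metrics equal the brute-force recomputation
  expect_equal(unname(res$confusion),
               unname(confusion_matrix(ds$labels, res$predictions, 3)))
  expect_error(dataset_subset(ds, integer(0)), class = "dftune_input_error")
})

test_that("fp16 rounding behaves like IEEE binary16 storage", {
  expect_identical(fp16_round(0), 0)
  expect_equal(fp16_round(1), 1)
  expect_equal(fp16_round(65504), 65504)
  expect_equal(fp16_round(70000), Inf)
  expect_equal(fp16_round(-70000), -Inf)
  expect_equal(fp16_round(2^-25), 0)          # below half the smallest subnormal
  expect_equal(fp16_round(2^-24), 2^-24)      # smallest subnormal survives
  # relative quantization error bounded by 2^-11 in the normal range
  set.seed(2)
  x <- 10^runif(1000, -4, 4)
  expect_lt(max(abs(fp16_round(x) - x) / x), 2^-11)
  # idempotent
  expect_identical(fp16_round(fp16_round(x)), fp16_round(x))
})

test_that("mixed-precision step honors the loss-scaling contract", {
  ds <- tiny_dataset(n = 16, K = 2, side = 16)
  m <- small_cnn(2, 16, seed = 4)
  batch <- list(x = stack_images(ds$images), y = ds$labels)
  # identity configuration: bit-path equal to the plain step
  plain <- m$loss_grad(m$params, batch)
  st1 <- mixed_precision_step(m, m$params, batch, loss_scale = 1,
                              emulate_fp16 = FALSE)
  expect_identical(st1$grads, plain$grads)
  expect_false(st1$skipped)
  # with scale 1024 + fp16 emulation, unscaled gradients match the
  # full-precision gradients at the same (rounded) weights to 1e-3 relative
  st <- mixed_precision_step(m, m$params, batch, loss_scale = 1024)
  ref <- m$loss_grad(dftune:::round_params_fp16(m$params), batch)
  for (g in names(ref$grads)) {
    rw <- ref$grads[[g]]$W
    keep <- abs(rw) > 1e-8
    expect_lt(max(abs(st$grads[[g]]$W[keep] - rw[keep]) / abs(rw[keep])), 1e-3)
  }
  # overflow guard: huge gradients skip the step and back off the scale
  boom <- exploding_model(rep(1, 10), magnitude = 1e6)
  stb <- mixed_precision_step(boom, boom$params, list(), loss_scale = 1024)
  expect_true(stb$skipped)
  expect_null(stb$grads)
  expect_equal(stb$next_scale, 512)
  expect_error(mixed_precision_step(m, m$params, batch, loss_scale = 0),
               class = "dftune_param_error")
})

test_that("a skipped overflow step leaves training parameters unchanged", {
  ds <- tiny_dataset(n = 8, K = 2, side = 16)
  boom <- exploding_model(rep(1, 4), magnitude = 1e9)
  boom$predict <- function(params, x) matrix(0, 2, dim(x)[3])
  boom$K <- 2L
  cfg <- train_config(epochs = 1, batch_size = 8, seed = 1,
                      mixed_precision = TRUE, loss_scale = 2^40,
                      weight_decay = 0)
  fit <- train_dft(structure(boom, class = "dft_model"), ds, ds, cfg,
                   lr_bounds(1e-3, 1e-2))
  expect_identical(fit$final_params, boom$params)
})
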
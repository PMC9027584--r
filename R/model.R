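# Compact trainable models. A model is a list with:
#   $params    named list of layer groups (registration order = depth order;
#              the classifier head is always the last group); each group is a
#              named list of numeric arrays (W, b)
#   $loss_grad function(params, batch) -> list(loss, grads) where `batch` is
#              list(x = (H, W, N) array, y = 0-based labels); `grads` mirrors
#              the structure of `params` (mean cross-entropy, no regularizer)
#   $predict   function(params, x) -> K x N score matrix
# The built-in backbone is a 3-conv-block CNN sized for desk-scale CPU
# training; larger pretrained backbones can be plugged in by supplying the
# same interface.

#' Checksum over all model parameters
#'
#' Used to assert that operations which promise not to touch weights (the
#' range-test sweep, head surgery on non-head groups) keep that promise.
#'
#' @param params a model's parameter list (or a model; its `$params` is used).
#' @return a single numeric hash-like value.
#' @export
param_checksum <- function(params) {
  if (!is.null(params$params)) params <- params$params
  sum(vapply(unlist(params, recursive = FALSE),
             function(a) sum(a * seq_along(a)), numeric(1)))
}

he_init <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

#' Build the small built-in convolutional network
#'
#' Three 3x3 convolution blocks (same-padding, ReLU, 2x2 max-pool) followed
#' by a linear classifier head. Four parameter groups in depth order:
#' `conv1`, `conv2`, `conv3`, `head` — the granularity at which
#' discriminative fine-tuning assigns learning rates. `side` must be a
#' multiple of 8 (three pooling halvings).
#'
#' @param K number of output classes.
#' @param side input image side in pixels.
#' @param channels integer vector of the three conv widths.
#' @param seed seed for He-normal weight initialization.
#' @return a model object of class `dft_model`.
#' @examples
#' m <- small_cnn(K = 3, side = 32, seed = 1)
#' names(m$params)
#' @export
small_cnn <- function(K, side = 64, channels = c(8, 16, 16), seed = 1) {
  check_scalar_num(K, "K"); check_scalar_num(side, "side")
  if (side %% 8 != 0) abort_input("`side` must be a multiple of 8")
  if (length(channels) != 3) abort_input("`channels` must have length 3")
  cin <- c(1L, channels[1], channels[2])
  feat <- (side %/% 8L)^2 * channels[3]
  params <- with_seed(seed, {
    p <- list()
    for (i in 1:3) p[[paste0("conv", i)]] <-
      list(W = he_init(9L * cin[i], channels[i], 9L * cin[i]),
           b = numeric(channels[i]))
    p$head <- list(W = he_init(K, feat, feat), b = numeric(K))
    p
  })
  model <- list(kind = "small_cnn", K = as.integer(K), side = as.integer(side),
                channels = as.integer(channels), params = params)
  model$loss_grad <- function(params, batch) cnn_loss_grad(model, params, batch)
  model$predict <- function(params, x) cnn_forward(model, params, x)$scores
  structure(model, class = "dft_model")
}

#' @export
print.dft_model <- function(x, ...) {
  np <- sum(vapply(unlist(x$params, recursive = FALSE), length, numeric(1)))
  cat(sprintf("<dft_model:%s> %d classes, %d layer groups, %d parameters\n",
              x$kind, x$K, length(x$params), np))
  invisible(x)
}

# ---- conv plumbing (im2col + GEMM), activations laid out (H, W, N, C) ----
# The gather/scatter index matrices depend only on the activation shape, so
# they are memoized per shape: one big vectorized `[` replaces nested loops.

.conv_cache <- new.env(parent = emptyenv())

conv_indices <- function(h, w, n) {
  key <- paste(h, w, n, sep = "x")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L; wp <- w + 2L
  # linear index of (i+1, j+1, nn) in one zero-padded (hp, wp, n) channel
  # plane, for output positions i=1:h (fastest), j=1:w, nn=1:n
  base <- rep(2:(h + 1L), times = w * n) +
    hp * rep(rep(1:w, each = h), times = n) +
    (hp * wp) * rep(0:(n - 1L), each = h * w)
  idx <- vector("list", 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    idx[[k]] <- base + di + hp * dj
  }
  .conv_cache[[key]] <- idx
  idx
}

im2col <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[3]; cch <- d[4]
  xp <- array(0, c(h + 2L, w + 2L, n, cch))
  xp[2:(h + 1L), 2:(w + 1L), , ] <- x
  dim(xp) <- c((h + 2L) * (w + 2L) * n, cch)
  idx <- conv_indices(h, w, n)
  cols <- matrix(0, h * w * n, 9L * cch)
  csel <- 9L * (seq_len(cch) - 1L)
  for (k in 1:9) cols[, k + csel] <- xp[idx[[k]], , drop = FALSE]
  cols
}

col2im <- function(dcols, h, w, n, cch) {
  dxp <- matrix(0, (h + 2L) * (w + 2L) * n, cch)
  idx <- conv_indices(h, w, n)
  csel <- 9L * (seq_len(cch) - 1L)
  for (k in 1:9) {
    ik <- idx[[k]]  # indices within one offset are distinct
    dxp[ik, ] <- dxp[ik, , drop = FALSE] + dcols[, k + csel, drop = FALSE]
  }
  dim(dxp) <- c(h + 2L, w + 2L, n, cch)
  dxp[2:(h + 1L), 2:(w + 1L), , , drop = FALSE]
}

conv_fwd <- function(x, Wm, b, keep_cache = TRUE) {
  d <- dim(x)
  cols <- im2col(x)
  z <- cols %*% Wm
  z <- z + rep(b, each = nrow(z))
  mask <- z > 0
  a <- z * mask
  list(out = array(a, c(d[1], d[2], d[3], ncol(Wm))),
       cols = if (keep_cache) cols, mask = if (keep_cache) mask)
}

conv_bwd <- function(dy, cache, d_in, need_dx = TRUE) {
  dym <- matrix(dy, ncol = dim(dy)[4])
  dz <- dym * cache$mask
  list(dW = crossprod(cache$cols, dz), db = colSums(dz),
       dx = if (need_dx)
         col2im(tcrossprod(dz, cache$Wm), d_in[1], d_in[2], d_in[3], d_in[4]))
}

pool_fwd <- function(x, keep_cache = TRUE) {
  d <- dim(x); h <- d[1]; w <- d[2]
  xm <- array(x, c(h, w, d[3] * d[4]))
  o1 <- seq(1L, h, 2L); o2 <- seq(2L, h, 2L)
  e1 <- seq(1L, w, 2L); e2 <- seq(2L, w, 2L)
  c11 <- xm[o1, e1, , drop = FALSE]; c21 <- xm[o2, e1, , drop = FALSE]
  c12 <- xm[o1, e2, , drop = FALSE]; c22 <- xm[o2, e2, , drop = FALSE]
  mx <- pmax(c11, c21, c12, c22)
  masks <- NULL
  if (keep_cache) {
    # deterministic tie-break: gradient routed to the first maximal position
    w11 <- c11 == mx
    w21 <- (c21 == mx) & !w11
    w12 <- (c12 == mx) & !w11 & !w21
    w22 <- !w11 & !w21 & !w12
    masks <- list(w11, w21, w12, w22)
  }
  list(out = array(mx, c(h %/% 2L, w %/% 2L, d[3], d[4])),
       masks = masks, d_in = d)
}

pool_bwd <- function(dy, cache) {
  d <- cache$d_in; h <- d[1]; w <- d[2]; m <- d[3] * d[4]
  dym <- array(dy, c(h %/% 2L, w %/% 2L, m))
  dxm <- array(0, c(h, w, m))
  o1 <- seq(1L, h, 2L); o2 <- seq(2L, h, 2L)
  e1 <- seq(1L, w, 2L); e2 <- seq(2L, w, 2L)
  dxm[o1, e1, ] <- dym * cache$masks[[1]]
  dxm[o2, e1, ] <- dym * cache$masks[[2]]
  dxm[o1, e2, ] <- dym * cache$masks[[3]]
  dxm[o2, e2, ] <- dym * cache$masks[[4]]
  array(dxm, d)
}

cnn_forward <- function(model, params, x, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  caches <- list()
  a <- x
  for (i in 1:3) {
    nm <- paste0("conv", i)
    cf <- conv_fwd(a, params[[nm]]$W, params[[nm]]$b, keep_cache = keep_cache)
    cf$Wm <- params[[nm]]$W
    cf$d_in <- dim(a)
    pf <- pool_fwd(cf$out, keep_cache = keep_cache)
    if (keep_cache) caches[[nm]] <- list(conv = cf, pool = pf)
    a <- pf$out
  }
  d <- dim(a)
  feat <- aperm(a, c(1, 2, 4, 3))
  dim(feat) <- c(d[1] * d[2] * d[4], d[3])
  scores <- sweep(params$head$W %*% feat, 1L, params$head$b, `+`)
  list(scores = scores, feat = feat, feat_dim = d, caches = caches)
}

cnn_loss_grad <- function(model, params, batch) {
  x <- batch$x; y <- as.integer(batch$y)
  fw <- cnn_forward(model, params, x, keep_cache = TRUE)
  z <- fw$scores
  n <- ncol(z)
  z <- sweep(z, 2L, apply(z, 2L, max), `-`)
  ez <- exp(z)
  p <- sweep(ez, 2L, colSums(ez), `/`)
  iy <- cbind(y + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[iy], 1e-12)))
  dz <- p
  dz[iy] <- dz[iy] - 1
  dz <- dz / n
  grads <- list()
  grads$head <- list(W = dz %*% t(fw$feat), b = rowSums(dz))
  dfeat <- t(params$head$W) %*% dz
  d <- fw$feat_dim
  dim(dfeat) <- c(d[1], d[2], d[4], d[3])
  da <- aperm(dfeat, c(1, 2, 4, 3))
  for (i in 3:1) {
    nm <- paste0("conv", i)
    cache <- fw$caches[[nm]]
    da <- pool_bwd(da, cache$pool)
    cb <- conv_bwd(da, cache$conv, cache$conv$d_in, need_dx = i > 1L)
    grads[[nm]] <- list(W = cb$dW, b = cb$db)
    da <- cb$dx
  }
  list(loss = loss, grads = grads[names(params)], preds = argmax0(fw$scores))
}

#' Replace the classifier head of a model
#'
#' Transfer-learning head surgery: swaps the final fully connected layer for
#' a freshly initialized `K`-output layer, leaving every other layer group's
#' weights untouched.
#'
#' @param model a `dft_model` whose last parameter group is a linear head
#'   (`W` matrix + `b` vector).
#' @param K number of classes for the new head.
#' @param seed seed for the new head's initialization.
#' @return the model with its new head (and updated `$K`).
#' @export
replace_head <- function(model, K, seed = 1) {
  if (!inherits(model, "dft_model")) abort_contract("not a dft_model")
  groups <- names(model$params)
  head_nm <- groups[length(groups)]
  head <- model$params[[head_nm]]
  if (!is.list(head) || !is.matrix(head$W) || length(head$b) != nrow(head$W))
    abort_contract("model has no recognizable linear classifier head")
  feat <- ncol(head$W)
  model$params[[head_nm]] <- with_seed(seed, list(W = he_init(K, feat, feat),
                                                  b = numeric(K)))
  model$K <- as.integer(K)
  model
}
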
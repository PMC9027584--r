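# Mammogram-style augmentation: Gaussian blur, gamma intensity shift, small
# rotation, mild white noise; a seeded random pipeline that draws one
# transform per emitted image; and random minority oversampling. Horizontal
# mirroring is deliberately absent from the registry — breast anatomy
# chirality must be preserved.

#' Normalized 2-D Gaussian kernel
#'
#' Square kernel of radius `ceiling(3 * sqrt(v))` with entries proportional
#' to `exp(-(x^2 + y^2) / (2 v))`, normalized to sum exactly 1.
#'
#' @param v variance of the Gaussian, in squared pixels, > 0.
#' @return an odd-sided numeric matrix summing to 1.
#' @export
gaussian_kernel <- function(v) {
  check_scalar_num(v, "v")
  if (v <= 0) abort_param("blur variance `v` must be > 0")
  r <- ceiling(3 * sqrt(v))
  x <- -r:r
  k <- exp(-outer(x^2, x^2, `+`) / (2 * v))
  k / sum(k)
}

# Reflect-pad a matrix by `r` pixels on every side (mirror including edge).
reflect_pad <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  if (r >= h || r >= w)
    abort_param("kernel radius exceeds image size; reduce blur variance")
  ri <- c(r:1, 1:h, h:(h - r + 1))
  ci <- c(r:1, 1:w, w:(w - r + 1))
  m[ri, ci, drop = FALSE]
}

#' Gaussian blur
#'
#' 2-D convolution of the image with [gaussian_kernel()] under
#' reflect-padding, emulating the acquisition blur seen in mammograms.
#' Because the kernel is normalized, constant regions are invariant and the
#' interior mean intensity is preserved.
#'
#' @param img image matrix in \[0, 1\].
#' @param v blur variance in squared pixels, > 0.
#' @return blurred image, same dimensions, intensities in \[0, 1\].
#' @export
gaussian_blur <- function(img, v) {
  img <- as_image(img)
  k <- gaussian_kernel(v)
  r <- (nrow(k) - 1L) %/% 2L
  p <- reflect_pad(img, r)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(k)))
    for (j in seq_len(ncol(k)))
      out <- out + k[i, j] * p[(i - 1L) + 1:h, (j - 1L) + 1:w]
  clip01(out)
}

#' Gamma intensity shift
#'
#' Per-pixel power-law transform `I' = clip(c * I^gamma, 0, 1)`, emulating
#' under- or over-exposure.
#'
#' @param img image matrix in \[0, 1\].
#' @param c_ positive scale constant.
#' @param gamma positive exponent; `< 1` brightens, `> 1` darkens.
#' @return transformed image.
#' @export
gamma_shift <- function(img, c_, gamma) {
  img <- as_image(img)
  check_scalar_num(c_, "c_"); check_scalar_num(gamma, "gamma")
  if (c_ <= 0 || gamma <= 0) abort_param("`c_` and `gamma` must be > 0")
  clip01(c_ * img^gamma)
}

#' Small rotation about the image center
#'
#' Rotates by `phi` degrees using the inverse coordinate map with bilinear
#' interpolation; pixels sampled from outside the frame are filled with 0
#' (background). Only small angles (|phi| <= 25 degrees) are admitted: the
#' transform models slight positioning variation, not arbitrary reorientation.
#'
#' @param img image matrix in \[0, 1\].
#' @param phi rotation angle in degrees, |phi| <= 25; positive is
#'   counter-clockwise in standard (x right, y up) orientation.
#' @return rotated image, same dimensions.
#' @export
rotate_small <- function(img, phi) {
  img <- as_image(img)
  check_scalar_num(phi, "phi")
  if (abs(phi) > 25) abort_param("|phi| must be <= 25 degrees (small-angle regime)")
  if (phi == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  th <- phi * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # output grid, centered coordinates
  rr <- matrix(seq_len(h) - cy, h, w)
  cc <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  # inverse map: rotate output coords by -phi to find source location
  sr <- cos(th) * rr - sin(th) * cc + cy
  sc <- sin(th) * rr + cos(th) * cc + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  sample_at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    val <- numeric(length(ri))
    val[ok] <- img[cbind(ri[ok], ci[ok])]
    val
  }
  v00 <- sample_at(r0, c0);     v10 <- sample_at(r0 + 1, c0)
  v01 <- sample_at(r0, c0 + 1); v11 <- sample_at(r0 + 1, c0 + 1)
  out <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
  clip01(matrix(out, h, w))
}

#' Additive white Gaussian noise
#'
#' Adds zero-mean Gaussian noise of standard deviation `noise_sigma` and
#' clips to \[0, 1\]. Seeded and reproducible.
#'
#' @param img image matrix in \[0, 1\].
#' @param noise_sigma noise standard deviation in intensity units, >= 0.
#' @param seed integer seed.
#' @return noisy image.
#' @export
add_white_noise <- function(img, noise_sigma, seed) {
  img <- as_image(img)
  check_scalar_num(noise_sigma, "noise_sigma")
  if (noise_sigma < 0) abort_param("`noise_sigma` must be >= 0")
  if (noise_sigma == 0) return(img)
  n <- with_seed(seed, stats::rnorm(length(img), 0, noise_sigma))
  clip01(img + matrix(n, nrow(img), ncol(img)))
}

default_param_ranges <- function() {
  list(blur   = list(v = c(0.25, 4)),
       gamma  = list(c_ = c(0.8, 1.2), gamma = c(0.7, 1.5)),
       rotate = list(angle = c(2, 15)),   # magnitude; sign drawn at random
       noise  = list(sigma = c(0.005, 0.02)),
       identity = list())
}

#' Augmentation plan
#'
#' The transform registry, per-transform parameter sampling ranges, target
#' dataset size, and RNG seed driving [augment_dataset()]. Defaults are
#' visually mild distortions: blur variance 0.25--4 px^2, gamma scale
#' 0.8--1.2 with exponent 0.7--1.5, rotation magnitude 2--15 degrees of
#' either sign, noise sigma 0.005--0.02. There is no mirroring transform,
#' by design.
#'
#' @param n_target desired number of emitted images (>= source size).
#' @param seed integer RNG seed.
#' @param transforms character subset of
#'   `c("blur", "gamma", "rotate", "noise", "identity")`.
#' @param param_ranges named list overriding entries of the default ranges.
#' @param chain if `TRUE`, apply every registered transform in sequence to
#'   each emitted image instead of drawing one at random (off by default).
#' @return an object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(n_target, seed,
                              transforms = c("blur", "gamma", "rotate", "noise"),
                              param_ranges = list(), chain = FALSE) {
  check_scalar_num(n_target, "n_target"); check_scalar_num(seed, "seed")
  defaults <- default_param_ranges()
  bad <- setdiff(transforms, names(defaults))
  if (length(transforms) == 0L) abort_input("transform registry must be non-empty")
  if (length(bad)) abort_input(paste("unknown transforms:", paste(bad, collapse = ", ")))
  ranges <- defaults
  for (nm in names(param_ranges)) ranges[[nm]] <- utils::modifyList(ranges[[nm]], param_ranges[[nm]])
  structure(list(transforms = transforms, param_ranges = ranges[transforms],
                 n_target = as.integer(n_target), seed = as.integer(seed),
                 chain = isTRUE(chain)), class = "augmentation_plan")
}

draw_params <- function(name, ranges) {
  rg <- ranges[[name]]
  switch(name,
    blur = list(v = stats::runif(1, rg$v[1], rg$v[2])),
    gamma = list(c_ = stats::runif(1, rg$c_[1], rg$c_[2]),
                 gamma = stats::runif(1, rg$gamma[1], rg$gamma[2])),
    rotate = list(phi = sample(c(-1, 1), 1) * stats::runif(1, rg$angle[1], rg$angle[2])),
    noise = list(sigma = stats::runif(1, rg$sigma[1], rg$sigma[2]),
                 seed = sample.int(2147483646L, 1)),
    identity = list())
}

apply_transform <- function(img, name, params) {
  switch(name,
    blur = gaussian_blur(img, params$v),
    gamma = gamma_shift(img, params$c_, params$gamma),
    rotate = rotate_small(img, params$phi),
    noise = add_white_noise(img, params$sigma, params$seed),
    identity = img)
}

image_hash <- function(img) rlang::hash(as.integer(round(img * 255)))

#' Augment a labeled dataset with a seeded random pipeline
#'
#' Repeats \{draw a source image with replacement, draw a transform from the
#' registry, draw its parameters, apply, emit\} until `n_target` images have
#' been emitted. Labels are inherited from the source image. Exact duplicates
#' (identical 8-bit content, detected by hash) are rejected and redrawn, a
#' deterministic stand-in for manual post-hoc curation. The registry contains
#' no mirroring transform, so breast-anatomy chirality is preserved. The
#' whole procedure is a pure function of `(source, plan)`.
#'
#' @param source an [image_dataset()].
#' @param plan an [augmentation_plan()].
#' @return an [image_dataset()] of `plan$n_target` images with a
#'   `provenance` attribute: a `data.frame` recording, for every emitted
#'   image, the source index, the transform applied, and its parameters
#'   (JSON-encoded).
#' @export
augment_dataset <- function(source, plan) {
  stopifnot(inherits(source, "image_dataset"), inherits(plan, "augmentation_plan"))
  n_src <- length(source$images)
  if (n_src == 0L) abort_input("source dataset is empty")
  if (plan$n_target < n_src)
    abort_input("`n_target` must be at least the source dataset size")
  with_seed(plan$seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out_imgs <- vector("list", plan$n_target)
    out_lab <- integer(plan$n_target)
    prov <- vector("list", plan$n_target)
    emitted <- 0L
    attempts <- 0L
    max_attempts <- 50L * plan$n_target
    while (emitted < plan$n_target) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        abort_input("could not emit enough distinct images; enlarge parameter ranges")
      src <- sample.int(n_src, 1L)
      names_applied <- if (plan$chain) plan$transforms
        else plan$transforms[sample.int(length(plan$transforms), 1L)]
      img <- source$images[[src]]
      par_log <- list()
      for (nm in names_applied) {
        p <- draw_params(nm, plan$param_ranges)
        img <- apply_transform(img, nm, p)
        par_log[[nm]] <- p
      }
      h <- image_hash(img)
      if (!is.null(seen[[h]])) next  # exact duplicate: redraw
      seen[[h]] <- TRUE
      emitted <- emitted + 1L
      out_imgs[[emitted]] <- img
      out_lab[emitted] <- source$labels[src]
      prov[[emitted]] <- data.frame(
        source = src, transform = paste(names_applied, collapse = "+"),
        params = as.character(jsonlite::toJSON(par_log, auto_unbox = TRUE, digits = 8)))
    }
    ds <- image_dataset(out_imgs, out_lab,
                        sprintf("aug_%05d.pgm", seq_len(plan$n_target)))
    attr(ds, "provenance") <- do.call(rbind, prov)
    ds
  })
}

#' Random minority oversampling
#'
#' Returns an index multiset over `labels` in which every class count equals
#' the majority-class count; the added indices are drawn uniformly with
#' replacement from the class's original indices. Already balanced input is
#' returned unchanged. Apply to the training partition only, after splitting,
#' so duplicated minority samples never leak into validation or test.
#'
#' @param labels integer class ids.
#' @param seed integer seed.
#' @return integer indices into `labels` (original order first, then the
#'   duplicated minority draws).
#' @export
oversample_minority <- function(labels, seed) {
  if (length(labels) == 0L) abort_input("`labels` must be non-empty")
  labels <- as.integer(labels)
  counts <- table(labels)
  target <- max(counts)
  idx <- seq_along(labels)
  extra <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      need <- target - counts[[cl]]
      if (need == 0L) return(integer(0))
      pool <- which(labels == as.integer(cl))
      pool[sample.int(length(pool), need, replace = TRUE)]
    }), use.names = FALSE)
  })
  c(idx, extra)
}
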
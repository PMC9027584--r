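# Seeded synthetic grayscale images with class-dependent structure, standing
# in for a small mammogram collection so the whole pipeline is testable
# offline. Each class is a distinct combination of Gaussian blobs (count and
# size vary with class) and an oriented sinusoidal texture (orientation and
# frequency vary with class) on a smooth background; a signal-strength knob
# fades the class pattern in or out against background noise. No claim of
# radiological realism is made.

#' Specification of a synthetic dataset
#'
#' @param K number of classes, 2--7.
#' @param n total number of images, >= K.
#' @param side image side in pixels, >= 16 (default 64).
#' @param imbalance per-class proportions summing to 1; `NULL` means uniform.
#' @param signal_strength separability knob in \[0, 1\]: 0 makes all
#'   class-conditional distributions identical (pure background + noise),
#'   1 gives noise-free class patterns.
#' @param seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(K, n, side = 64, imbalance = NULL,
                           signal_strength = 0.9, seed = 1) {
  check_scalar_num(K, "K"); check_scalar_num(n, "n"); check_scalar_num(side, "side")
  check_scalar_num(signal_strength, "signal_strength"); check_scalar_num(seed, "seed")
  if (K < 2 || K > 7) abort_input("`K` must be between 2 and 7")
  if (n < K) abort_input("`n` must be at least `K`")
  if (side < 16) abort_input("`side` must be >= 16")
  if (signal_strength < 0 || signal_strength > 1)
    abort_input("`signal_strength` must lie in [0, 1]")
  if (is.null(imbalance)) imbalance <- rep(1 / K, K)
  if (length(imbalance) != K || any(imbalance < 0) ||
      abs(sum(imbalance) - 1) > 1e-8)
    abort_input("`imbalance` must be K non-negative proportions summing to 1")
  structure(list(K = as.integer(K), n = as.integer(n), side = as.integer(side),
                 imbalance = imbalance, signal_strength = signal_strength,
                 seed = as.integer(seed)), class = "synthetic_spec")
}

# Largest-remainder (Hamilton) apportionment of n into proportions p.
largest_remainder <- function(n, p) {
  q <- n * p
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    # ties broken toward the lower class index for determinism
    ord <- order(-(q - base), seq_along(p))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

class_pattern <- function(k, K, side, jitter) {
  # blobs: class k gets k+1 Gaussian bumps of class-dependent radius
  g <- seq_len(side)
  rr <- matrix(g, side, side); cc <- matrix(g, side, side, byrow = TRUE)
  n_blobs <- k + 1L
  radius <- side / (5 + 1.5 * k)
  pat <- matrix(0, side, side)
  for (b in seq_len(n_blobs)) {
    ang <- 2 * pi * (b - 1) / n_blobs + jitter[b]
    cy <- side / 2 + side / 4 * sin(ang)
    cx <- side / 2 + side / 4 * cos(ang)
    pat <- pat + exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * radius^2))
  }
  pat <- pat / max(pat)
  # oriented sinusoid: orientation and spatial frequency encode the class
  theta <- pi * k / K
  freq <- 2 * pi * (2 + k) / side
  tex <- 0.5 + 0.5 * sin(freq * (cos(theta) * rr + sin(theta) * cc))
  0.6 * pat + 0.4 * tex
}

#' Generate a seeded synthetic labeled image set
#'
#' Class counts follow the requested proportions exactly under
#' largest-remainder rounding. Each image is a smooth random background plus
#' `signal_strength` times its class pattern plus background Gaussian noise
#' scaled by `(1 - signal_strength)`; with `signal_strength = 0` every class
#' is distributionally identical and any classifier sits at chance.
#'
#' @param spec a [synthetic_spec()].
#' @return an [image_dataset()] with labels `0:(K-1)`.
#' @examples
#' ds <- generate_synthetic(synthetic_spec(K = 3, n = 30, side = 32, seed = 1))
#' table(ds$labels)
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  counts <- largest_remainder(spec$n, spec$imbalance)
  labels <- rep(0:(spec$K - 1L), counts)
  side <- spec$side
  with_seed(spec$seed, {
    imgs <- lapply(seq_len(spec$n), function(i) {
      k <- labels[i]
      # smooth background: low-frequency cosine sheet with random phase
      ph <- stats::runif(2, 0, 2 * pi)
      g <- seq_len(side) / side
      bg <- 0.35 + 0.1 * outer(cos(2 * pi * g + ph[1]), cos(2 * pi * g + ph[2]))
      jitter <- stats::runif(8, -0.2, 0.2)
      pat <- class_pattern(k, spec$K, side, jitter)
      noise <- matrix(stats::rnorm(side * side, 0, 0.15), side, side)
      img <- bg + spec$signal_strength * 0.5 * pat +
        (1 - spec$signal_strength) * noise
      clip01(img)
    })
    image_dataset(imgs, labels, sprintf("syn_%05d.pgm", seq_len(spec$n)))
  })
}

#' Embed a chirality marker
#'
#' Overwrites a narrow strip on each vertical edge of the image with fixed
#' intensities (dark on one side, bright on the other), making horizontally
#' mirrored copies detectable. The overwrite is idempotent. Used to verify
#' that the augmentation registry never mirrors an image.
#'
#' @param img image matrix in \[0, 1\].
#' @param side which edge carries the bright strip: `"right"` (default) or
#'   `"left"`.
#' @return the marked image.
#' @export
chirality_marker <- function(img, side = c("right", "left")) {
  img <- as_image(img)
  side <- match.arg(side)
  w <- ncol(img)
  strip <- max(2L, round(w * 0.06))
  bright <- matrix(seq(0.85, 1, length.out = strip), nrow(img), strip, byrow = TRUE)
  dark <- matrix(seq(0.15, 0, length.out = strip), nrow(img), strip, byrow = TRUE)
  if (side == "right") {
    img[, (w - strip + 1L):w] <- bright
    img[, 1:strip] <- dark[, strip:1]
  } else {
    img[, 1:strip] <- bright[, strip:1]
    img[, (w - strip + 1L):w] <- dark
  }
  img
}

#' Detect the chirality of a marked image
#'
#' Compares the mean intensity of the outer left and right quarters; robust
#' to the registry's mild blur, gamma shift, noise, and small rotations, but
#' flipped by horizontal mirroring.
#'
#' @param img a marked image.
#' @param expected the side the marker was placed on.
#' @return `"unflipped"` or `"flipped"`.
#' @export
detect_chirality <- function(img, expected = c("right", "left")) {
  img <- as_image(img)
  expected <- match.arg(expected)
  w <- ncol(img)
  q <- max(2L, w %/% 4L)
  diffmean <- mean(img[, (w - q + 1L):w]) - mean(img[, 1:q])
  bright_right <- diffmean > 0
  if ((expected == "right") == bright_right) "unflipped" else "flipped"
}
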
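# Grayscale image container and plain-text (PGM) I/O. An image is a numeric
# matrix with intensities in [0, 1]; a dataset is a list of images plus an
# integer class-label vector (0-based ids, BI-RADS style) and file names.

#' Validate a grayscale image
#'
#' @param pixels numeric matrix with all entries finite and in \[0, 1\].
#' @return the validated matrix (invisibly classed as a plain matrix).
#' @export
as_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort_input("an image must be a numeric matrix")
  if (any(!is.finite(pixels)))
    abort_input("image intensities must be finite")
  if (any(pixels < 0) || any(pixels > 1))
    abort_input("image intensities must lie in [0, 1]")
  pixels
}

clip01 <- function(x) {
  # pmin/pmax take attributes from their first argument; keep the dims
  y <- pmin(1, pmax(0, x))
  dim(y) <- dim(x)
  y
}

#' Write a grayscale image as ASCII PGM (P2)
#'
#' Portable graymap is the plain-text raster format used throughout the
#' package (no binary image codecs are required). Intensities are quantized
#' to `maxval` levels.
#'
#' @param img image matrix in \[0, 1\].
#' @param path output file path.
#' @param maxval maximum gray level (default 255, i.e. 8-bit).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  img <- as_image(img)
  q <- round(img * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  # one image row per line, row-major as PGM requires
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#'
#' @param path file path.
#' @return image matrix in \[0, 1\].
#' @export
read_pgm <- function(path) {
  raw <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(raw) < 4L || raw[1] != "P2")
    abort_input(sprintf("'%s' is not an ASCII PGM (P2) file", path))
  w <- as.integer(raw[2]); h <- as.integer(raw[3]); maxval <- as.numeric(raw[4])
  px <- as.numeric(raw[-(1:4)])
  if (length(px) != w * h)
    abort_input(sprintf("'%s': expected %d pixels, found %d", path, w * h, length(px)))
  matrix(px, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Construct a labeled image dataset
#'
#' @param images list of image matrices (all the same dimensions).
#' @param labels integer class ids, 0-based, one per image.
#' @param files optional character vector of file names.
#' @return an object of class `image_dataset`.
#' @export
image_dataset <- function(images, labels, files = NULL) {
  if (!is.list(images) || length(images) == 0L)
    abort_input("`images` must be a non-empty list of matrices")
  labels <- as.integer(labels)
  if (length(labels) != length(images))
    abort_input("`labels` must have one entry per image")
  if (any(is.na(labels)) || any(labels < 0L))
    abort_input("labels must be non-negative integers")
  if (is.null(files))
    files <- sprintf("img_%05d.pgm", seq_along(images))
  structure(list(images = images, labels = labels, files = files),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<image_dataset> %d images (%dx%d), %d classes\n",
              length(x$images), d[1], d[2], length(unique(x$labels))))
  print(table(label = x$labels))
  invisible(x)
}

#' @export
length.image_dataset <- function(x) length(x$images)

#' Subset an image dataset by index
#'
#' @param ds an [image_dataset()].
#' @param idx integer indices (duplicates allowed, e.g. after oversampling).
#' @return the subsetted `image_dataset`.
#' @export
dataset_subset <- function(ds, idx) {
  stopifnot(inherits(ds, "image_dataset"))
  image_dataset(ds$images[idx], ds$labels[idx], make.unique(ds$files[idx]))
}

#' Write a dataset as PGM files plus a CSV manifest
#'
#' Emits one `P2` PGM per image and a `manifest.csv` with columns
#' `filename,label` — the on-disk layout shared by the synthetic generator,
#' the augmentation CLI, and the trainer.
#'
#' @param ds an [image_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "image_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$images))
    write_pgm(ds$images[[i]], file.path(dir, ds$files[i]))
  utils::write.csv(data.frame(filename = ds$files, label = ds$labels),
                   file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Read a dataset from a PGM directory with a CSV manifest
#'
#' @param dir directory containing PGM files and `manifest.csv`.
#' @return an [image_dataset()].
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) abort_input(sprintf("no manifest.csv under '%s'", dir))
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  imgs <- lapply(file.path(dir, man$filename), read_pgm)
  image_dataset(imgs, man$label, man$filename)
}

#' Stack a list of images into an (H, W, N) array
#'
#' @param images list of equally sized image matrices.
#' @return numeric array of dimension height x width x n.
#' @export
stack_images <- function(images) {
  d <- dim(images[[1]])
  array(unlist(images, use.names = FALSE), c(d[1], d[2], length(images)))
}
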
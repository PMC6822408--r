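#' Raster image and binary mask containers
#'
#' Images are plain `H x W x 3` integer arrays with channel values in
#' \[0, 255\]; binary masks are `H x W` integer matrices with values in
#' \{0, 1\} (1 = foreground). These helpers validate and construct them.
#'
#' @param pixels numeric array (`H x W x 3`) or matrix that can be coerced.
#' @return `as_raster()` returns a validated `H x W x 3` integer array;
#'   `as_mask()` a validated 0/1 integer matrix.
#' @examples
#' img <- as_raster(array(128L, c(4, 5, 3)))
#' dim(img)
#' @export
as_raster <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("raster image must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) stop("empty image")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("channel values must be integers in [0, 255]")
  pixels
}

#' @rdname as_raster
#' @export
as_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("mask must be a matrix")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || !all(pixels == 0L | pixels == 1L))
    stop("mask values must be 0 or 1")
  pixels
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Weighted luminance with ITU-R BT.601 weights by default
#' (0.299 R + 0.587 G + 0.114 B), rounded to the nearest integer.
#'
#' @param img `H x W x 3` integer array in \[0, 255\].
#' @param weights length-3 numeric RGB weights (normalized to sum 1).
#' @return `H x W` integer matrix of gray levels in \[0, 255\].
#' @examples
#' to_grayscale(as_raster(array(c(255L, 0L, 0L), c(1, 1, 3))))  # 76
#' @export
to_grayscale <- function(img, weights = c(0.299, 0.587, 0.114)) {
  img <- as_raster(img)
  w <- weights / sum(weights)
  g <- img[, , 1] * w[1] + img[, , 2] * w[2] + img[, , 3] * w[3]
  matrix(as.integer(round(g)), nrow = dim(img)[1])
}

#' Apply a binary mask to an RGB image
#'
#' Keeps the original pixels where the mask is 1 and blacks out the rest,
#' producing the stem- and noise-free RGB image at the end of preprocessing.
#'
#' @param img `H x W x 3` integer array.
#' @param mask `H x W` 0/1 matrix of the same height and width.
#' @return masked `H x W x 3` integer array.
#' @export
apply_mask <- function(img, mask) {
  img <- as_raster(img)
  mask <- as_mask(mask)
  if (!identical(dim(img)[1:2], dim(mask)))
    stop("image and mask shapes differ")
  out <- img * as.integer(rep(mask, 3L))
  storage.mode(out) <- "integer"
  out
}

#' Read and write panicle images and masks
#'
#' 8-bit RGB PNG and TIFF are supported. Grayscale files are expanded to
#' three identical channels; an alpha channel, if present, is dropped.
#' Masks are written as 8-bit grayscale PNG with foreground = 255.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @return `read_panicle_image()` returns an `H x W x 3` integer array.
#' @export
read_panicle_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, " (PNG and TIFF are supported)"))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  as_raster(array(as.integer(round(px * 255)), dim(px)))
}

#' @rdname read_panicle_image
#' @param img image array to write.
#' @export
write_panicle_image <- function(img, path) {
  img <- as_raster(img)
  ext <- tolower(tools::file_ext(path))
  arr <- img / 255
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path),
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' @rdname read_panicle_image
#' @param mask 0/1 matrix to write (stored as 0/255 grayscale PNG).
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' @rdname read_panicle_image
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  as_mask(matrix(as.integer(px > 0.5), nrow = nrow(px)))
}
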
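#' Skeletonize a binary mask
#'
#' Zhang-Suen two-subiteration thinning to an (approximately) one-pixel-wide
#' skeleton. The skeleton is always a subset of the input mask and preserves
#' the connectivity of each 8-connected component, with the classic
#' Zhang-Suen caveat that isolated blobs smaller than about 3 x 3 px can be
#' thinned away entirely -- far below grain size, so irrelevant after
#' component-area denoising.
#'
#' @param mask 0/1 integer matrix.
#' @return 0/1 integer matrix of skeleton pixels.
#' @examples
#' sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
#' which(skeletonize(sq) == 1L)  # single center pixel
#' @export
skeletonize <- function(mask) {
  mask <- as_mask(mask)
  .thin_cpp(mask)
}

#' Extract the inner contour of a binary mask
#'
#' A foreground pixel belongs to the contour when at least one of its four
#' edge-neighbors is background; the image border counts as background.
#'
#' @param mask 0/1 integer matrix.
#' @return 0/1 integer matrix of contour pixels (subset of `mask`).
#' @examples
#' sum(extract_contour(matrix(1L, 10, 10)))  # 36 = 2*(10+10) - 4
#' @export
extract_contour <- function(mask) {
  mask <- as_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  p <- matrix(0L, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- mask
  i <- 2:(H + 1L); j <- 2:(W + 1L)
  interior <- p[i - 1L, j] & p[i + 1L, j] & p[i, j - 1L] & p[i, j + 1L]
  matrix(as.integer(mask == 1L & !interior), nrow = H)
}
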
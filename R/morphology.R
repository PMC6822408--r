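#' Disk structuring element
#'
#' The discrete disk inscribed in a `diameter x diameter` window: for the
#' default diameter 5 this is the 25-pixel window with its four corners
#' excluded (21 pixels), the element used throughout stem removal.
#'
#' @param diameter odd integer window size in pixels.
#' @return 0/1 integer matrix of the element footprint.
#' @examples
#' disk_kernel(5)
#' @export
disk_kernel <- function(diameter = 5) {
  if (diameter < 1 || diameter %% 2 == 0) stop("disk diameter must be odd and >= 1")
  k <- EBImage::makeBrush(as.integer(diameter), shape = "disc")
  storage.mode(k) <- "integer"
  k
}

# Pad with `pad` background pixels on every side, run f, crop back.
# Morphology here treats everything outside the frame as background,
# whereas EBImage replicates the border row/column.
.with_zero_pad <- function(mask, pad, f) {
  H <- nrow(mask); W <- ncol(mask)
  big <- matrix(0L, H + 2L * pad, W + 2L * pad)
  big[(pad + 1L):(pad + H), (pad + 1L):(pad + W)] <- mask
  out <- f(big)
  out[(pad + 1L):(pad + H), (pad + 1L):(pad + W)]
}

#' Binary erosion and dilation by a disk
#'
#' Iterated morphological erosion/dilation with the [disk_kernel()]
#' structuring element. Pixels outside the image count as background, so
#' erosion shrinks foreground touching the frame edge. `iterations = 0`
#' returns the input unchanged.
#'
#' @param mask 0/1 integer matrix.
#' @param disk_diameter odd disk window size (default 5).
#' @param iterations number of successive applications (default 1).
#' @return 0/1 integer matrix of the same shape.
#' @examples
#' sq <- matrix(1L, 10, 10)
#' sum(erode_mask(sq, 5, 1))  # 6 x 6 core survives
#' @export
erode_mask <- function(mask, disk_diameter = 5, iterations = 1) {
  mask <- as_mask(mask)
  if (iterations == 0) return(mask)
  k <- disk_kernel(disk_diameter)
  pad <- (disk_diameter %/% 2L) * iterations
  out <- .with_zero_pad(mask, pad, function(m) {
    for (i in seq_len(iterations)) m <- EBImage::erode(m, k)
    m
  })
  as_mask(matrix(as.integer(out), nrow = nrow(mask)))
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, disk_diameter = 5, iterations = 1) {
  mask <- as_mask(mask)
  if (iterations == 0) return(mask)
  k <- disk_kernel(disk_diameter)
  pad <- (disk_diameter %/% 2L) * iterations
  out <- .with_zero_pad(mask, pad, function(m) {
    for (i in seq_len(iterations)) m <- EBImage::dilate(m, k)
    m
  })
  as_mask(matrix(as.integer(out), nrow = nrow(mask)))
}

#' Label connected components
#'
#' @param mask 0/1 integer matrix.
#' @param connectivity 4 or 8 (default 8: diagonal touching merges).
#' @return integer matrix of component labels, 0 for background; components
#'   are numbered in column-major order of first occurrence.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- as_mask(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  .label_components_cpp(mask, as.integer(connectivity))
}

#' Remove small connected components
#'
#' Keeps exactly the components whose pixel area is at least `min_area`;
#' used with a 1000-px threshold (full scanner frame) to strip fabric
#' speckles before stem removal, and a 200-px threshold to clean the stem
#' residual.
#'
#' @inheritParams label_components
#' @param min_area minimum component area in pixels (components with
#'   area >= `min_area` are kept).
#' @return filtered 0/1 integer matrix.
#' @export
remove_small_components <- function(mask, min_area, connectivity = 8) {
  mask <- as_mask(mask)
  if (min_area < 0) stop("min_area must be >= 0")
  if (min_area <= 1 || !any(mask == 1L)) return(mask)
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- c(FALSE, areas >= min_area)  # index 1 = background label 0
  out <- matrix(as.integer(keep[lab + 1L]), nrow = nrow(mask))
  out
}

# Bounding boxes of labeled components: 4 x n matrix (rmin, rmax, cmin, cmax).
.component_bboxes <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(matrix(integer(), 4, 0))
  idx <- which(lab > 0L)
  r <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  l <- lab[idx]
  rbind(rmin = tapply(r, l, min), rmax = tapply(r, l, max),
        cmin = tapply(cc, l, min), cmax = tapply(cc, l, max))
}
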
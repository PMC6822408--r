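#' Naive grain counting baselines
#'
#' The traditional counting approaches the regression method is motivated
#' against. `count_components()` counts connected regions of the binary
#' mask: exact for untouched grains, an undercount as soon as grains touch.
#' `erosion_split_count()` erodes first in the hope of splitting touching
#' grains, then counts components; grains merged deeper than the erosion
#' depth stay merged, and small grains can vanish entirely -- both failure
#' modes are deliberate and observable.
#'
#' @param mask 0/1 integer matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer count of connected components.
#' @examples
#' m <- matrix(0L, 5, 5); m[1, 1] <- 1L; m[2, 2] <- 1L
#' count_components(m, connectivity = 8)  # 1
#' count_components(m, connectivity = 4)  # 2
#' @export
count_components <- function(mask, connectivity = 8) {
  max(label_components(mask, connectivity))
}

#' @rdname count_components
#' @param disk_diameter,iterations erosion parameters (see [erode_mask()]).
#' @export
erosion_split_count <- function(mask, disk_diameter = 5, iterations = 1,
                                connectivity = 8) {
  count_components(erode_mask(mask, disk_diameter, iterations), connectivity)
}
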
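#' Preprocessing configuration
#'
#' Parameters of the preprocessing chain. The defaults are tuned to the
#' full scanner frame (2480 x 3507 px) where rice grains are 30-50 px wide
#' and the out-of-focus stem is 5-10 px: a 1000-px component filter strips
#' fabric speckles (< 100 px), three erosions with the 5 x 5 disk (total
#' erosion depth 6 px) erase the stem but not the grains, and a 200-px
#' filter cleans the stem residual.
#'
#' `scaled_preprocess_config()` rescales those pixel-dependent defaults to
#' another frame size: areas scale with s^2 and the erosion depth with s,
#' where `s = sqrt(H*W / (2480*3507))` is the linear scale relative to the
#' reference frame. At 620 x 877 (s = 0.25) this gives a 62-px denoise
#' filter, a 12-px stem filter and one erode/dilate iteration.
#'
#' @param denoise_min_area minimum component area (px) kept after Otsu.
#' @param stem_min_area minimum component area (px) kept in the stem residual.
#' @param disk_diameter odd disk window size for the opening (px).
#' @param erode_iterations,dilate_iterations iteration counts of the opening.
#' @param remove_stem logical; disable to keep stems (with/without-stem
#'   comparisons).
#' @param connectivity component connectivity, 4 or 8.
#' @param invert logical; foreground darker than background.
#' @return a `preprocess_config` list.
#' @examples
#' scaled_preprocess_config(c(620, 877))
#' @export
preprocess_config <- function(denoise_min_area = 1000, stem_min_area = 200,
                              disk_diameter = 5, erode_iterations = 3,
                              dilate_iterations = 3, remove_stem = TRUE,
                              connectivity = 8, invert = FALSE) {
  if (denoise_min_area < 0 || stem_min_area < 0) stop("area thresholds must be >= 0")
  if (erode_iterations < 0 || dilate_iterations < 0) stop("iterations must be >= 0")
  if (disk_diameter < 1 || disk_diameter %% 2 == 0) stop("disk_diameter must be odd and >= 1")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(denoise_min_area = denoise_min_area,
                 stem_min_area = stem_min_area,
                 disk_diameter = as.integer(disk_diameter),
                 erode_iterations = as.integer(erode_iterations),
                 dilate_iterations = as.integer(dilate_iterations),
                 remove_stem = isTRUE(remove_stem),
                 connectivity = as.integer(connectivity),
                 invert = isTRUE(invert)),
            class = "preprocess_config")
}

#' @rdname preprocess_config
#' @param image_size `c(H, W)` of the images to be processed.
#' @param reference_size the frame the defaults were tuned on.
#' @param ... further arguments passed to [preprocess_config()].
#' @export
scaled_preprocess_config <- function(image_size,
                                     reference_size = c(2480, 3507), ...) {
  s <- sqrt(prod(image_size) / prod(reference_size))
  radius <- 2L  # 5 x 5 disk
  depth <- max(1L, as.integer(round(3 * radius * s)))
  iters <- max(1L, as.integer(ceiling(depth / radius)))
  preprocess_config(denoise_min_area = max(1, round(1000 * s^2)),
                    stem_min_area = max(1, round(200 * s^2)),
                    disk_diameter = 5,
                    erode_iterations = iters, dilate_iterations = iters, ...)
}

#' Separate stem pixels from branch pixels
#'
#' Opens the denoised mask with the disk element (erode then dilate with
#' equal iteration counts), which erases structures thinner than the total
#' erosion depth -- the stem -- while restoring the wider grains. The
#' residual `denoised AND NOT opened` is the stem plus erosion fringe; a
#' component-area filter keeps only the true stem pieces, and subtracting
#' those from the denoised mask yields the stem-free branch mask. All
#' subtractions are set differences, so masks remain 0/1.
#'
#' @param denoised 0/1 matrix, already component-filtered.
#' @param cfg a [preprocess_config()].
#' @return list with `stemless`, `stem` and `opened` masks; `stemless` and
#'   `stem` are disjoint and both subsets of `denoised`.
#' @export
remove_stem <- function(denoised, cfg = preprocess_config()) {
  denoised <- as_mask(denoised)
  opened <- dilate_mask(erode_mask(denoised, cfg$disk_diameter, cfg$erode_iterations),
                        cfg$disk_diameter, cfg$dilate_iterations)
  stem_noisy <- matrix(as.integer(denoised == 1L & opened == 0L), nrow = nrow(denoised))
  stem <- remove_small_components(stem_noisy, cfg$stem_min_area, cfg$connectivity)
  stemless <- matrix(as.integer(denoised == 1L & stem == 0L), nrow = nrow(denoised))
  list(stemless = stemless, stem = stem, opened = opened)
}

#' Preprocess a panicle image
#'
#' Full preprocessing chain: grayscale conversion, Otsu segmentation,
#' component-area denoising, disk-opening stem removal, and RGB masking.
#' With `cfg$remove_stem = FALSE` the stem stage is skipped (`stem_mask`
#' empty, `stemless_mask` = `denoised_mask`), which supports with/without
#' stem comparisons.
#'
#' @param img `H x W x 3` integer array in \[0, 255\].
#' @param cfg a [preprocess_config()].
#' @return a `preprocess_result` with fields `otsu_threshold`, `raw_mask`,
#'   `denoised_mask`, `opened_mask`, `stem_mask`, `stemless_mask`,
#'   `masked_rgb`, `config`, and per-stage foreground `pixel_counts`.
#' @export
preprocess_image <- function(img, cfg = preprocess_config()) {
  img <- as_raster(img)
  gray <- to_grayscale(img)
  ot <- otsu_threshold(gray, invert = cfg$invert)
  denoised <- remove_small_components(ot$mask, cfg$denoise_min_area, cfg$connectivity)
  if (cfg$remove_stem) {
    st <- remove_stem(denoised, cfg)
  } else {
    st <- list(stemless = denoised,
               stem = matrix(0L, nrow(denoised), ncol(denoised)),
               opened = denoised)
  }
  masked <- apply_mask(img, st$stemless)
  res <- list(otsu_threshold = ot$threshold,
              raw_mask = ot$mask,
              denoised_mask = denoised,
              opened_mask = st$opened,
              stem_mask = st$stem,
              stemless_mask = st$stemless,
              masked_rgb = masked,
              config = cfg,
              pixel_counts = c(raw = sum(ot$mask), denoised = sum(denoised),
                               opened = sum(st$opened), stem = sum(st$stem),
                               stemless = sum(st$stemless)))
  class(res) <- "preprocess_result"
  res
}

#' @export
print.preprocess_result <- function(x, ...) {
  d <- dim(x$raw_mask)
  cat("preprocess_result:", d[1], "x", d[2], "px, Otsu threshold",
      x$otsu_threshold, "\n")
  cat("  foreground px:",
      paste(names(x$pixel_counts), x$pixel_counts, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write preprocessing outputs to disk
#'
#' Saves the intermediate masks as 0/255 PNG images, the masked RGB image,
#' and a JSON metadata file with the Otsu threshold and per-stage pixel
#' counts, mirroring the auditable stages of the preprocessing flow chart.
#'
#' @param res a `preprocess_result`.
#' @param dir output directory (created if missing).
#' @param stem base name for the output files.
#' @return invisibly, the metadata file path.
#' @export
write_preprocess_result <- function(res, dir, stem = "image") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("raw_mask", "denoised_mask", "opened_mask", "stem_mask",
               "stemless_mask"))
    write_mask(res[[nm]], file.path(dir, paste0(stem, "_", nm, ".png")))
  write_panicle_image(res$masked_rgb, file.path(dir, paste0(stem, "_masked.png")))
  meta <- list(otsu_threshold = res$otsu_threshold,
               pixel_counts = as.list(res$pixel_counts),
               config = unclass(res$config))
  path <- file.path(dir, paste0(stem, "_meta.json"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
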
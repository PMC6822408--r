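#' Split a branch mask into connected components
#'
#' One full-size mask per connected component (primary branch, or grain
#' cluster once the stem has been removed). The returned masks are pairwise
#' disjoint and their union is the input.
#'
#' @param stemless 0/1 integer matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return list of 0/1 matrices, empty for an empty mask.
#' @export
split_branches <- function(stemless, connectivity = 8) {
  stemless <- as_mask(stemless)
  lab <- label_components(stemless, connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i)
    matrix(as.integer(lab == i), nrow = nrow(stemless)))
}

#' Pixel-fraction features of a branch mask
#'
#' The three counting features, each a foreground pixel count divided by the
#' original image area `s_im`:
#' \describe{
#'   \item{CD (coverage degree)}{branch mask pixels / `s_im`}
#'   \item{Sk (skeleton)}{pixels of the thinned one-px skeleton / `s_im`}
#'   \item{Co (contour)}{pixels of the inner boundary / `s_im`}
#' }
#' Skeleton and contour are computed per connected component (on a padded
#' bounding-box crop, which is exact because 8-connected components never
#' interact across a 3 x 3 neighborhood) and summed over components; for
#' disjoint components the summed counts equal the whole-mask counts, which
#' is asserted for CD.
#'
#' @param stemless 0/1 integer matrix (stem-free branch mask).
#' @param s_im area of the original image in pixels (H * W).
#' @param connectivity component connectivity (default 8).
#' @return object of class `panicle_features`: list with fractions `cd`,
#'   `sk`, `co`, counts `n_cd`, `n_sk`, `n_co`, `s_im`, `n_branches` and a
#'   `per_branch` data frame.
#' @export
compute_features <- function(stemless, s_im, connectivity = 8) {
  stemless <- as_mask(stemless)
  if (s_im <= 0) stop("s_im must be positive")
  lab <- label_components(stemless, connectivity)
  n <- max(lab)
  per <- data.frame(branch = integer(0), n_cd = integer(0),
                    n_sk = integer(0), n_co = integer(0))
  if (n > 0L) {
    bb <- .component_bboxes(lab)
    H <- nrow(stemless); W <- ncol(stemless)
    rows <- lapply(seq_len(n), function(i) {
      r0 <- max(1L, bb["rmin", i] - 1L); r1 <- min(H, bb["rmax", i] + 1L)
      c0 <- max(1L, bb["cmin", i] - 1L); c1 <- min(W, bb["cmax", i] + 1L)
      crop <- matrix(as.integer(lab[r0:r1, c0:c1] == i), nrow = r1 - r0 + 1L)
      data.frame(branch = i, n_cd = sum(crop),
                 n_sk = sum(skeletonize(crop)),
                 n_co = sum(extract_contour(crop)))
    })
    per <- do.call(rbind, rows)
  }
  n_cd <- sum(per$n_cd)
  stopifnot(n_cd == sum(stemless))  # branch additivity of coverage
  out <- list(cd = n_cd / s_im, sk = sum(per$n_sk) / s_im,
              co = sum(per$n_co) / s_im,
              n_cd = n_cd, n_sk = sum(per$n_sk), n_co = sum(per$n_co),
              s_im = s_im, n_branches = n, per_branch = per)
  class(out) <- "panicle_features"
  out
}

#' @export
print.panicle_features <- function(x, ...) {
  cat(sprintf("panicle_features: %d branches, CD=%.5f Sk=%.5f Co=%.5f (s_im=%d)\n",
              x$n_branches, x$cd, x$sk, x$co, as.integer(x$s_im)))
  invisible(x)
}

#' Assemble a feature table
#'
#' @param fvs list of `panicle_features`.
#' @param image_id optional character vector of image identifiers.
#' @return data frame with one row per image: `image_id`, `n_branches`,
#'   `cd`, `sk`, `co`.
#' @export
feature_table <- function(fvs, image_id = NULL) {
  if (is.null(image_id)) image_id <- sprintf("img%03d", seq_along(fvs))
  data.frame(image_id = image_id,
             n_branches = vapply(fvs, `[[`, 0L, "n_branches"),
             cd = vapply(fvs, `[[`, 0, "cd"),
             sk = vapply(fvs, `[[`, 0, "sk"),
             co = vapply(fvs, `[[`, 0, "co"))
}

#' Min-max normalization statistics
#'
#' Per-feature training-set extremes used to rescale CD, Sk and Co to
#' \[0, 1\] (CD' = (CD - CD_min) / (CD_max - CD_min), likewise Sk', Co').
#' Statistics are fit per group (subspecies x device x shape), matching the
#' per-group counting models.
#'
#' @param train feature table (data frame with `cd`, `sk`, `co` columns) or
#'   list of `panicle_features`.
#' @param group optional group label stored with the stats.
#' @return object of class `norm_stats`.
#' @export
fit_normalizer <- function(train, group = NULL) {
  if (!is.data.frame(train)) train <- feature_table(train)
  if (nrow(train) < 2) stop("need at least 2 feature vectors to fit normalization")
  st <- lapply(c("cd", "sk", "co"), function(f) {
    rng <- range(train[[f]])
    if (diff(rng) <= 0)
      stop("degenerate feature range: ", f, " has max = min")
    rng
  })
  names(st) <- c("cd", "sk", "co")
  structure(list(cd = st$cd, sk = st$sk, co = st$co, group = group),
            class = "norm_stats")
}

#' @export
print.norm_stats <- function(x, ...) {
  cat("norm_stats", if (!is.null(x$group)) paste0("[", x$group, "]"), ":\n")
  for (f in c("cd", "sk", "co"))
    cat(sprintf("  %s: min=%.6f max=%.6f\n", f, x[[f]][1], x[[f]][2]))
  invisible(x)
}

#' Apply min-max normalization
#'
#' Maps each feature through `(x - min) / (max - min)` using training-set
#' extremes. Values for unseen images may fall outside \[0, 1\]; they are
#' not clamped.
#'
#' @param x feature table (data frame), single `panicle_features`, or list
#'   of them.
#' @param stats a [fit_normalizer()] result.
#' @return data frame with columns `cd_n`, `sk_n`, `co_n` (other columns of
#'   a feature-table input are carried through).
#' @export
normalize_features <- function(x, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (inherits(x, "panicle_features")) x <- list(x)
  if (!is.data.frame(x)) x <- feature_table(x)
  for (f in c("cd", "sk", "co")) {
    rng <- stats[[f]]
    x[[paste0(f, "_n")]] <- (x[[f]] - rng[1]) / (rng[2] - rng[1])
  }
  x
}

#' Serialize normalization statistics
#' @param stats a `norm_stats`.
#' @param path JSON file path.
#' @export
write_norm_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
read_norm_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(cd = as.numeric(x$cd), sk = as.numeric(x$sk),
                 co = as.numeric(x$co), group = x$group),
            class = "norm_stats")
}
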
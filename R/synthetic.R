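#' Specification of a synthetic panicle image
#'
#' Describes one rendered panicle: bright elongated grains drawn as filled
#' rotated ellipses attached along thin branch rachides on a near-black
#' fabric background, with optional fabric speckle noise. Geometry defaults
#' mimic the scanner setup: on the 2480 x 3507 reference frame grains are
#' 30-50 px wide, stems and rachides 5-10 px, and speckles under 100 px.
#' For other frame sizes every length is scaled by
#' `s = sqrt(H*W / (2480*3507))` and every area by `s^2`, so the same
#' morphological structure is rendered at any resolution.
#'
#' Shape C renders each primary branch as a detached group; Shape B joins
#' the branches to a common stem polyline. `overlap_prob` is the per-grain
#' probability that a placement is allowed to touch/overlap an earlier
#' grain of the same branch (placed close to it deliberately); with
#' `overlap_prob = 0` grains are guaranteed pairwise disjoint, so the
#' ground-truth grain mask has exactly `n_grains` connected components.
#'
#' @param n_grains total grains on the panicle.
#' @param shape `"C"` (branches detached) or `"B"` (branches on a stem).
#' @param subspecies `"indica"` (long, slender grains; default aspect 3.5)
#'   or `"japonica"` (default aspect 2.2).
#' @param image_size `c(H, W)` in pixels.
#' @param n_branches number of primary branches; by default drawn at render
#'   time, uniformly between `max(8, n_grains/20)` and 14 (a branch holds at
#'   most ~20 grains; beyond that the branch count varies freely, so
#'   stem/rachis area is mostly count-independent clutter rather than a
#'   counting signal).
#' @param grain_width `c(min, max)` grain width in px on the reference frame.
#' @param grain_aspect grain length/width ratio; default from `subspecies`.
#' @param stem_width `c(min, max)` stem/rachis width in px (reference
#'   frame); `c(0, 0)` renders grains only, with no stem or rachis drawn.
#' @param overlap_prob probability in \[0, 1\] of an overlap-permitted
#'   grain placement.
#' @param n_speckles number of fabric speckles.
#' @param speckle_area `c(min, max)` speckle area in px (reference frame);
#'   must stay below 100.
#' @param background_level maximum background gray level (uniform in
#'   \[0, level\]).
#' @param foreground_level `c(min, max)` grain gray level range.
#' @param awns draw 1-2 px awn hairlines at grain tips (off by default).
#' @param seed integer RNG seed; same spec (incl. seed) renders
#'   bit-identical output.
#' @param reference_size frame the pixel defaults refer to.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_grains = 150, shape = c("C", "B"),
                           subspecies = c("indica", "japonica"),
                           image_size = c(2480, 3507), n_branches = NULL,
                           grain_width = c(30, 50), grain_aspect = NULL,
                           stem_width = c(5, 10), overlap_prob = 0.1,
                           n_speckles = 12, speckle_area = c(10, 90),
                           background_level = 20,
                           foreground_level = c(140, 230), awns = FALSE,
                           seed = 1L, reference_size = c(2480, 3507)) {
  shape <- match.arg(shape)
  subspecies <- match.arg(subspecies)
  if (n_grains < 1) stop("n_grains must be >= 1")
  if (overlap_prob < 0 || overlap_prob > 1) stop("overlap_prob must be in [0, 1]")
  if (any(grain_width <= 0) || any(stem_width < 0)) stop("invalid width range")
  if (max(speckle_area) >= 100) stop("speckle areas must stay below 100 px")
  if (is.null(grain_aspect))
    grain_aspect <- if (subspecies == "indica") 3.5 else 2.2
  structure(list(n_grains = as.integer(n_grains), shape = shape,
                 subspecies = subspecies,
                 image_size = as.integer(image_size),
                 n_branches = if (is.null(n_branches)) NULL else as.integer(n_branches),
                 grain_width = grain_width, grain_aspect = grain_aspect,
                 stem_width = stem_width, overlap_prob = overlap_prob,
                 n_speckles = as.integer(n_speckles),
                 speckle_area = speckle_area,
                 background_level = as.integer(background_level),
                 foreground_level = foreground_level, awns = isTRUE(awns),
                 seed = as.integer(seed),
                 reference_size = as.integer(reference_size)),
            class = "synthetic_spec")
}

# linear indices of pixels inside a rotated ellipse, clipped to the frame
.ellipse_pixels <- function(H, W, cy, cx, a, b, phi) {
  ey <- sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
  ex <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
  r0 <- max(1L, floor(cy - ey)); r1 <- min(H, ceiling(cy + ey))
  c0 <- max(1L, floor(cx - ex)); c1 <- min(W, ceiling(cx + ex))
  if (r0 > r1 || c0 > c1) return(integer(0))
  dy <- (r0:r1) - cy
  dx <- (c0:c1) - cx
  Xr <- outer(dy, dx, function(y, x) (x * cos(phi) + y * sin(phi)) / a)
  Yr <- outer(dy, dx, function(y, x) (-x * sin(phi) + y * cos(phi)) / b)
  inside <- which(Xr^2 + Yr^2 <= 1)
  if (!length(inside)) return(integer(0))
  rr <- (inside - 1L) %% length(dy) + r0
  cc <- (inside - 1L) %/% length(dy) + c0
  rr + (cc - 1L) * H
}

# linear indices of a thick line segment (width w) from (y0,x0) to (y1,x1)
.segment_pixels <- function(H, W, y0, x0, y1, x1, w) {
  half <- max(w / 2, 0.5)
  r0 <- max(1L, floor(min(y0, y1) - half)); r1 <- min(H, ceiling(max(y0, y1) + half))
  c0 <- max(1L, floor(min(x0, x1) - half)); c1 <- min(W, ceiling(max(x0, x1) + half))
  if (r0 > r1 || c0 > c1) return(integer(0))
  ys <- r0:r1; xs <- c0:c1
  vy <- y1 - y0; vx <- x1 - x0
  len2 <- vy^2 + vx^2
  gy <- matrix(ys, length(ys), length(xs))
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((gy - y0) * vy + (gx - x0) * vx) / len2))
  d2 <- (gy - (y0 + t * vy))^2 + (gx - (x0 + t * vx))^2
  inside <- which(d2 <= half^2)
  if (!length(inside)) return(integer(0))
  rr <- (inside - 1L) %% length(ys) + r0
  cc <- (inside - 1L) %/% length(ys) + c0
  rr + (cc - 1L) * H
}

#' Render a synthetic panicle
#'
#' Draws the panicle described by a [synthetic_spec()] and returns the RGB
#' image together with ground-truth grain and stem masks, the true grain
#' count, and per-grain geometry records. Rendering is fully deterministic
#' given the spec (including its seed).
#'
#' Grains are placed at alternating sides of each rachis at evenly spaced
#' nodes; a placement that is not overlap-permitted is collision-checked
#' against all previously drawn grains and all other branches and retried
#' with fresh angles, node jitter and side flips (up to 80 times, after
#' which rendering aborts with a "placement overflow" error).
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `synthetic_panicle`: list with `image`
#'   (`H x W x 3` integer array), `grain_mask`, `stem_mask`, `true_count`,
#'   `per_grain` (data frame: center, axes, angle, branch), and `spec`.
#' @export
render_panicle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  s <- sqrt(prod(spec$image_size) / prod(spec$reference_size))
  gown <- matrix(0L, H, W)  # grain owner (branch id)
  sown <- matrix(0L, H, W)  # stem/rachis owner
  lvl <- matrix(0, H, W)    # foreground gray level before noise
  nb <- spec$n_branches
  if (is.null(nb)) {
    # large panicles carry more primary branches (at most ~20 grains each);
    # the upper range is free so stem/rachis area stays mostly
    # count-independent
    lo <- max(8L, as.integer(ceiling(spec$n_grains / 20)))
    nb <- sample(lo:max(14L, lo + 2L), 1)
  }
  # distribute grains over branches
  per_branch <- rep(spec$n_grains %/% nb, nb)
  extra <- spec$n_grains %% nb
  if (extra > 0) per_branch[seq_len(extra)] <- per_branch[seq_len(extra)] + 1L
  # branch slots along the width; rachides run along the height
  x_lo <- 0.06 * W; x_hi <- 0.94 * W
  slot <- (x_hi - x_lo) / nb
  y_top <- 0.08 * H; y_bot <- 0.94 * H
  stem_w <- runif(1, spec$stem_width[1], spec$stem_width[2]) * s
  stem_lvl <- runif(1, 110, 170)
  cx_base <- x_lo + (seq_len(nb) - 0.5) * slot
  per_grain <- vector("list", spec$n_grains)
  gi <- 0L
  draw_stems <- max(spec$stem_width) > 0
  if (spec$shape == "B" && draw_stems) {
    # common stem across the top joining all branch bases
    idx <- .segment_pixels(H, W, y_top, cx_base[1], y_top, cx_base[nb], stem_w)
    sown[idx] <- 1L; lvl[idx] <- stem_lvl
  }
  for (b in seq_len(nb)) {
    g <- per_branch[b]
    cx <- cx_base[b] + runif(1, -0.08, 0.08) * slot
    tilt <- tan(runif(1, -2, 2) * pi / 180)
    rx0 <- cx + tilt * (y_top - (y_top + y_bot) / 2)
    rx1 <- cx + tilt * (y_bot - (y_top + y_bot) / 2)
    rw <- runif(1, spec$stem_width[1], spec$stem_width[2]) * s
    if (draw_stems) {
      ridx <- .segment_pixels(H, W, y_top, rx0, y_bot, rx1, rw)
      free <- ridx[sown[ridx] == 0L | sown[ridx] == b]
      sown[free] <- b; lvl[free] <- stem_lvl + runif(1, -15, 15)
    }
    if (g == 0) next
    phi_r <- atan2(y_bot - y_top, rx1 - rx0)  # rachis direction (approx. pi/2)
    # grains point down-rachis; stop the node run early enough that the
    # longest possible grain tip stays inside the frame
    a_max <- spec$grain_width[2] / 2 * spec$grain_aspect * 1.1 * s
    y_nodes_end <- max(y_bot - 2 * a_max, (y_top + y_bot) / 2)
    d <- (y_nodes_end - y_top) / (g + 1)
    prev_node <- NULL; prev_side <- 1
    for (j in seq_len(g)) {
      gi <- gi + 1L
      side <- if (j %% 2 == 0) 1 else -1
      ny <- y_top + j * d + runif(1, -0.15, 0.15) * d
      nx <- rx0 + (ny - y_top) / (y_bot - y_top) * (rx1 - rx0)
      wpx <- runif(1, spec$grain_width[1], spec$grain_width[2]) * s
      bax <- wpx / 2
      aax <- bax * spec$grain_aspect * runif(1, 0.9, 1.1)
      ny0 <- ny
      allow <- runif(1) < spec$overlap_prob && !is.null(prev_node)
      if (allow) {  # slide toward the previous grain so they actually touch
        shift <- runif(1, 0.45, 0.75) * d
        ny <- prev_node[1] + shift * 0.3
        nx <- prev_node[2]
        side <- prev_side
      }
      placed <- FALSE
      for (try in seq_len(80)) {
        # steep angles pack tightly along the rachis, shallow ones stay
        # inside the branch slot; retries explore both, flipping sides and
        # sliding along the rachis when crowded
        theta <- runif(1, 25, 65) * pi / 180
        # pinned overlap placements fall back to clean ones when crowded;
        # under overlap_prob > 0, last-resort retries may touch a
        # same-branch grain instead of failing outright
        eff_allow <- (allow && try <= 30) ||
          (spec$overlap_prob > 0 && try > 60)
        tside <- if (!eff_allow && try > 40 && try %% 2 == 0) -side else side
        tny <- if (eff_allow) ny else ny0 + runif(1, -0.35, 0.35) * d
        phi <- phi_r + tside * theta
        # base of the ellipse just overlaps the rachis edge (attachment),
        # body entirely on one side
        off <- aax + rw / 2 - max(2, 0.12 * aax)
        cyg <- tny + off * sin(phi); cxg <- nx + off * cos(phi)
        idx <- .ellipse_pixels(H, W, cyg, cxg, aax, bax, phi)
        if (!length(idx)) next
        # 8-neighborhood of the footprint: grains merely touching (no shared
        # pixel) would still merge components, so adjacency counts as conflict
        nidx <- unique(c(idx, idx - 1L, idx + 1L, idx - H, idx + H,
                         idx - H - 1L, idx - H + 1L, idx + H - 1L, idx + H + 1L))
        nidx <- nidx[nidx >= 1L & nidx <= H * W]
        ok <- if (eff_allow)
          all(gown[nidx] %in% c(0L, b)) && all(sown[nidx] %in% c(0L, b))
        else
          all(gown[nidx] == 0L) && all(sown[nidx] %in% c(0L, b))
        if (ok) {
          glvl <- runif(1, spec$foreground_level[1], spec$foreground_level[2])
          gown[idx] <- b
          lvl[idx] <- glvl
          if (spec$awns && runif(1) < 0.3) {
            tipy <- cyg + aax * sin(phi); tipx <- cxg + aax * cos(phi)
            aidx <- .segment_pixels(H, W, tipy, tipx,
                                    tipy + aax * sin(phi), tipx + aax * cos(phi),
                                    max(1, 1.5 * s))
            aidx <- aidx[gown[aidx] == 0L & sown[aidx] == 0L]
            gown[aidx] <- b
            lvl[aidx] <- glvl * 0.8
          }
          per_grain[[gi]] <- data.frame(center_y = cyg, center_x = cxg,
                                        a = aax, b = bax, angle = phi,
                                        branch = b, width_px = wpx)
          placed <- TRUE
          prev_node <- c(tny, nx); prev_side <- tside
          break
        }
      }
      if (!placed)
        stop("placement overflow: could not place grain ", gi,
             " without violating overlap constraints")
    }
  }
  grain_mask <- matrix(as.integer(gown > 0L), H, W)
  stem_mask <- matrix(as.integer(sown > 0L & gown == 0L), H, W)
  cls <- matrix(0L, H, W)
  cls[sown > 0L] <- 2L
  cls[gown > 0L] <- 1L
  # fabric speckles on free background
  for (k in seq_len(spec$n_speckles)) {
    A <- runif(1, spec$speckle_area[1], spec$speckle_area[2]) * s^2
    r1 <- sqrt(A / pi) * runif(1, 0.7, 1.4)
    r2 <- A / pi / r1
    idx <- .ellipse_pixels(H, W, runif(1, 2, H - 1), runif(1, 2, W - 1),
                           max(r1, 0.6), max(r2, 0.6), runif(1, 0, pi))
    idx <- idx[cls[idx] == 0L]
    if (!length(idx)) next
    cls[idx] <- 3L
    lvl[idx] <- runif(1, 90, 200)
  }
  # photometry: per-pixel noise on foreground, uniform dark background
  fg <- which(cls > 0L)
  lvl[fg] <- pmin(255, pmax(70, lvl[fg] + rnorm(length(fg), 0, 6)))
  bg <- which(cls == 0L)
  lvl[bg] <- sample.int(spec$background_level + 1L, length(bg), replace = TRUE) - 1L
  rmul <- c(1, 1, 0.85, 1)[cls + 1L]     # bg, grain, stem, speckle
  gmul <- c(1, 0.92, 1, 0.95)[cls + 1L]
  bmul <- c(1, 0.55, 0.5, 0.8)[cls + 1L]
  img <- array(0L, c(H, W, 3))
  img[, , 1] <- as.integer(round(pmin(255, lvl * rmul)))
  img[, , 2] <- as.integer(round(pmin(255, lvl * gmul)))
  img[, , 3] <- as.integer(round(pmin(255, lvl * bmul)))
  out <- list(image = img, grain_mask = grain_mask, stem_mask = stem_mask,
              true_count = spec$n_grains, n_branches = nb,
              per_grain = do.call(rbind, per_grain), spec = spec)
  class(out) <- "synthetic_panicle"
  out
}

#' @export
print.synthetic_panicle <- function(x, ...) {
  cat(sprintf("synthetic_panicle: %d x %d px, %d grains on %d branches (shape %s, %s)\n",
              nrow(x$grain_mask), ncol(x$grain_mask), x$true_count,
              x$n_branches, x$spec$shape, x$spec$subspecies))
  invisible(x)
}

#' Per-image specs for a synthetic dataset
#'
#' Samples one [synthetic_spec()] per image: grain counts uniform over
#' `count_range` and an independent sub-seed per image, both drawn from the
#' dataset seed, so the dataset is reproducible image by image without
#' keeping all images in memory.
#'
#' @param n_images number of images.
#' @param seed dataset RNG seed.
#' @param count_range `c(min, max)` true grain counts.
#' @param ... forwarded to [synthetic_spec()] (shape, subspecies,
#'   image_size, overlap_prob, ...).
#' @return list of `synthetic_spec`.
#' @export
dataset_specs <- function(n_images, seed = 1L, count_range = c(60, 220), ...) {
  if (n_images < 1) stop("n_images must be >= 1")
  set.seed(seed)
  counts <- sample(count_range[1]:count_range[2], n_images, replace = TRUE)
  sub_seeds <- sample.int(2147483646L, n_images)
  lapply(seq_len(n_images), function(i)
    synthetic_spec(n_grains = counts[i], seed = sub_seeds[i], ...))
}

#' Generate an annotated synthetic dataset
#'
#' Renders `n_images` panicles from [dataset_specs()] and returns them with
#' a metadata table; optionally writes images, ground-truth masks and a
#' `truth.csv` to a directory.
#'
#' @inheritParams dataset_specs
#' @param dir optional output directory.
#' @return list with `panicles` (list of `synthetic_panicle`) and
#'   `metadata` (data frame: image_id, true_count, shape, subspecies, seed).
#' @export
generate_dataset <- function(n_images, seed = 1L, count_range = c(60, 220),
                             dir = NULL, ...) {
  specs <- dataset_specs(n_images, seed = seed, count_range = count_range, ...)
  panicles <- lapply(specs, render_panicle)
  metadata <- data.frame(
    image_id = sprintf("img%04d", seq_len(n_images)),
    true_count = vapply(specs, `[[`, 0L, "n_grains"),
    shape = vapply(specs, `[[`, "", "shape"),
    subspecies = vapply(specs, `[[`, "", "subspecies"),
    seed = vapply(specs, `[[`, 0L, "seed"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_images)) {
      id <- metadata$image_id[i]
      write_panicle_image(panicles[[i]]$image, file.path(dir, paste0(id, ".png")))
      write_mask(panicles[[i]]$grain_mask, file.path(dir, paste0(id, "_grains.png")))
      write_mask(panicles[[i]]$stem_mask, file.path(dir, paste0(id, "_stem.png")))
    }
    write.csv(metadata, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(panicles = panicles, metadata = metadata)
}
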
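# Independent brute-force reference implementations used to validate the
# package's morphology, thresholding and thinning. Deliberately written with
# different algorithms/formulations than the package code paths.

# flood-fill component labeling with an explicit stack
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offs <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (cc in seq_len(W)) for (rr in seq_len(H)) {
    if (mask[rr, cc] == 0L || lab[rr, cc] != 0L) next
    nxt <- nxt + 1L
    stack <- matrix(c(rr, cc), 1)
    lab[rr, cc] <- nxt
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        r2 <- p[1] + offs[k, 1]; c2 <- p[2] + offs[k, 2]
        if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
            mask[r2, c2] == 1L && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          stack <- rbind(stack, c(r2, c2))
        }
      }
    }
  }
  lab
}

# shift a matrix by (dy, dx), filling exposed cells with `fill`
shift_mat <- function(m, dy, dx, fill = 0L) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- seq_len(H) - dy; cs <- seq_len(W) - dx
  ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Minkowski formulation: erosion = AND over kernel-offset shifts (background
# outside the frame), dilation = OR
oracle_erode <- function(mask, kernel) {
  r0 <- (nrow(kernel) + 1) %/% 2
  out <- matrix(1L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(kernel))) for (j in seq_len(ncol(kernel))) {
    if (kernel[i, j] == 0) next
    out <- out & shift_mat(mask, r0 - i, r0 - j, 0L)
  }
  matrix(as.integer(out), nrow = nrow(mask))
}

oracle_dilate <- function(mask, kernel) {
  r0 <- (nrow(kernel) + 1) %/% 2
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(kernel))) for (j in seq_len(ncol(kernel))) {
    if (kernel[i, j] == 0) next
    out <- out | shift_mat(mask, i - r0, j - r0, 0L)
  }
  matrix(as.integer(out), nrow = nrow(mask))
}

# per-pixel 4-neighbor scan
oracle_contour <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (mask[r, cc] == 0L) next
    nb <- c(if (r > 1) mask[r - 1, cc] else 0L,
            if (r < H) mask[r + 1, cc] else 0L,
            if (cc > 1) mask[r, cc - 1] else 0L,
            if (cc < W) mask[r, cc + 1] else 0L)
    if (any(nb == 0L) || r == 1 || r == H || cc == 1 || cc == W)
      out[r, cc] <- 1L
  }
  out
}

# Otsu by minimizing total within-class sum of squares (equivalent dual of
# maximizing between-class variance); returns the smallest optimal t
oracle_otsu <- function(gray) {
  v <- as.vector(gray)
  best_t <- NA_integer_; best_w <- Inf
  for (t in 0:254) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    if (!length(g0) || !length(g1)) next
    wcv <- sum((g0 - mean(g0))^2) + sum((g1 - mean(g1))^2)
    if (wcv < best_w - 1e-9) { best_w <- wcv; best_t <- t }
  }
  best_t
}

# Zhang-Suen thinning, plain-R transcription on a padded matrix
oracle_thin <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  img <- matrix(0L, H + 2, W + 2)
  img[2:(H + 1), 2:(W + 1)] <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      idx <- which(img == 1L)
      if (!length(idx)) break
      del <- integer(0)
      for (q in idx) {
        r <- (q - 1) %% (H + 2) + 1; cc <- (q - 1) %/% (H + 2) + 1
        if (r == 1 || r == H + 2 || cc == 1 || cc == W + 2) next
        p <- c(img[r - 1, cc], img[r - 1, cc + 1], img[r, cc + 1],
               img[r + 1, cc + 1], img[r + 1, cc], img[r + 1, cc - 1],
               img[r, cc - 1], img[r - 1, cc - 1])
        B <- sum(p)
        if (B < 2 || B > 6) next
        A <- sum(p == 0L & c(p[-1], p[1]) == 1L)
        if (A != 1) next
        if (step == 1) {
          if (p[1] * p[3] * p[5] != 0 || p[3] * p[5] * p[7] != 0) next
        } else {
          if (p[1] * p[3] * p[7] != 0 || p[1] * p[5] * p[7] != 0) next
        }
        del <- c(del, q)
      }
      if (length(del)) { img[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img[2:(H + 1), 2:(W + 1)]
}

# reproducible random blob mask: rectangles, ellipses and salt noise
random_blob_mask <- function(seed, H = 64, W = 64) {
  set.seed(seed)
  m <- matrix(0L, H, W)
  for (i in seq_len(sample(2:5, 1))) {
    r0 <- sample(seq_len(H - 8), 1); c0 <- sample(seq_len(W - 8), 1)
    m[r0:(r0 + sample(3:8, 1)), c0:(c0 + sample(3:8, 1))] <- 1L
  }
  for (i in seq_len(sample(2:4, 1))) {
    cy <- runif(1, 8, H - 8); cx <- runif(1, 8, W - 8)
    a <- runif(1, 3, 9); b <- runif(1, 2, 5); phi <- runif(1, 0, pi)
    for (r in max(1, floor(cy - a)):min(H, ceiling(cy + a)))
      for (cc in max(1, floor(cx - a)):min(W, ceiling(cx + a))) {
        x <- (cc - cx) * cos(phi) + (r - cy) * sin(phi)
        y <- -(cc - cx) * sin(phi) + (r - cy) * cos(phi)
        if ((x / a)^2 + (y / b)^2 <= 1) m[r, cc] <- 1L
      }
  }
  salt <- sample(H * W, sample(10:40, 1))
  m[salt] <- 1L
  m
}

# small default-geometry synthetic panicle for pipeline-level tests
quick_panicle <- function(seed = 1, n_grains = 100, ...) {
  render_panicle(synthetic_spec(n_grains = n_grains,
                                image_size = c(620, 877), seed = seed, ...))
}

quick_cfg <- function() scaled_preprocess_config(c(620, 877))
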
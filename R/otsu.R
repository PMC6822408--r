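#' Otsu threshold of an 8-bit grayscale image
#'
#' Exhaustive search over integer thresholds t = 0..254: the returned
#' threshold maximizes the between-class variance
#' \eqn{\sigma_b^2(t) = w_0 w_1 (\mu_0 - \mu_1)^2} of the split
#' \{gray <= t\} vs \{gray > t\}. Ties take the smallest t. The panicle is
#' bright on the black light-absorbing fabric, so the foreground mask is
#' `gray > t` (set `invert = TRUE` for dark objects on bright background).
#'
#' @param gray `H x W` integer matrix of gray levels in \[0, 255\].
#' @param invert if `TRUE`, foreground is `gray <= t`.
#' @return list with `threshold` (integer gray level) and `mask`
#'   (0/1 integer matrix).
#' @examples
#' g <- matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10)
#' otsu_threshold(g)$threshold
#' @export
otsu_threshold <- function(gray, invert = FALSE) {
  if (!is.matrix(gray)) stop("gray must be a matrix")
  storage.mode(gray) <- "integer"
  if (anyNA(gray) || min(gray) < 0L || max(gray) > 255L)
    stop("gray levels must be integers in [0, 255]")
  h <- tabulate(as.vector(gray) + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L) stop("degenerate histogram: image has a single gray level")
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)                    # pixels with gray <= t, t = 0..255
  m0 <- cumsum(h * lev)              # their gray-level sum
  tot <- m0[256]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0           # both classes non-empty
  mu0 <- m0 / w0
  mu1 <- (tot - m0) / w1
  sigma_b <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  sigma_b[!valid] <- -Inf
  t <- which.max(sigma_b) - 1L       # first argmax -> smallest threshold
  fg <- if (invert) gray <= t else gray > t
  list(threshold = t,
       mask = matrix(as.integer(fg), nrow = nrow(gray)))
}
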
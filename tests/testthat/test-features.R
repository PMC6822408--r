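test_that("split_branches returns one disjoint mask per component, union = input", {
  p <- render_panicle(synthetic_spec(n_grains = 60, n_branches = 7,
                                     shape = "C", image_size = c(620, 877),
                                     seed = 6))
  full <- matrix(as.integer(p$grain_mask | p$stem_mask), nrow(p$grain_mask))
  parts <- split_branches(full)
  expect_length(parts, 7)
  acc <- Reduce(`+`, parts)
  expect_true(max(acc) == 1L)            # pairwise disjoint
  expect_identical(matrix(as.integer(acc > 0), nrow(full)), full)
  blob <- matrix(0L, 6, 6); blob[2:4, 3:5] <- 1L
  expect_identical(split_branches(blob), list(blob))
  expect_length(split_branches(matrix(0L, 4, 4)), 0)
})

test_that("feature fractions follow their defining arithmetic", {
  m <- matrix(0L, 10, 10); m[3:7, 3:7] <- 1L
  fv <- compute_features(m, 100)
  expect_equal(fv$cd, 0.25)
  expect_equal(fv$n_cd, 25L)
  empty <- compute_features(matrix(0L, 10, 10), 100)
  expect_equal(c(empty$cd, empty$sk, empty$co), c(0, 0, 0))
  full <- compute_features(matrix(1L, 10, 10), 100)
  expect_equal(full$cd, 1)
  expect_equal(full$co, 36 / 100)
  expect_error(compute_features(m, 0), "positive")
})

test_that("feature chains Sk <= CD and Co <= CD hold, and branch sums equal whole-mask counts", {
  for (seed in c(3, 14, 25)) {
    p <- quick_panicle(seed = seed, n_grains = 70)
    res <- preprocess_image(p$image, quick_cfg())
    fv <- compute_features(res$stemless_mask, prod(dim(res$stemless_mask)))
    expect_lte(fv$sk, fv$cd)
    expect_lte(fv$co, fv$cd)
    # per-branch sums match whole-mask skeleton/contour counts
    expect_equal(fv$n_sk, sum(skeletonize(res$stemless_mask)))
    expect_equal(fv$n_co, sum(extract_contour(res$stemless_mask)))
    expect_equal(fv$n_cd, sum(res$stemless_mask))
  }
})

test_that("coverage grows with grain count", {
  cds <- vapply(c(60, 130, 200), function(ng) {
    p <- render_panicle(synthetic_spec(n_grains = ng, overlap_prob = 0,
                                       image_size = c(620, 877), seed = 31))
    compute_features(p$grain_mask, prod(dim(p$grain_mask)))$cd
  }, 0)
  expect_true(all(diff(cds) > 0))
})

test_that("min-max normalization maps training extremes to 0 and 1", {
  ft <- data.frame(cd = c(0.1, 0.3, 0.5), sk = c(0.01, 0.02, 0.04),
                   co = c(0.05, 0.06, 0.09))
  st <- fit_normalizer(ft)
  expect_equal(st$cd, c(0.1, 0.5))
  nf <- normalize_features(ft, st)
  expect_equal(nf$cd_n, c(0, 0.5, 1))
  expect_true(all(nf$sk_n >= 0 & nf$sk_n <= 1))
  # values outside the training range are not clamped
  out <- normalize_features(data.frame(cd = 0.7, sk = 0.05, co = 0.01), st)
  expect_gt(out$cd_n, 1)
  expect_lt(out$co_n, 0)
})

test_that("degenerate normalization inputs are refused", {
  expect_error(fit_normalizer(data.frame(cd = 0.2, sk = 0.1, co = 0.1)),
               "at least 2")
  ft <- data.frame(cd = c(0.2, 0.2), sk = c(0.1, 0.2), co = c(0.1, 0.2))
  expect_error(fit_normalizer(ft), "degenerate feature range")
})

test_that("norm stats survive a JSON round-trip", {
  ft <- data.frame(cd = c(0.1, 0.5), sk = c(0.01, 0.04), co = c(0.05, 0.09))
  st <- fit_normalizer(ft, group = "indica.scanner.C")
  f <- tempfile(fileext = ".json")
  write_norm_stats(st, f)
  st2 <- read_norm_stats(f)
  expect_equal(st2[c("cd", "sk", "co", "group")],
               st[c("cd", "sk", "co", "group")])
  unlink(f)
})
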
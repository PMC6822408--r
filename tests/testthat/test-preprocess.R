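test_that("stem removal recovers the stem and keeps the grains on synthetic panicles", {
  p <- render_panicle(synthetic_spec(n_grains = 90, stem_width = c(6, 6),
                                     grain_width = c(40, 40),
                                     image_size = c(620, 877), seed = 3))
  res <- preprocess_image(p$image, quick_cfg())
  stem_recovery <- sum(res$stem_mask & p$stem_mask) / sum(p$stem_mask)
  grain_retention <- sum(res$stemless_mask & p$grain_mask) / sum(p$grain_mask)
  expect_gte(stem_recovery, 0.90)
  expect_gte(grain_retention, 0.95)
})

test_that("opening leaves thick-only masks untouched and removes a thin line entirely", {
  thick <- matrix(0L, 60, 60)
  thick[5:30, 5:30] <- 1L; thick[40:55, 35:55] <- 1L
  st <- remove_stem(thick, preprocess_config())
  expect_equal(sum(st$stem), 0L)
  expect_identical(st$stemless, thick)
  # a 6-px line (area >= 200) is all residual, hence all stem
  line <- matrix(0L, 30, 120); line[13:18, 5:112] <- 1L
  st <- remove_stem(line, preprocess_config())
  expect_identical(st$stem, line)
  expect_equal(sum(st$stemless), 0L)
})

test_that("stem and stemless masks partition within the denoised mask", {
  for (seed in c(2, 9)) {
    p <- quick_panicle(seed = seed)
    res <- preprocess_image(p$image, quick_cfg())
    expect_equal(sum(res$stemless_mask & res$stem_mask), 0L)
    expect_true(all((res$stemless_mask | res$stem_mask) <= res$denoised_mask))
    expect_true(all(res$opened_mask <= res$denoised_mask))
  }
})

test_that("speckles below the area threshold never survive denoising", {
  p <- render_panicle(synthetic_spec(n_grains = 80, n_speckles = 25,
                                     image_size = c(620, 877), seed = 5))
  cfg <- quick_cfg()
  res <- preprocess_image(p$image, cfg)
  lab <- label_components(res$denoised_mask, cfg$connectivity)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    expect_true(all(areas >= cfg$denoise_min_area))
  }
  # everything kept belongs to the panicle, not the fabric speckles
  truth <- p$grain_mask | p$stem_mask
  expect_lt(sum(res$denoised_mask & !truth) / sum(res$denoised_mask), 0.02)
})

test_that("without stems or speckles the stemless mask is the raw mask up to opening residuals", {
  p <- render_panicle(synthetic_spec(n_grains = 70, stem_width = c(0, 0),
                                     n_speckles = 0, image_size = c(620, 877),
                                     seed = 8))
  res <- preprocess_image(p$image, quick_cfg())
  diff_frac <- sum(res$stemless_mask != res$raw_mask) / prod(dim(res$raw_mask))
  expect_lt(diff_frac, 0.01)
})

test_that("preprocessing is deterministic and the stem stage can be disabled", {
  p <- quick_panicle(seed = 13, n_grains = 60)
  cfg <- quick_cfg()
  r1 <- preprocess_image(p$image, cfg)
  r2 <- preprocess_image(p$image, cfg)
  expect_identical(r1[names(r1) != "config"], r2[names(r2) != "config"])
  cfg_off <- scaled_preprocess_config(c(620, 877), remove_stem = FALSE)
  r3 <- preprocess_image(p$image, cfg_off)
  expect_equal(sum(r3$stem_mask), 0L)
  expect_identical(r3$stemless_mask, r3$denoised_mask)
})

test_that("preprocess outputs can be written and reread", {
  p <- quick_panicle(seed = 4, n_grains = 50)
  res <- preprocess_image(p$image, quick_cfg())
  d <- tempfile()
  meta <- write_preprocess_result(res, d, "t")
  expect_true(file.exists(meta))
  expect_identical(read_mask(file.path(d, "t_stemless_mask.png")),
                   res$stemless_mask)
  js <- jsonlite::read_json(meta)
  expect_equal(js$otsu_threshold, res$otsu_threshold)
  unlink(d, recursive = TRUE)
})
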
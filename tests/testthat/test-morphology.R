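test_that("the 5x5 disk element is the 25-px window minus its corners", {
  k <- disk_kernel(5)
  expect_equal(dim(k), c(5L, 5L))
  expect_equal(sum(k), 21L)
  expect_equal(k[c(1, 5), c(1, 5)], matrix(0L, 2, 2))
  expect_true(all(k[2:4, ] == 1L) && all(k[, 2:4] == 1L))
  expect_error(disk_kernel(4), "odd")
})

test_that("erosion shrinks a solid square by the disk radius on every side", {
  sq <- matrix(1L, 50, 50)
  er <- erode_mask(sq, 5, 1)
  expected <- matrix(0L, 50, 50); expected[3:48, 3:48] <- 1L
  expect_identical(er, expected)
  expect_identical(erode_mask(sq, 5, 0), sq)
  # a 3-px-wide line is annihilated by the diameter-5 disk
  line <- matrix(0L, 20, 40); line[9:11, 3:38] <- 1L
  expect_equal(sum(erode_mask(line, 5, 1)), 0L)
})

test_that("dilating a single pixel reproduces the element footprint", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  di <- dilate_mask(m, 5, 1)
  expect_identical(di[3:7, 3:7], disk_kernel(5))
  expect_equal(sum(di), 21L)
  expect_equal(sum(dilate_mask(matrix(0L, 6, 6), 5, 2)), 0L)
})

test_that("erosion is anti-extensive, dilation extensive, opening idempotent", {
  for (seed in 1:8) {
    m <- random_blob_mask(seed)
    er <- erode_mask(m, 5, 1); di <- dilate_mask(m, 5, 1)
    expect_true(all(er <= m))
    expect_true(all(di >= m))
    op <- dilate_mask(er, 5, 1)
    expect_true(all(op <= m))  # opening anti-extensive
    op2 <- dilate_mask(erode_mask(op, 5, 1), 5, 1)
    expect_identical(op2, op)  # opening idempotent
  }
})

test_that("component filter keeps exactly the components at or above the area threshold", {
  m <- matrix(0L, 100, 100)
  m[2:4, 2:4] <- 1L            # area 9
  m[10:19, 30:49] <- 1L        # area 200
  m[50:89, 50:89] <- 1L        # area 1600
  out1000 <- remove_small_components(m, 1000)
  expect_equal(sum(out1000), 1600L)
  expect_true(all(out1000[50:89, 50:89] == 1L))
  out200 <- remove_small_components(m, 200)  # >= convention: 200 survives
  expect_equal(sum(out200), 1800L)
  expect_identical(remove_small_components(matrix(0L, 5, 5), 10),
                   matrix(0L, 5, 5))
})

test_that("component filter is idempotent and never adds foreground", {
  for (seed in 1:10) {
    m <- random_blob_mask(seed)
    f <- remove_small_components(m, 12)
    expect_true(sum(f) <= sum(m))
    expect_identical(remove_small_components(f, 12), f)
  }
})

test_that("labeling respects 4- vs 8-connectivity and matches EBImage on 4", {
  m <- matrix(0L, 5, 5); m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_equal(max(label_components(m, 8)), 1L)
  expect_equal(max(label_components(m, 4)), 2L)
  for (seed in 1:10) {
    m <- random_blob_mask(seed)
    lab4 <- label_components(m, 4)
    ref4 <- EBImage::bwlabel(m)
    expect_equal(max(lab4), max(ref4))
    # same partition: labels agree up to renaming
    expect_equal(length(unique(paste(lab4, ref4)[m == 1L])), max(lab4))
  }
})
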
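make_contrast_volume <- function(img) {
  root <- tempfile()
  spec <- make_image_volume(root, img, chunk_size = c(32, 32, 1))
  list(root = root, spec = spec)
}

test_that("full coverage sampling reproduces the whole-slice histogram", {
  img <- make_graded_image(c(64, 64, 3), noise = 0.4, seed = 71)
  v <- make_contrast_volume(img)
  sample_slice_histograms(v$root, v$spec, 0, coverage_fraction = 1.0)
  h <- jsonlite::read_json(file.path(v$root, "levels", "0", "1.json"),
                           simplifyVector = TRUE)
  expect_equal(h$counts, tabulate(as.vector(img[, , 2]) + 1, 256))
})

test_that("a constant slice samples into a single nonzero bin", {
  img <- array(123, c(64, 64, 1))
  v <- make_contrast_volume(img)
  sample_slice_histograms(v$root, v$spec, 0, coverage_fraction = 0.25)
  h <- jsonlite::read_json(file.path(v$root, "levels", "0", "0.json"),
                           simplifyVector = TRUE)
  expect_equal(sum(h$counts > 0), 1)
  expect_gt(h$counts[124], 0)
})

test_that("grid sampling of a checkerboard keeps both bins near-equal", {
  img <- array(0, c(64, 64, 1))
  img[, , 1] <- (outer(1:64, 1:64, "+") %% 2) * 255
  v <- make_contrast_volume(img)
  sample_slice_histograms(v$root, v$spec, 0, coverage_fraction = 0.25)
  h <- jsonlite::read_json(file.path(v$root, "levels", "0", "0.json"),
                           simplifyVector = TRUE)
  counts <- h$counts[c(1, 256)]
  expect_lt(abs(counts[1] - counts[2]) / sum(counts), 0.01)
  expect_error(sample_slice_histograms(v$root, v$spec, 0, 1.5),
               "coverage_fraction")
})

test_that("the two-value slice maps onto {127, 255}", {
  counts <- numeric(256)
  counts[51] <- 500   # value 50, half the mass
  counts[201] <- 500  # value 200, the other half
  lut <- chunkvol:::equalize_lut(counts, 0, 0)
  expect_equal(lut[51], 127)
  expect_equal(lut[201], 255)
})

test_that("equalization is monotone and idempotent within one grey level", {
  img <- make_graded_image(c(64, 64, 2), noise = 0.3, seed = 72)
  v <- make_contrast_volume(img)
  sample_slice_histograms(v$root, v$spec, 0, coverage_fraction = 1.0)
  equalize_slices(v$root, v$spec, 0, clip_low = 0, clip_high = 0)
  once <- read_region(v$root, v$spec, 0, bbox3(c(0, 0, 0), dim(img)))
  # monotone per slice
  for (z in 1:2) {
    o <- order(as.vector(img[, , z]))
    expect_true(all(diff(as.vector(once[, , z])[o]) >= 0))
  }
  # second application changes nothing beyond quantization
  sample_slice_histograms(v$root, v$spec, 0, coverage_fraction = 1.0)
  equalize_slices(v$root, v$spec, 0, clip_low = 0, clip_high = 0)
  twice <- read_region(v$root, v$spec, 0, bbox3(c(0, 0, 0), dim(img)))
  expect_true(all(abs(twice - once) <= 1))
})

test_that("an already-uniform slice is a fixed point within one grey level", {
  img <- array(rep(0:255, each = 16), c(64, 64, 1))
  v <- make_contrast_volume(img)
  sample_slice_histograms(v$root, v$spec, 0, coverage_fraction = 1.0)
  equalize_slices(v$root, v$spec, 0, clip_low = 0, clip_high = 0)
  out <- read_region(v$root, v$spec, 0, bbox3(c(0, 0, 0), dim(img)))
  expect_true(all(abs(out - img) <= 1))
})

test_that("tail clipping saturates outliers and rescales the remainder", {
  counts <- numeric(256)
  counts[1 + 0:199] <- 10      # ramp mass
  counts[256] <- 10            # 0.5% saturated-255 outliers
  lut <- chunkvol:::equalize_lut(counts, 0, 0.01)
  expect_equal(lut[256], 255)
  lut0 <- chunkvol:::equalize_lut(counts, 0, 0)
  # with the top tail clipped the ramp maps steeper (higher values sooner)
  expect_true(all(lut[1:200] >= lut0[1:200]))
  expect_error(chunkvol:::equalize_lut(counts, 0.6, 0.6), "clip")
})

test_that("chunked equalization equals whole-slice LUT application", {
  img <- make_graded_image(c(64, 64, 2), noise = 0.2, seed = 73)
  v <- make_contrast_volume(img)  # chunked 32x32x1: 8 chunks
  sample_slice_histograms(v$root, v$spec, 0, coverage_fraction = 1.0)
  equalize_slices(v$root, v$spec, 0, clip_low = 0.01, clip_high = 0.01)
  got <- read_region(v$root, v$spec, 0, bbox3(c(0, 0, 0), dim(img)))
  for (z in 1:2) {
    lut <- chunkvol:::equalize_lut(tabulate(as.vector(img[, , z]) + 1, 256),
                                   0.01, 0.01)
    expect_equal(got[, , z], array(lut[img[, , z] + 1], dim(img)[1:2]))
  }
})

test_that("a missing pass-1 histogram is an error", {
  img <- make_graded_image(c(32, 32, 2), seed = 74)
  v <- make_contrast_volume(img)
  sample_slice_histograms(v$root, v$spec, 0, 1.0)
  unlink(file.path(v$root, "levels", "0", "1.json"))
  expect_error(equalize_slices(v$root, v$spec, 0), "missing pass-1")
})

test_that("the integrated downsample emits corrected mips", {
  img <- make_graded_image(c(64, 64, 2), noise = 0.3, seed = 75)
  v <- make_contrast_volume(img)
  sample_slice_histograms(v$root, v$spec, 0, 1.0)
  equalize_slices(v$root, v$spec, 0, 0, 0, downsample_mips = 1)
  spec2 <- read_info(v$root)
  expect_equal(length(spec2$scales), 2)
  corrected <- read_region(v$root, spec2, 0, bbox3(c(0, 0, 0), dim(img)))
  mip1 <- read_region(v$root, spec2, 1, bbox3(c(0, 0, 0), c(32, 32, 2)))
  expect_equal(mip1, avg_pool_pyramid(corrected, c(2, 2, 1), 1)[[1]])
})
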
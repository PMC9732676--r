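test_that("constant images are fixed points of both pooling modes", {
  img <- array(7, c(16, 16, 8))
  for (mode in c("accumulate", "per_level")) {
    mips <- avg_pool_pyramid(img, c(2, 2, 2), 3, mode = mode)
    for (m in mips) expect_true(all(m == 7))
  }
})

test_that("per-level truncation loses what accumulate mode preserves", {
  # 2x2 block [0,1,1,1]: exact mean 0.75, truncated per-level mean 0
  blk <- array(c(0, 1, 1, 1), c(2, 2, 1))
  expect_equal(as.numeric(avg_pool_pyramid(blk, c(2, 2, 1), 1,
                                           "per_level")[[1]]), 0)
  expect_equal(as.numeric(avg_pool_pyramid(blk, c(2, 2, 1), 1,
                                           "accumulate")[[1]]), 0)
  # after two levels the accumulated sums keep the error under 1 grey level
  set.seed(41)
  img <- array(sample(0:255, 32 * 32 * 4, replace = TRUE), c(32, 32, 4))
  acc <- avg_pool_pyramid(img, c(2, 2, 1), 3, "accumulate")
  exact <- img
  for (k in 1:3) {
    exact <- chunkvol:::pool_sum(exact, c(2, 2, 1))
  }
  exact_mean <- exact / 4^3
  expect_true(all(abs(acc[[3]] - exact_mean) < 1))
})

test_that("brute-force enumeration reproduces the truncation loss bounds", {
  # all integer-residue 2x2 blocks: max per-level loss 0.75
  res2 <- expand.grid(a = 0:3, b = 0:3, c = 0:3, d = 0:3)
  loss2 <- with(res2, (a + b + c + d) / 4 - floor((a + b + c + d) / 4))
  expect_equal(max(loss2), 0.75)
  # all 2x2x2 blocks via the sum residue mod 8: max loss 0.875
  loss3 <- sapply(0:7, function(r) r / 8)
  expect_equal(max(loss3), 0.875)
  # at 10 mips the worst case accumulates linearly
  expect_equal(10 * max(loss2), 7.5)
  expect_equal(10 * max(loss3), 8.75)
})

test_that("adversarial fixtures approach the per-level loss bound", {
  # every 2x2 block holds {0,1,1,1}: each per_level mip loses 0.75
  img <- array(0, c(16, 16, 1))
  img[] <- 3
  img[seq(1, 16, 2), seq(1, 16, 2), 1] <- 0  # sum 3+3+3+0 = 9 -> mean 2.25
  pl <- avg_pool_pyramid(img, c(2, 2, 1), 2, "per_level")
  acc <- avg_pool_pyramid(img, c(2, 2, 1), 2, "accumulate")
  expect_true(all(pl[[1]] == 2))   # truncated from 2.25
  expect_true(all(acc[[1]] == 2))
  expect_true(all(acc[[2]] == 2))  # exact mean 2.25 floors to 2
})

test_that("mode pooling picks the majority label with a deterministic tie", {
  expect_equal(as.numeric(mode_pool_pyramid(array(5, c(2, 2, 1)),
                                            c(2, 2, 1), 1)[[1]]), 5)
  expect_equal(as.numeric(mode_pool_pyramid(array(c(1, 1, 2, 3), c(2, 2, 1)),
                                            c(2, 2, 1), 1)[[1]]), 1)
  # tie {1,1,2,2}: earliest modal value in flattened order wins
  expect_equal(as.numeric(mode_pool_pyramid(array(c(1, 1, 2, 2), c(2, 2, 1)),
                                            c(2, 2, 1), 1)[[1]]), 1)
  expect_equal(as.numeric(mode_pool_pyramid(array(c(2, 2, 1, 1), c(2, 2, 1)),
                                            c(2, 2, 1), 1)[[1]]), 2)
})

test_that("mode pooling never invents labels and is idempotent on constants", {
  set.seed(42)
  lab <- smooth_labels_fixture(c(24, 24, 12), n = 9)
  mips <- mode_pool_pyramid(lab, c(2, 2, 2), 3)
  for (m in mips) expect_true(all(unique(as.vector(m)) %in% unique(as.vector(lab))))
  const <- array(4, c(8, 8, 8))
  expect_true(all(mode_pool_pyramid(const, c(2, 2, 2), 2)[[2]] == 4))
})

test_that("sparse pooling averages nonzero members only", {
  expect_equal(as.numeric(sparse_avg_pool(array(0, c(2, 2, 1)), c(2, 2, 1))), 0)
  expect_equal(as.numeric(sparse_avg_pool(array(c(0, 0, 100, 102), c(2, 2, 1)),
                                          c(2, 2, 1))), 101)
  img <- array(sample(1:255, 64, replace = TRUE), c(4, 4, 4))  # no zeros
  expect_equal(sparse_avg_pool(img, c(2, 2, 2)),
               avg_pool_pyramid(img, c(2, 2, 2), 1, "accumulate")[[1]])
})

test_that("pyramid storage overhead converges to 1/3 and 1/7", {
  img <- make_graded_image(c(512, 512, 64), noise = 0.05, seed = 2)
  bytes0 <- prod(dim(img))
  p221 <- avg_pool_pyramid(img, c(2, 2, 1), 9, "accumulate")
  over221 <- sum(vapply(p221, function(m) prod(dim(m)), numeric(1))) / bytes0
  expect_equal(round(100 * over221), 33)
  expect_equal(100 * prod(dim(p221[[1]])) / bytes0, 25)
  p222 <- avg_pool_pyramid(img, c(2, 2, 2), 6, "accumulate")
  over222 <- sum(vapply(p222, function(m) prod(dim(m)), numeric(1))) / bytes0
  expect_equal(round(100 * over222), 14)
  expect_equal(100 * prod(dim(p222[[1]])) / bytes0, 12.5)
})

test_that("downsample task planning clamps to the volume and runs in grid", {
  root <- withr::local_tempdir()
  sc <- scale_spec("k", c(8, 8, 40), c(1024, 1024, 8), c(64, 64, 8))
  spec <- volume_spec("uint8", "image", list(sc))
  tasks <- plan_downsample_tasks(root, spec, 0, 5, c(2, 2, 1))
  # 64 * 2^5 = 2048 exceeds the volume: a single clamped task
  expect_equal(length(tasks), 1)
  expect_equal(unlist(tasks[[1]]$payload$bbox_max), c(1024, 1024, 8))
  # empty volume: no tasks
  sc0 <- scale_spec("k", c(8, 8, 40), c(0, 0, 0), c(64, 64, 8))
  spec0 <- volume_spec("uint8", "image", list(sc0))
  expect_equal(length(plan_downsample_tasks(root, spec0, 0, 5)), 0)
})

test_that("superdownsampling matches one deep pyramid within 1 grey level", {
  img <- make_graded_image(c(128, 128, 4), noise = 0.3, seed = 3)
  root <- withr::local_tempdir()
  spec <- make_image_volume(root, img, chunk_size = c(32, 32, 4))
  reg <- default_registry()
  spec <- prepare_downsample_scales(root, 0, 3, c(2, 2, 1))
  for (t in plan_downsample_tasks(root, spec, 0, 3, c(2, 2, 1))) {
    reg$downsample(t$payload)
  }
  # superdownsample: re-plan with the top mip as the new source
  spec <- prepare_downsample_scales(root, 3, 2, c(2, 2, 1))
  for (t in plan_downsample_tasks(root, spec, 3, 2, c(2, 2, 1))) {
    reg$downsample(t$payload)
  }
  got <- read_region(root, spec, 5, bbox3(c(0, 0, 0), c(4, 4, 4)))
  deep <- avg_pool_pyramid(img, c(2, 2, 1), 5, "accumulate")[[5]]
  expect_true(all(abs(got - deep) <= 1))
})
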
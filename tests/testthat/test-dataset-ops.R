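seg_fixture <- function() smooth_labels_fixture(c(48, 48, 24), n = 10)

run_tasks <- function(tasks) {
  reg <- default_registry()
  for (t in tasks) reg[[t$kind]](t$payload)
}

test_that("identity transfers pass chunk files through byte-identically", {
  lab <- seg_fixture()
  src <- withr::local_tempdir(); dst <- withr::local_tempdir()
  spec <- make_seg_volume(src, lab, chunk_size = c(24, 24, 24),
                          encoding = "compresso")
  write_info(spec, dst)
  tasks <- plan_transfer(src, dst)
  expect_true(all(vapply(tasks, function(t) isTRUE(t$payload$passthrough),
                         logical(1))))
  run_tasks(tasks)
  sf <- list_chunk_files(src, spec, 0)
  expect_setequal(list_chunk_files(dst, spec, 0), sf)
  for (f in sf) {
    expect_identical(tools::md5sum(file.path(src, spec$scales[[1]]$key, f)),
                     tools::md5sum(file.path(dst, spec$scales[[1]]$key, f)),
                     ignore_attr = TRUE)
  }
})

test_that("re-chunk and re-encode transfers conserve every voxel", {
  lab <- seg_fixture()
  src <- withr::local_tempdir(); dst <- withr::local_tempdir()
  spec <- make_seg_volume(src, lab, chunk_size = c(16, 16, 8),
                          encoding = "raw")
  dsc <- scale_spec(spec$scales[[1]]$key, c(32, 32, 40), dim(lab),
                    c(24, 24, 24), encoding = "compressed_segmentation")
  dspec <- volume_spec("uint64", "segmentation", list(dsc))
  write_info(dspec, dst)
  tasks <- plan_transfer(src, dst)
  expect_false(any(vapply(tasks, function(t) isTRUE(t$payload$passthrough),
                          logical(1))))
  run_tasks(tasks)
  expect_equal(read_region(dst, dspec, 0, bbox3(c(0, 0, 0), dim(lab))), lab)
})

test_that("transfers can emit downsampled mips that match a direct run", {
  img <- make_graded_image(c(64, 64, 8), noise = 0.2, seed = 81)
  src <- withr::local_tempdir(); dst <- withr::local_tempdir()
  spec <- make_image_volume(src, img, chunk_size = c(16, 16, 8))
  dspec <- volume_spec("uint8", "image", list(spec$scales[[1]]))
  write_info(dspec, dst)
  dspec <- prepare_downsample_scales(dst, 0, 2, c(2, 2, 1))
  run_tasks(plan_transfer(src, dst, downsample_mips = 2))
  for (k in 1:2) {
    got <- read_region(dst, dspec, k,
                       scale_bounds(dspec$scales[[k + 1]]))
    expect_equal(got, avg_pool_pyramid(img, c(2, 2, 1), 2)[[k]])
  }
})

test_that("unsharded data aggregates into shards; reverse is unsupported", {
  lab <- seg_fixture()
  src <- withr::local_tempdir(); dst <- withr::local_tempdir()
  spec <- make_seg_volume(src, lab, chunk_size = c(24, 24, 24),
                          encoding = "raw")
  dsc <- scale_spec(spec$scales[[1]]$key, c(32, 32, 40), dim(lab),
                    c(24, 24, 24), encoding = "compresso",
                    sharding = sharding_params(0, 2, 1, hash_kind = "mixing"))
  dspec <- volume_spec("uint64", "segmentation", list(dsc))
  write_info(dspec, dst)
  run_tasks(plan_transfer(src, dst))
  expect_equal(read_region(dst, dspec, 0, bbox3(c(0, 0, 0), dim(lab))), lab)
  # sharded -> unsharded is an explicit unsupported operation
  back <- withr::local_tempdir()
  write_info(spec, back)
  expect_error(plan_transfer(dst, back), "unsupported")
  # sharded -> sharded re-encode conserves voxels too
  dst2 <- withr::local_tempdir()
  d2 <- scale_spec(spec$scales[[1]]$key, c(32, 32, 40), dim(lab),
                   c(24, 24, 24), encoding = "compressed_segmentation",
                   sharding = sharding_params(0, 1, 2))
  write_info(volume_spec("uint64", "segmentation", list(d2)), dst2)
  run_tasks(plan_transfer(dst, dst2))
  d2spec <- read_info(dst2)
  expect_equal(read_region(dst2, d2spec, 0, bbox3(c(0, 0, 0), dim(lab))), lab)
})

test_that("delete removes the default five mips above and is idempotent", {
  img <- make_graded_image(c(64, 64, 8), seed = 82)
  root <- withr::local_tempdir()
  make_image_volume(root, img, chunk_size = c(16, 16, 8))
  spec <- prepare_downsample_scales(root, 0, 6, c(2, 2, 1))
  run_tasks(plan_downsample_tasks(root, spec, 0, 6, c(2, 2, 1)))
  for (m in 0:6) expect_gt(length(list_chunk_files(root, spec, m)), 0)
  run_tasks(plan_delete(root, 0))  # default: this mip + five above
  for (m in 0:5) expect_equal(length(list_chunk_files(root, spec, m)), 0)
  expect_gt(length(list_chunk_files(root, spec, 6)), 0)
  # re-running deletes nothing and raises no error
  expect_no_error(run_tasks(plan_delete(root, 0)))
  expect_gt(length(list_chunk_files(root, spec, 6)), 0)
  # deleting an empty volume is a no-op
  empty <- withr::local_tempdir()
  sc0 <- scale_spec("k", c(8, 8, 40), c(0, 0, 0), c(16, 16, 8))
  write_info(volume_spec("uint8", "image", list(sc0)), empty)
  expect_equal(length(plan_delete(empty, 0)), 0)
})

test_that("label prefix buckets partition the label space", {
  labs <- 1:1000
  buckets <- vapply(labs, label_prefix_bucket, numeric(1), n_buckets = 10)
  expect_true(all(buckets >= 0 & buckets < 10))
  # every label in exactly one bucket; skewed prefixes still fully covered
  skew <- c(9, 90:99, 900:999)
  expect_true(all(vapply(skew, label_prefix_bucket, numeric(1), 10) == 9))
  tasks <- plan_label_prefix_tasks("mesh", tempfile(), 10)
  expect_equal(length(tasks), 10)
  expect_setequal(vapply(tasks, function(t) t$payload$bucket, numeric(1)), 0:9)
})

test_that("pipeline tasks are idempotent: re-execution rewrites same bytes", {
  lab <- seg_fixture()
  src <- withr::local_tempdir(); dst <- withr::local_tempdir()
  spec <- make_seg_volume(src, lab, chunk_size = c(24, 24, 24),
                          encoding = "compresso")
  spec <- prepare_downsample_scales(src, 0, 2, c(2, 2, 2))
  tasks <- c(plan_downsample_tasks(src, spec, 0, 2, c(2, 2, 2)),
             plan_mesh_tasks(src, spec, 0, c(24, 24, 24)))
  run_tasks(tasks)
  snap1 <- tree_digest(src)
  run_tasks(tasks)  # forced re-execution
  expect_identical(tree_digest(src), snap1)

  write_info(volume_spec("uint64", "segmentation", list(spec$scales[[1]])), dst)
  xfer <- plan_transfer(src, dst)
  run_tasks(xfer)
  s1 <- tree_digest(dst)
  run_tasks(xfer)
  expect_identical(tree_digest(dst), s1)
})
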
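test_that("the hand-built unit cube passes QC with volume 1", {
  cube <- unit_cube_mesh()
  qc <- mesh_qc(cube)
  expect_true(qc$watertight)
  expect_true(qc$consistent_winding)
  expect_equal(qc$volume, 1.0)
  expect_equal(qc$centroid, c(0.5, 0.5, 0.5))
  # removing a face breaks watertightness
  open_cube <- cube
  open_cube$triangles <- cube$triangles[-c(1, 2), ]
  expect_false(mesh_qc(open_cube)$watertight)
})

test_that("all-background chunks produce no fragments", {
  expect_equal(length(multilabel_marching_cubes(array(0, c(8, 8, 8)))), 0)
})

test_that("an interior solid cube meshes watertight, just under voxel volume", {
  chunk <- array(0, c(14, 14, 14))
  chunk[3:12, 3:12, 3:12] <- 1
  an <- c(8, 8, 40)
  frags <- multilabel_marching_cubes(chunk, an)
  expect_equal(names(frags), "1")
  qc <- mesh_qc(frags[["1"]])
  expect_true(qc$watertight)
  expect_true(qc$consistent_winding)
  expect_lt(qc$volume, 1000 * prod(an))  # corner cutting
  expect_gt(qc$volume, 0.85 * 1000 * prod(an))
})

test_that("single-pass multi-label output equals the per-label binary oracle", {
  set.seed(51)
  for (trial in 1:3) {
    lab <- array(sample(0:4, 12^3, replace = TRUE), c(12, 12, 12))
    an <- c(2, 2, 3)
    ml <- multilabel_marching_cubes(lab, an)
    expect_equal(sort(as.numeric(names(ml))),
                 setdiff(sort(unique(as.vector(lab))), 0))
    for (L in names(ml)) {
      oracle <- marching_cubes_binary(lab == as.numeric(L), an)
      expect_equal(mesh_canonical(ml[[L]]), mesh_canonical(oracle))
    }
  }
})

test_that("mesh task grids carry the one-voxel positive-face overlap", {
  root <- withr::local_tempdir()
  sc <- scale_spec("k", c(32, 32, 32), c(128, 128, 128), c(64, 64, 64))
  spec <- volume_spec("uint32", "segmentation", list(sc))
  tasks <- plan_mesh_tasks(root, spec, 0, c(64, 64, 64))
  expect_equal(length(tasks), 8)
  interior <- Filter(function(t) all(unlist(t$payload$bbox_min) == 0), tasks)
  expect_equal(unlist(interior[[1]]$payload$bbox_max), c(65, 65, 65))
  # single-task volumes get no overlap beyond bounds
  sc1 <- scale_spec("k", c(32, 32, 32), c(48, 48, 48), c(64, 64, 64))
  spec1 <- volume_spec("uint32", "segmentation", list(sc1))
  t1 <- plan_mesh_tasks(root, spec1, 0, c(64, 64, 64))
  expect_equal(length(t1), 1)
  expect_equal(unlist(t1[[1]]$payload$bbox_max), c(48, 48, 48))
})

test_that("fragments from adjacent tasks share exact boundary vertices", {
  vol <- array(0, c(24, 12, 12))
  vol[3:22, 5:9, 5:9] <- 1
  an <- c(16, 16, 40)
  fa <- multilabel_marching_cubes(vol[1:13, , ], an, offset = c(0, 0, 0))[["1"]]
  fb <- multilabel_marching_cubes(vol[13:24, , ], an, offset = c(12, 0, 0))[["1"]]
  ka <- paste(fa$vertices[, 1], fa$vertices[, 2], fa$vertices[, 3])
  kb <- paste(fb$vertices[, 1], fb$vertices[, 2], fb$vertices[, 3])
  shared <- intersect(ka, kb)
  expect_gt(length(shared), 0)
  # stitching: merged object is watertight with consistent winding
  merged <- merge_fragments(list(fa, fb))
  qc <- mesh_qc(merged)
  expect_true(qc$watertight)
  expect_true(qc$consistent_winding)
  # and the merged volume tracks the voxel volume within 10%
  expect_lt(abs(qc$volume - sum(vol) * prod(an)) / (sum(vol) * prod(an)), 0.1)
  # a single fragment merges to itself
  solo <- merge_fragments(list(fa))
  expect_equal(mesh_canonical(solo), mesh_canonical(fa))
})

test_that("mesh volume converges to voxel volume as objects grow", {
  ratios <- sapply(c(4, 8, 12), function(r) {
    b <- make_ball(r)
    qc <- mesh_qc(marching_cubes_binary(b$mask))
    qc$volume / sum(b$mask)
  })
  expect_true(all(diff(ratios) > 0))   # small objects underestimated most
  expect_gt(ratios[3], 0.95)
  expect_lt(ratios[3], 1.0)
})

test_that("simplification honors the target, the error bound and topology", {
  b <- make_ball(10)
  mesh <- marching_cubes_binary(b$mask, c(4, 4, 4))
  expect_identical(simplify_mesh(mesh, 1), mesh)  # factor 1: unchanged
  q0 <- mesh_qc(mesh)
  s4 <- simplify_mesh(mesh, 4, max_error_nm = 40)
  expect_lte(nrow(s4$triangles), nrow(mesh$triangles))
  q4 <- mesh_qc(s4)
  expect_true(q4$watertight)
  expect_true(q4$consistent_winding)
  expect_lt(abs(q4$volume - q0$volume) / q0$volume, 0.1)
  # the production QC settings: reduction factor 100, 40 nm error cap
  s100 <- simplify_mesh(mesh, 100, max_error_nm = 40)
  q100 <- mesh_qc(s100)
  expect_true(q100$watertight)
  expect_true(q100$consistent_winding)
})

test_that("mesh serialization round-trips and the manifest names fragments", {
  b <- make_ball(5)
  mesh <- marching_cubes_binary(b$mask, c(8, 8, 8))
  rt <- parse_mesh(serialize_mesh(mesh))
  expect_equal(rt$triangles, mesh$triangles)
  expect_equal(rt$vertices, mesh$vertices, tolerance = 1e-6)  # float32
  empty <- list(vertices = matrix(0, 0, 3), triangles = matrix(0L, 0, 3))
  ser <- serialize_mesh(empty)
  expect_equal(length(ser), 4)  # vertex count 0, no index section
  expect_equal(nrow(parse_mesh(ser)$vertices), 0)

  mdir <- withr::local_tempdir()
  write_mesh_manifest(mdir, 42, c("42:0:frag-a", "42:0:frag-b"))
  expect_true(file.exists(file.path(mdir, "42:0")))
  expect_equal(read_mesh_manifest(mdir, 42), c("42:0:frag-a", "42:0:frag-b"))
})
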
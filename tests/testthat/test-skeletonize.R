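test_that("anisotropic EDT matches a brute-force all-pairs oracle", {
  set.seed(61)
  lab <- array(sample(0:2, 8^3, replace = TRUE), c(8, 8, 8))
  an <- c(2, 2, 3)
  d <- anisotropic_edt(lab, an)
  pos <- sweep(which(array(TRUE, dim(lab)), arr.ind = TRUE), 2, an, "*")
  for (i in sample(length(lab), 40)) {
    if (lab[i] == 0) {
      expect_equal(d[i], 0)
    } else {
      diff_idx <- which(as.vector(lab) != lab[i])
      oracle <- min(sqrt(rowSums(sweep(pos[diff_idx, , drop = FALSE], 2,
                                       pos[i, ], "-")^2)))
      expect_equal(d[i], oracle)
    }
  }
})

test_that("EDT conventions: single voxel, slab, all-background", {
  one <- array(0, c(5, 5, 5)); one[3, 3, 3] <- 1
  expect_equal(anisotropic_edt(one, c(32, 32, 40))[3, 3, 3], 32)
  slab <- array(0, c(7, 7, 9)); slab[, , 3:7] <- 1
  expect_equal(anisotropic_edt(slab, c(1, 1, 1))[4, 4, 5], 3)
  expect_true(all(anisotropic_edt(array(0, c(6, 6, 6)), c(1, 1, 1)) == 0))
})

test_that("a circular disk component yields one target at its center", {
  ch <- array(0, c(17, 17, 6))
  idx <- which(array(TRUE, c(17, 17)), arr.ind = TRUE)
  disk <- (idx[, 1] - 9)^2 + (idx[, 2] - 9)^2 <= 36
  for (z in 1:6) ch[, , z][disk] <- 1
  bt <- border_targets(ch, "-z")
  expect_equal(nrow(bt), 1)
  expect_equal(c(bt$vx, bt$vy, bt$vz), c(9, 9, 1))
})

test_that("edge and corner contact produce two and three targets", {
  # a blob touching the (-x,-y) edge line of the box: visible on two faces
  v <- array(0, c(64, 64, 64))
  v[1:10, 1:10, 28:36] <- 1
  all_faces <- do.call(rbind, lapply(c("-x", "+x", "-y", "+y", "-z", "+z"),
                                     function(f) border_targets(v, f)))
  expect_equal(nrow(all_faces), 2)
  # touching the (-x,-y,-z) corner: three faces see it
  v2 <- array(0, c(64, 64, 64))
  v2[1:10, 1:10, 1:10] <- 1
  all2 <- do.call(rbind, lapply(c("-x", "+x", "-y", "+y", "-z", "+z"),
                                function(f) border_targets(v2, f)))
  expect_equal(nrow(all2), 3)
})

test_that("adjacent tasks choose the identical world voxel as target", {
  set.seed(62)
  vol <- array(0, c(40, 24, 24))
  vol[8:34, 6:18, 7:19] <- 1
  vol[10:30, 9:15, 10:16] <- 1  # irregular blob spanning the split
  # tasks split at x=20 with one-voxel overlap
  a <- vol[1:21, , ]
  b <- vol[21:40, , ]
  ta <- border_targets(a, "+x", c(1, 1, 1), offset = c(0, 0, 0))
  tb <- border_targets(b, "-x", c(1, 1, 1), offset = c(20, 0, 0))
  expect_equal(nrow(ta), nrow(tb))
  expect_equal(ta[, c("wx", "wy", "wz")], tb[, c("wx", "wy", "wz")])
})

test_that("a straight tube skeletonizes to one path of the right length", {
  ph <- make_tube_phantom(100, 3, orientation = 1)
  sks <- forge_skeletons(ph$mask * 1, c(1, 1, 1),
                         params = teasar_params(scale = 3, const = 2))
  sk <- merge_skeletons(sks[["1"]])
  expect_equal(skeleton_components(sk), 1)
  expect_equal(skeleton_cycles(sk), 0)
  expect_lt(abs(cable_length(sk) - 100) / 100, 0.05)
  # all vertices lie on foreground voxels
  vox <- round(sk$vertices) + 1
  expect_true(all(ph$mask[vox]))
})

test_that("empty masks and dust produce empty skeletons", {
  expect_equal(nrow(teasar(integer(0), c(4, 4, 4), numeric(0))$vertices), 0)
  ph <- make_tube_phantom(10, 2)
  sks <- forge_skeletons(ph$mask * 1, c(1, 1, 1),
                         params = teasar_params(dust_threshold = 1e6))
  expect_equal(length(sks), 0)
})

test_that("bulbous objects trip soma mode and radiate from the center", {
  b <- make_ball(14)
  p <- teasar_params(scale = 3, const = 1, soma_detect = 8, soma_accept = 12,
                     soma_scale = 1, soma_const = 4)
  sks <- forge_skeletons(b$mask * 1, c(1, 1, 1), params = p)
  sk <- sks[["1"]][[1]]
  expect_true(attr(sk, "soma"))
  expect_equal(sum(sk$vertex_types == 1), 1)
  root <- which(sk$vertex_types == 1)
  expect_equal(sk$vertices[root, ], b$center - 1, tolerance = 0.1)
  # paths radiate: the soma root has the highest radius
  expect_equal(which.max(sk$radii), root)
})

test_that("a tube split across two tasks merges into one acyclic component", {
  ph <- make_tube_phantom(60, 3, orientation = 1)
  vol <- ph$mask * 1
  nx <- dim(vol)[1]
  half <- floor(nx / 2)
  p <- teasar_params(scale = 3, const = 2)
  fa <- forge_skeletons(vol[1:(half + 1), , ], c(1, 1, 1),
                        offset = c(0, 0, 0), params = p)
  fb <- forge_skeletons(vol[(half + 1):nx, , ], c(1, 1, 1),
                        offset = c(half, 0, 0), params = p)
  frags <- c(fa[["1"]], fb[["1"]])
  merged <- merge_skeletons(frags, p)
  expect_equal(skeleton_components(merged), 1)
  expect_equal(skeleton_cycles(merged), 0)
  expect_lt(abs(cable_length(merged) - 60) / 60, 0.05)
  # the fragments met at a bit-identical border vertex
  ka <- do.call(paste, as.data.frame(do.call(rbind, lapply(fa[["1"]], `[[`, "vertices"))))
  kb <- do.call(paste, as.data.frame(do.call(rbind, lapply(fb[["1"]], `[[`, "vertices"))))
  expect_gt(length(intersect(ka, kb)), 0)
})

test_that("cycles from double targets are removed in post-processing", {
  # two fragments that share two fused vertices create a loop
  ring <- skeleton(
    vertices = rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)),
    edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
    radii = c(5, 5, 1, 3))
  merged <- merge_skeletons(list(ring))
  expect_equal(skeleton_cycles(merged), 0)
  expect_equal(nrow(merged$edges), 3)
  # the dropped edge is the thinnest (lowest mean endpoint radius): 3-4
  kept <- apply(merged$edges, 1, function(e) paste(sort(e), collapse = "-"))
  expect_false("3-4" %in% kept)
})

test_that("short terminal branches are pruned as ticks", {
  ph <- make_branching_phantom(arm = 24, radius = 2)
  p <- teasar_params(scale = 2, const = 2)
  sks <- forge_skeletons(ph$mask * 1, c(1, 1, 1), params = p)
  sk0 <- merge_skeletons(sks[["1"]], p)
  arms <- sum(ph$arm_lengths)
  expect_lt(abs(cable_length(sk0) - arms) / arms, 0.1)
  # an aggressive tick threshold prunes everything terminal at junctions
  pt <- teasar_params(scale = 2, const = 2, tick_threshold = 5)
  skt <- merge_skeletons(sks[["1"]], pt)
  expect_lte(cable_length(skt), cable_length(sk0))
  expect_equal(skeleton_cycles(skt), 0)
})

test_that("larger invalidation parameters give fewer or equal branches", {
  ph <- make_branching_phantom(arm = 20, radius = 3)
  branch_count <- function(const) {
    sks <- forge_skeletons(ph$mask * 1, c(1, 1, 1),
                           params = teasar_params(scale = 2, const = const))
    sk <- merge_skeletons(sks[["1"]])
    if (nrow(sk$edges) == 0) return(0)
    deg <- tabulate(as.vector(sk$edges), nrow(sk$vertices))
    sum(deg == 1)  # leaves ~ branch tips
  }
  expect_gte(branch_count(1), branch_count(20))
})

test_that("skeleton serialization round-trips and SWC rejects cycles", {
  expect_equal(nrow(parse_skeleton(serialize_skeleton(skeleton()))$vertices), 0)
  set.seed(63)
  sk <- skeleton(
    vertices = matrix(round(runif(30, 0, 1000), 2), 10, 3),
    edges = cbind(1:9, 2:10),
    radii = round(runif(10, 1, 50), 2),
    vertex_types = c(1L, rep(0L, 9)))
  rt <- parse_skeleton(serialize_skeleton(sk))
  expect_equal(rt$edges, sk$edges)
  expect_equal(rt$vertices, sk$vertices, tolerance = 1e-5)
  expect_equal(rt$radii, sk$radii, tolerance = 1e-5)
  expect_equal(rt$vertex_types, sk$vertex_types)

  swc <- swc_export(sk)
  expect_equal(length(swc), 10)
  # roots at the highest-radius vertex: exactly one parent of -1
  expect_equal(sum(grepl(" -1$", swc)), 1)

  cyc <- skeleton(vertices = matrix(runif(9), 3, 3),
                  edges = rbind(c(1, 2), c(2, 3), c(3, 1)),
                  radii = rep(1, 3))
  expect_error(swc_export(cyc), "cycle")
})

test_that("two vertices 100 nm apart have cable length 100", {
  sk <- skeleton(vertices = rbind(c(0, 0, 0), c(100, 0, 0)),
                 edges = matrix(c(1L, 2L), 1), radii = c(1, 1))
  expect_equal(cable_length(sk), 100)
})
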
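#' Synthetic volume generators
#'
#' Deterministic fixtures emulating the data the pipeline targets:
#' densely packed organic segmentation, wire-like neurites with known
#' centerlines, and graded microscopy images. All generators are seeded
#' and reproducible; every test in the package runs on them.
#'
#' `make_dense_labels()` produces a seeded nearest-seed (Voronoi) dense
#' labeling under the given anisotropy: every voxel is foreground and
#' labels are contiguous 1..n. Boundaries between cells are smooth
#' planes, the qualitative structure of packed cellular segmentation.
#'
#' @param shape 3-vector volume shape.
#' @param n_seeds number of Voronoi seeds (= labels).
#' @param anisotropy nm per voxel used for the distance metric.
#' @param seed RNG seed.
#' @return 3D label array.
#' @export
make_dense_labels <- function(shape, n_seeds, anisotropy = c(1, 1, 1),
                              seed = 1) {
  set.seed(seed)
  pts <- cbind(stats::runif(n_seeds, 1, shape[1]),
               stats::runif(n_seeds, 1, shape[2]),
               stats::runif(n_seeds, 1, shape[3]))
  pts <- sweep(pts, 2, anisotropy, "*")
  coords <- as.matrix(expand.grid(x = seq_len(shape[1]) * anisotropy[1],
                                  y = seq_len(shape[2]) * anisotropy[2],
                                  z = seq_len(shape[3]) * anisotropy[3]))
  lab <- numeric(nrow(coords))
  best <- rep(Inf, nrow(coords))
  for (s in seq_len(n_seeds)) {
    d2 <- (coords[, 1] - pts[s, 1])^2 + (coords[, 2] - pts[s, 2])^2 +
      (coords[, 3] - pts[s, 3])^2
    upd <- d2 < best
    lab[upd] <- s
    best[upd] <- d2[upd]
  }
  # relabel contiguously in case a seed captured no voxel
  lab <- match(lab, sort(unique(lab)))
  array(as.numeric(lab), shape)
}

#' Tube phantom with known centerline
#'
#' A straight axis-aligned cylinder; its centerline length, radius and
#' analytic volume are known, making it the ground truth for meshing and
#' skeletonization checks.
#'
#' @param length centerline length in voxels along `orientation`.
#' @param radius tube radius in voxels (isotropic frame).
#' @param orientation 1 (x), 2 (y) or 3 (z).
#' @param pad background margin around the tube, voxels.
#' @return list: `mask` (logical array), `start`/`end` centerline voxel
#'   coordinates (1-based), `radius`.
#' @export
make_tube_phantom <- function(length = 100, radius = 3, orientation = 1,
                              pad = 4) {
  rpad <- ceiling(radius) + pad
  cross_n <- 2 * rpad + 1
  shape <- rep(cross_n, 3)
  shape[orientation] <- length + 2 * pad
  ctr <- rpad + 1
  mask <- array(FALSE, shape)
  inplane <- setdiff(1:3, orientation)
  idx <- which(array(TRUE, shape), arr.ind = TRUE)
  r2 <- (idx[, inplane[1]] - ctr)^2 + (idx[, inplane[2]] - ctr)^2
  along <- idx[, orientation]
  mask[r2 <= radius^2 & along > pad & along <= pad + length] <- TRUE
  start <- rep(ctr, 3); start[orientation] <- pad + 1
  end <- rep(ctr, 3); end[orientation] <- pad + length
  list(mask = array(mask, shape), start = start, end = end, radius = radius)
}

#' Solid ball phantom
#'
#' @param r radius in voxels.
#' @param pad background margin, voxels.
#' @return list: `mask`, `center` (1-based voxel), `r`.
#' @export
make_ball <- function(r, pad = 2) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  xs <- seq_len(n) - ctr
  mask <- array(outer(outer(xs^2, xs^2, "+"), xs^2, "+") <= r^2, c(n, n, n))
  list(mask = mask, center = rep(ctr, 3), r = r)
}

#' Y-branching phantom
#'
#' Three straight arms of known length meeting at one junction: one arm
#' along -x and two diagonal arms in the xy plane.
#'
#' @param arm length of each arm in voxels.
#' @param radius tube radius in voxels.
#' @return list: `mask`, `junction` (1-based voxel), `arm_lengths` in
#'   voxel units.
#' @export
make_branching_phantom <- function(arm = 30, radius = 3, pad = 4) {
  n <- 2 * (arm + pad) + 1
  ctr <- arm + pad + 1
  shape <- c(n, n, 2 * (radius + pad) + 1)
  zc <- radius + pad + 1
  mask <- array(FALSE, shape)
  idx <- which(array(TRUE, shape), arr.ind = TRUE)
  seg_dist2 <- function(p0, p1) {
    d <- p1 - p0
    t <- ((idx[, 1] - p0[1]) * d[1] + (idx[, 2] - p0[2]) * d[2] +
          (idx[, 3] - p0[3]) * d[3]) / sum(d^2)
    t <- pmin(pmax(t, 0), 1)
    (idx[, 1] - p0[1] - t * d[1])^2 + (idx[, 2] - p0[2] - t * d[2])^2 +
      (idx[, 3] - p0[3] - t * d[3])^2
  }
  j <- c(ctr, ctr, zc)
  tips <- list(c(ctr - arm, ctr, zc),
               c(ctr + round(arm / sqrt(2)), ctr + round(arm / sqrt(2)), zc),
               c(ctr + round(arm / sqrt(2)), ctr - round(arm / sqrt(2)), zc))
  lens <- numeric(3)
  for (k in 1:3) {
    mask[seg_dist2(j, tips[[k]]) <= radius^2] <- TRUE
    lens[k] <- sqrt(sum((tips[[k]] - j)^2))
  }
  list(mask = array(mask, shape), junction = j, arm_lengths = lens)
}

#' Graded test image
#'
#' Smooth intensity gradient plus reproducible uniform noise, spanning
#' the full dynamic range of the dtype.
#'
#' @param shape 3-vector.
#' @param noise noise amplitude as a fraction of the range.
#' @param seed RNG seed.
#' @param data_type `"uint8"` or `"uint16"`.
#' @return 3D array of intensities.
#' @export
make_graded_image <- function(shape, noise = 0.1, seed = 1,
                              data_type = "uint8") {
  set.seed(seed)
  maxval <- 2^(8 * dtype_bytes(data_type)) - 1
  g <- array(0, shape)
  xs <- seq(0, 1, length.out = shape[1])
  ys <- seq(0, 1, length.out = shape[2])
  zs <- seq(0, 1, length.out = shape[3])
  base <- outer(outer(xs, ys, function(a, b) (a + b) / 2), zs,
                function(ab, c) (2 * ab + c) / 3)
  img <- base + noise * (array(stats::runif(prod(shape)), shape) - 0.5)
  round(pmin(pmax(img, 0), 1) * maxval)
}
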
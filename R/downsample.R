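#' Image pyramid pooling
#'
#' `avg_pool_pyramid()` builds mip levels by average pooling. In
#' `"accumulate"` mode integer sums are carried across every requested mip
#' and divided once per level (`floor(sum / count)`), so the error against
#' the exact real mean stays below one grey level at every mip. In
#' `"per_level"` mode each mip is recomputed from the previous one with
#' truncating division, which loses up to 0.75 grey levels per level under
#' 2x2 pooling and 0.875 under 2x2x2 — the pathology accumulate mode
#' exists to avoid.
#'
#' Odd-sized axes are handled by replicating the last row/column/slab so
#' edge averages stay unbiased.
#'
#' @param image 3D array of unsigned integer intensities.
#' @param factor per-axis pooling factor, `c(2,2,1)` or `c(2,2,2)`.
#' @param num_mips number of levels to generate (>= 1).
#' @param mode `"accumulate"` or `"per_level"`.
#' @return list of `num_mips` arrays; element k is mip k.
#' @export
avg_pool_pyramid <- function(image, factor = c(2, 2, 1), num_mips = 1,
                             mode = c("accumulate", "per_level")) {
  mode <- match.arg(mode)
  if (num_mips < 1) stop("num_mips must be >= 1")
  out <- vector("list", num_mips)
  if (mode == "accumulate") {
    sums <- image
    count <- 1
    for (k in seq_len(num_mips)) {
      sums <- pool_sum(sums, factor)
      count <- count * prod(factor)
      out[[k]] <- floor(sums / count)
    }
  } else {
    prev <- image
    for (k in seq_len(num_mips)) {
      prev <- floor(pool_sum(prev, factor) / prod(factor))
      out[[k]] <- prev
    }
  }
  out
}

# sum over pooling blocks with edge replication on odd axes
pool_sum <- function(a, factor) {
  dims <- dim(a)
  for (ax in 1:3) {
    f <- factor[ax]
    if (f == 1) next
    n <- dim(a)[ax]
    pad <- (f - n %% f) %% f
    if (pad > 0) {
      idx <- c(seq_len(n), rep(n, pad))
      a <- index_axis(a, ax, idx)
    }
    a <- sum_axis(a, ax, f)
  }
  a
}

index_axis <- function(a, ax, idx) {
  switch(ax,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# collapse groups of f consecutive planes along axis ax by summation
sum_axis <- function(a, ax, f) {
  d <- dim(a)
  n_out <- d[ax] %/% f
  out <- index_axis(a, ax, seq(1, by = f, length.out = n_out))
  for (j in 2:f) {
    out <- out + index_axis(a, ax, seq(j, by = f, length.out = n_out))
  }
  out
}

#' Mode pooling for segmentation pyramids
#'
#' Each output voxel is the most frequent label of its pooling block;
#' further mips are mode pools of the previous mip (recursive mode
#' pooling). Ties break to the modal label whose first occurrence in the
#' block's flattened x-fastest order is earliest, which keeps the rule
#' deterministic. Output label sets are always subsets of the input's.
#'
#' @param labels 3D label array.
#' @inheritParams avg_pool_pyramid
#' @export
mode_pool_pyramid <- function(labels, factor = c(2, 2, 1), num_mips = 1) {
  if (num_mips < 1) stop("num_mips must be >= 1")
  out <- vector("list", num_mips)
  prev <- labels
  for (k in seq_len(num_mips)) {
    prev <- mode_pool(prev, factor)
    out[[k]] <- prev
  }
  out
}

mode_pool <- function(a, factor) {
  dims <- dim(a)
  n_out <- ceiling(dims / factor)
  # replicate edges so every block is full
  for (ax in 1:3) {
    f <- factor[ax]
    n <- dim(a)[ax]
    pad <- (f - n %% f) %% f
    if (pad > 0) a <- index_axis(a, ax, c(seq_len(n), rep(n, pad)))
  }
  d <- dim(a)
  # gather each block as a row: members ordered by flattened x-fastest
  # position inside the block (the tie-break order)
  blockvol <- prod(factor)
  members <- matrix(0, prod(n_out), blockvol)
  m <- 1L
  for (dz in seq_len(factor[3])) {
    for (dy in seq_len(factor[2])) {
      for (dx in seq_len(factor[1])) {
        members[, m] <- as.vector(a[seq(dx, d[1], by = factor[1]),
                                    seq(dy, d[2], by = factor[2]),
                                    seq(dz, d[3], by = factor[3])])
        m <- m + 1L
      }
    }
  }
  # per block, count each member's multiplicity by pairwise comparison
  # (blocks are tiny: <= 8 members), then take the modal value whose first
  # occurrence in flattened order is earliest
  counts <- matrix(0L, nrow(members), blockvol)
  for (j in seq_len(blockvol)) {
    for (k in seq_len(blockvol)) {
      counts[, j] <- counts[, j] + (members[, k] == members[, j])
    }
  }
  best <- max.col(counts, ties.method = "first")
  array(members[cbind(seq_len(nrow(members)), best)], n_out)
}

#' Sparse average pooling
#'
#' Averages only the nonzero members of each pooling block (zeros are
#' treated as missing data, as when countless background voxels would
#' otherwise dilute a sparse signal); an all-zero block stays 0.
#'
#' @inheritParams avg_pool_pyramid
#' @export
sparse_avg_pool <- function(image, factor = c(2, 2, 1)) {
  sums <- pool_sum(image, factor)
  counts <- pool_sum((image != 0) * 1, factor)
  out <- sums
  nz <- counts > 0
  out[nz] <- floor(sums[nz] / counts[nz])
  out[!nz] <- 0
  out
}

#' Plan downsample tasks over a chunked volume
#'
#' Divides the source mip into grid tasks whose regions are divisible by
#' `factor^mips_per_task` (edge tasks truncated at volume bounds), each
#' emitting `mips_per_task` levels in one accumulate-mode pass.
#' Superdownsampling re-runs planning with a previously generated top mip
#' as the new source. Sharded source scales are restricted to one mip per
#' task.
#'
#' @param root dataset root (carried into the task payloads).
#' @param spec a [volume_spec()].
#' @param mip source mip.
#' @param mips_per_task levels per task (default 5).
#' @param factor per-level downsample factor.
#' @param sparse use sparse average pooling (images only).
#' @return list of [task_record()]s of kind `"downsample"`.
#' @export
plan_downsample_tasks <- function(root, spec, mip, mips_per_task = 5,
                                  factor = c(2, 2, 1), sparse = FALSE) {
  scale <- mip_scale(spec, mip)
  if (!is.null(scale$sharding)) mips_per_task <- 1
  if (any(scale$size == 0)) return(list())
  if (all(ceiling(scale$size / factor) == scale$size)) {
    stop("requesting mips beyond 1-voxel extent")
  }
  # task regions are chunk-aligned at every emitted mip: an integral
  # multiple of chunk_size * factor^mips_per_task, truncated at edges
  step <- scale$chunk_size * factor^mips_per_task
  bounds <- scale_bounds(scale)
  tasks <- list()
  for (cb in grid_chunks(bounds, step, scale$voxel_offset, bounds)) {
    tasks[[length(tasks) + 1L]] <- task_record(
      kind = "downsample",
      payload = list(root = root, mip = mip,
                     bbox_min = cb$minpt, bbox_max = cb$maxpt,
                     num_mips = mips_per_task, factor = factor,
                     sparse = sparse))
  }
  tasks
}
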
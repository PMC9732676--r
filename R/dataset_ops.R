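#' Plan a transfer (re-chunk / re-encode / downsample-on-the-fly)
#'
#' Divides the destination into grid tasks sized an integral multiple of
#' the destination chunk size. When source and destination agree on chunk
#' size and encoding, neither is sharded and no downsample is requested,
#' tasks degrade to byte-level file copies (pass-through) — detection is
#' conservative and triggers only when copying is provably safe.
#'
#' @param src_root,dst_root dataset roots. The destination info must
#'   exist (create it from the source spec, adjusted as desired).
#' @param mip source mip to transfer.
#' @param downsample_mips additional averaged/mode-pooled mips to emit
#'   while transferring.
#' @param chunks_per_task task edge length, in destination chunks.
#' @return list of [task_record()]s.
#' @export
plan_transfer <- function(src_root, dst_root, mip = 0, downsample_mips = 0,
                          chunks_per_task = 4) {
  src <- read_info(src_root)
  dst <- read_info(dst_root)
  ssc <- mip_scale(src, mip)
  dsc <- mip_scale(dst, mip)
  if (!is.null(ssc$sharding) && is.null(dsc$sharding)) {
    stop("unsupported operation: sharded to unsharded transfer")
  }
  if (!is.null(dsc$sharding)) {
    return(plan_sharded_transfer(src_root, dst_root, mip))
  }
  passthrough <- is.null(ssc$sharding) && is.null(dsc$sharding) &&
    all(ssc$chunk_size == dsc$chunk_size) &&
    identical(ssc$encoding, dsc$encoding) && downsample_mips == 0
  step <- dsc$chunk_size * chunks_per_task
  if (downsample_mips > 0) step <- step * 2^downsample_mips
  bounds <- scale_bounds(dsc)
  lapply(grid_chunks(bounds, step, dsc$voxel_offset, bounds), function(cb) {
    task_record("transfer", list(
      src_root = src_root, dst_root = dst_root, mip = mip,
      bbox_min = cb$minpt, bbox_max = cb$maxpt,
      passthrough = passthrough, downsample_mips = downsample_mips))
  })
}

#' Plan aggregation of an unsharded scale into shards
#'
#' One task per shard number: every chunk whose grid id routes to that
#' shard is read, encoded, and condensed into one write-once shard file.
#'
#' @inheritParams plan_transfer
#' @export
plan_sharded_transfer <- function(src_root, dst_root, mip = 0) {
  src <- read_info(src_root)
  dst <- read_info(dst_root)
  dsc <- mip_scale(dst, mip)
  if (is.null(dsc$sharding)) stop("destination scale has no sharding params")
  bounds <- scale_bounds(dsc)
  chunks <- grid_chunks(bounds, dsc$chunk_size, dsc$voxel_offset, bounds)
  shard_of <- vapply(chunks, function(cb) {
    shard_location(chunk_grid_id(cb, dsc), dsc$sharding)$shard
  }, numeric(1))
  lapply(unique(shard_of), function(s) {
    task_record("shard_aggregate", list(
      src_root = src_root, dst_root = dst_root, mip = mip, shard = s))
  })
}

#' Plan deletion of a scale's chunks
#'
#' Grid tasks that unlink chunk files; by default each task also deletes
#' the five mip levels above its own, so one pass removes a whole
#' pyramid branch. Idempotent: re-running deletes nothing and raises no
#' error. Higher mips beyond the window need a second ("superdelete")
#' pass.
#'
#' @param root dataset root.
#' @param mip lowest mip to delete.
#' @param superdelete_levels additional mips above `mip` deleted by the
#'   same tasks (default 5).
#' @param chunks_per_task task edge length in chunks.
#' @export
plan_delete <- function(root, mip = 0, superdelete_levels = 5,
                        chunks_per_task = 8) {
  spec <- read_info(root)
  scale <- mip_scale(spec, mip)
  if (any(scale$size == 0)) return(list())
  step <- scale$chunk_size * chunks_per_task
  bounds <- scale_bounds(scale)
  lapply(grid_chunks(bounds, step, scale$voxel_offset, bounds), function(cb) {
    task_record("delete", list(
      root = root, mip = mip, bbox_min = cb$minpt, bbox_max = cb$maxpt,
      levels = superdelete_levels))
  })
}

#' Plan label-prefix tasks over a mesh or skeleton directory
#'
#' Divides the label prefix space among tasks; every stored file whose
#' name starts with a label matches exactly one task's bucket (coverage
#' is the contract; balance is not).
#'
#' @param kind `"mesh"` or `"skeleton"`.
#' @param dir the mesh/skeleton directory.
#' @param n_buckets number of prefix buckets.
#' @param op operation name the executing handler dispatches on.
#' @export
plan_label_prefix_tasks <- function(kind = c("mesh", "skeleton"), dir,
                                    n_buckets = 10, op = "merge") {
  kind <- match.arg(kind)
  lapply(seq_len(n_buckets) - 1, function(b) {
    task_record(paste0(kind, "_prefix"), list(
      dir = dir, bucket = b, n_buckets = n_buckets, op = op))
  })
}

#' Which prefix bucket a label falls into
#'
#' Labels are distributed by their leading decimal digit sequence:
#' bucket = label's decimal string mapped through its first digits. The
#' same label always lands in the same single bucket.
#' @param label non-negative integer.
#' @param n_buckets bucket count.
#' @export
label_prefix_bucket <- function(label, n_buckets) {
  # leading digit striding: stable, total, single-bucket per label
  d <- as.numeric(substr(format_label(label), 1, 1))
  d %% n_buckets
}

# ---- task handlers --------------------------------------------------------

run_downsample_payload <- function(p) {
  root <- p$root
  spec <- read_info(root)
  bbox <- bbox3(unlist(p$bbox_min), unlist(p$bbox_max))
  src <- read_region(root, spec, p$mip, bbox)
  factor <- unlist(p$factor)
  layer <- spec$layer_kind
  n <- p$num_mips
  mips <- if (layer == "segmentation") {
    mode_pool_pyramid(src, factor, n)
  } else if (isTRUE(p$sparse)) {
    out <- list(); prev <- src
    for (k in seq_len(n)) { prev <- sparse_avg_pool(prev, factor); out[[k]] <- prev }
    out
  } else {
    avg_pool_pyramid(src, factor, n, mode = "accumulate")
  }
  for (k in seq_len(n)) {
    dmip <- p$mip + k
    if (dmip >= length(spec$scales)) break
    dsc <- mip_scale(spec, dmip)
    f <- factor^k
    lo <- bbox$minpt %/% f
    hi <- pmin(ceiling(bbox$maxpt / f), scale_bounds(dsc)$maxpt)
    write_region(root, spec, dmip, bbox3(lo, hi), mips[[k]])
  }
}

run_transfer_payload <- function(p) {
  src <- read_info(p$src_root)
  dst <- read_info(p$dst_root)
  bbox <- bbox3(unlist(p$bbox_min), unlist(p$bbox_max))
  ssc <- mip_scale(src, p$mip)
  dsc <- mip_scale(dst, p$mip)
  if (isTRUE(p$passthrough)) {
    bounds <- scale_bounds(ssc)
    dir.create(file.path(p$dst_root, dsc$key), recursive = TRUE,
               showWarnings = FALSE)
    for (cb in grid_chunks(bbox, ssc$chunk_size, ssc$voxel_offset, bounds)) {
      fname <- chunk_name(cb, ssc)
      for (f in c(fname, paste0(fname, ".gz"))) {
        sp <- file.path(p$src_root, ssc$key, f)
        if (file.exists(sp)) {
          file.copy(sp, file.path(p$dst_root, dsc$key, f), overwrite = TRUE)
        }
      }
    }
    return(invisible(NULL))
  }
  data <- read_region(p$src_root, src, p$mip, bbox)
  write_region(p$dst_root, dst, p$mip, bbox, data)
  nmips <- if (is.null(p$downsample_mips)) 0 else p$downsample_mips
  if (nmips > 0) {
    factor <- c(2, 2, 1)
    mips <- if (dst$layer_kind == "segmentation") {
      mode_pool_pyramid(data, factor, nmips)
    } else {
      avg_pool_pyramid(data, factor, nmips, mode = "accumulate")
    }
    for (k in seq_len(nmips)) {
      if (p$mip + k >= length(dst$scales)) break
      dk <- mip_scale(dst, p$mip + k)
      f <- factor^k
      lo <- bbox$minpt %/% f
      hi <- pmin(ceiling(bbox$maxpt / f), scale_bounds(dk)$maxpt)
      write_region(p$dst_root, dst, p$mip + k, bbox3(lo, hi), mips[[k]])
    }
  }
}

run_shard_aggregate_payload <- function(p) {
  src <- read_info(p$src_root)
  dst <- read_info(p$dst_root)
  dsc <- mip_scale(dst, p$mip)
  bounds <- scale_bounds(dsc)
  chunks <- grid_chunks(bounds, dsc$chunk_size, dsc$voxel_offset, bounds)
  entries <- list()
  for (cb in chunks) {
    label <- chunk_grid_id(cb, dsc)
    if (shard_location(label, dsc$sharding)$shard != p$shard) next
    data <- read_region(p$src_root, src, p$mip, cb)
    entries[[as.character(label)]] <-
      encode_chunk(data, dsc$encoding, dst$data_type)
  }
  dir.create(file.path(p$dst_root, dsc$key), recursive = TRUE,
             showWarnings = FALSE)
  writeBin(build_shard(entries, dsc$sharding),
           file.path(p$dst_root, dsc$key,
                     shard_filename(p$shard, dsc$sharding)))
}

run_delete_payload <- function(p) {
  spec <- read_info(p$root)
  bbox <- bbox3(unlist(p$bbox_min), unlist(p$bbox_max))
  for (k in 0:p$levels) {
    dmip <- p$mip + k
    if (dmip >= length(spec$scales)) break
    scale <- mip_scale(spec, dmip)
    f <- vapply(1:3, function(ax) {
      scale$resolution[ax] / mip_scale(spec, p$mip)$resolution[ax]
    }, numeric(1))
    lo <- bbox$minpt %/% f
    hi <- pmin(ceiling(bbox$maxpt / f), scale_bounds(scale)$maxpt)
    if (any(hi <= lo)) next
    bounds <- scale_bounds(scale)
    for (cb in grid_chunks(bbox3(lo, hi), scale$chunk_size,
                           scale$voxel_offset, bounds)) {
      fname <- chunk_name(cb, scale)
      unlink(file.path(p$root, scale$key, c(fname, paste0(fname, ".gz"))))
    }
  }
}

run_mesh_payload <- function(p) {
  spec <- read_info(p$root)
  scale <- mip_scale(spec, p$mip)
  bbox <- bbox3(unlist(p$bbox_min), unlist(p$bbox_max))
  chunk <- read_region(p$root, spec, p$mip, bbox)
  frags <- multilabel_marching_cubes(chunk, scale$resolution, bbox$minpt)
  mdir <- file.path(p$root, if (is.null(spec$mesh_dir)) "mesh" else spec$mesh_dir)
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  core <- bbox3(bbox$minpt, unlist(p$core_max))
  for (f in frags) {
    fname <- sprintf("%s:0:%s", format_label(f$label), format(core))
    writeBin(serialize_mesh(f), file.path(mdir, fname))
  }
}

run_mesh_merge_payload <- function(p) {
  mdir <- p$mesh_dir
  files <- list.files(mdir, pattern = paste0("^", p$label, ":0:"))
  frags <- lapply(files, function(f) {
    parse_mesh(readBin(file.path(mdir, f), "raw",
                       n = file.info(file.path(mdir, f))$size))
  })
  merged <- merge_fragments(frags)
  fname <- sprintf("%s:0:merged", p$label)
  writeBin(serialize_mesh(merged), file.path(mdir, fname))
  write_mesh_manifest(mdir, p$label, fname)
}

run_skeleton_payload <- function(p) {
  spec <- read_info(p$root)
  scale <- mip_scale(spec, p$mip)
  bbox <- bbox3(unlist(p$bbox_min), unlist(p$bbox_max))
  chunk <- read_region(p$root, spec, p$mip, bbox)
  params <- do.call(teasar_params, p$params)
  sks <- forge_skeletons(chunk, scale$resolution, bbox$minpt, params)
  sdir <- file.path(p$root,
                    if (is.null(spec$skeleton_dir)) "skeletons"
                    else spec$skeleton_dir)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  core <- bbox3(bbox$minpt, unlist(p$core_max))
  for (lab in names(sks)) {
    for (i in seq_along(sks[[lab]])) {
      fname <- sprintf("%s:%s:%d.frag", lab, format(core), i)
      writeBin(serialize_skeleton(sks[[lab]][[i]]), file.path(sdir, fname))
    }
  }
}

run_skeleton_merge_payload <- function(p) {
  sdir <- p$skeleton_dir
  files <- list.files(sdir, pattern = paste0("^", p$label, ":.*\\.frag$"))
  frags <- lapply(files, function(f) {
    parse_skeleton(readBin(file.path(sdir, f), "raw",
                           n = file.info(file.path(sdir, f))$size))
  })
  params <- do.call(teasar_params, p$params)
  vb <- if (is.null(p$volume_bounds_nm)) NULL else
    matrix(unlist(p$volume_bounds_nm), 2, 3, byrow = TRUE)
  merged <- merge_skeletons(frags, params, vb)
  writeBin(serialize_skeleton(merged), file.path(sdir, p$label))
}

#' The default task handler registry
#'
#' Maps every task kind this package plans to its executing function.
#' All handlers are idempotent: re-running a task rewrites the same
#' bytes.
#'
#' @return named list of `function(payload)` handlers.
#' @export
default_registry <- function() {
  list(
    downsample = run_downsample_payload,
    transfer = run_transfer_payload,
    shard_aggregate = run_shard_aggregate_payload,
    delete = run_delete_payload,
    mesh = run_mesh_payload,
    mesh_merge = run_mesh_merge_payload,
    skeleton = run_skeleton_payload,
    skeleton_merge = run_skeleton_merge_payload
  )
}

#' Prepare destination scales for a downsample run
#'
#' Appends `num_mips` scales to the info (no-op for scales that already
#' exist), so downsample tasks only ever write chunk data.
#'
#' @param root dataset root.
#' @param mip source mip.
#' @param num_mips levels to append.
#' @param factor per-level factor.
#' @export
prepare_downsample_scales <- function(root, mip, num_mips,
                                      factor = c(2, 2, 1)) {
  spec <- read_info(root)
  while (length(spec$scales) < mip + 1 + num_mips) {
    spec <- add_downsample_scale(spec, factor)
  }
  write_info(spec, root)
  invisible(spec)
}
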
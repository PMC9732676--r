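#' Read and write regions of a chunked volume
#'
#' `write_region()` renders a 3D array into the grid chunk files of an
#' unsharded scale; the bbox must be chunk-aligned (every chunk it touches
#' is fully covered, edge chunks excepted). `read_region()` reads any bbox
#' at any alignment, stitching and cropping the intersecting chunks, from
#' unsharded or sharded scales alike.
#'
#' Volumes are declared complete: a missing chunk is an error unless
#' `fill_missing = TRUE`, which substitutes background zeros.
#'
#' @param root dataset root directory.
#' @param spec a [volume_spec()].
#' @param mip 0-based mip level (index into `spec$scales`).
#' @param bbox region in world voxel coordinates of that mip ([bbox3()]).
#' @param data 3D array matching `bbox_size(bbox)`.
#' @param compress apply a second-stage gzip container, signaled by a
#'   `.gz` file suffix.
#' @param fill_missing treat absent chunks as zeros when reading.
#' @name region_io
NULL

mip_scale <- function(spec, mip) {
  if (mip < 0 || mip >= length(spec$scales)) {
    stop("mip ", mip, " not present (volume has ",
         length(spec$scales), " scales)")
  }
  spec$scales[[mip + 1]]
}

chunk_grid_id <- function(chunk_bbox, scale) {
  # linear grid index, x fastest: the label a chunk carries inside shards
  g <- (chunk_bbox$minpt - scale$voxel_offset) %/% scale$chunk_size
  ng <- ceiling(scale$size / scale$chunk_size)
  g[1] + ng[1] * (g[2] + ng[2] * g[3])
}

#' @rdname region_io
#' @export
write_region <- function(root, spec, mip, bbox, data, compress = FALSE) {
  scale <- mip_scale(spec, mip)
  if (!is.null(scale$sharding)) {
    stop("unsupported operation: sharded scales are random-read, not ",
         "random-write; build them with write_sharded_scale()")
  }
  stopifnot(all(dim(data) == bbox_size(bbox)))
  bounds <- scale_bounds(scale)
  if (!bbox_contains(bounds, bbox)) stop("bbox exceeds scale bounds")
  rel <- bbox$minpt - scale$voxel_offset
  if (any(rel %% scale$chunk_size != 0)) {
    stop("write_region: bbox must be chunk-aligned")
  }
  hi_ok <- bbox$maxpt == bounds$maxpt |
    (bbox$maxpt - scale$voxel_offset) %% scale$chunk_size == 0
  if (!all(hi_ok)) stop("write_region: bbox must be chunk-aligned")

  dir.create(file.path(root, scale$key), recursive = TRUE, showWarnings = FALSE)
  for (cb in grid_chunks(bbox, scale$chunk_size, scale$voxel_offset, bounds)) {
    lo <- cb$minpt - bbox$minpt
    sz <- bbox_size(cb)
    sub <- data[lo[1] + seq_len(sz[1]), lo[2] + seq_len(sz[2]),
                lo[3] + seq_len(sz[3]), drop = FALSE]
    bytes <- encode_chunk(sub, scale$encoding, spec$data_type)
    fname <- chunk_name(cb, scale)
    if (compress) {
      bytes <- memCompress(bytes, "gzip")
      fname <- paste0(fname, ".gz")
    }
    writeBin(bytes, file.path(root, scale$key, fname))
  }
  invisible(NULL)
}

read_chunk_file <- function(root, spec, scale, cb, fill_missing) {
  fname <- chunk_name(cb, scale)
  path <- file.path(root, scale$key, fname)
  gzpath <- paste0(path, ".gz")
  if (file.exists(path)) {
    bytes <- readBin(path, "raw", n = file.info(path)$size)
  } else if (file.exists(gzpath)) {
    bytes <- memDecompress(readBin(gzpath, "raw", n = file.info(gzpath)$size),
                           "gzip")
  } else if (fill_missing) {
    return(array(0, bbox_size(cb)))
  } else {
    stop("missing chunk ", fname, " in declared-complete volume at ",
         file.path(root, scale$key))
  }
  decode_chunk(bytes, scale$encoding, spec$data_type, bbox_size(cb))
}

read_chunk_sharded <- function(root, spec, scale, cb, fill_missing) {
  label <- chunk_grid_id(cb, scale)
  loc <- shard_location(label, scale$sharding)
  path <- file.path(root, scale$key, shard_filename(loc$shard, scale$sharding))
  if (!file.exists(path)) {
    if (fill_missing) return(array(0, bbox_size(cb)))
    stop("missing shard file ", path)
  }
  bytes <- read_shard_entry(file_range_reader(path), label, scale$sharding)
  if (is.null(bytes)) {
    if (fill_missing) return(array(0, bbox_size(cb)))
    stop("chunk ", format(cb), " absent from shard ", path)
  }
  decode_chunk(bytes, scale$encoding, spec$data_type, bbox_size(cb))
}

#' @rdname region_io
#' @export
read_region <- function(root, spec, mip, bbox, fill_missing = FALSE) {
  scale <- mip_scale(spec, mip)
  bounds <- scale_bounds(scale)
  if (!bbox_contains(bounds, bbox)) stop("bbox exceeds scale bounds")
  out <- array(0, bbox_size(bbox))
  for (cb in grid_chunks(bbox, scale$chunk_size, scale$voxel_offset, bounds)) {
    chunk <- if (is.null(scale$sharding)) {
      read_chunk_file(root, spec, scale, cb, fill_missing)
    } else {
      read_chunk_sharded(root, spec, scale, cb, fill_missing)
    }
    sect <- bbox_intersect(cb, bbox)
    src_lo <- sect$minpt - cb$minpt
    dst_lo <- sect$minpt - bbox$minpt
    sz <- bbox_size(sect)
    out[dst_lo[1] + seq_len(sz[1]), dst_lo[2] + seq_len(sz[2]),
        dst_lo[3] + seq_len(sz[3])] <-
      chunk[src_lo[1] + seq_len(sz[1]), src_lo[2] + seq_len(sz[2]),
            src_lo[3] + seq_len(sz[3]), drop = FALSE]
  }
  out
}

#' Build every shard file of a sharded scale from a full array
#'
#' Shards are write-once; this renders all grid chunks of `data`, routes
#' them by chunk grid id, and writes one shard file per occupied shard
#' number.
#'
#' @inheritParams region_io
#' @param data full-extent array of the scale.
#' @export
write_sharded_scale <- function(root, spec, mip, data) {
  scale <- mip_scale(spec, mip)
  if (is.null(scale$sharding)) stop("scale has no sharding params")
  stopifnot(all(dim(data) == scale$size))
  bounds <- scale_bounds(scale)
  chunks <- grid_chunks(bounds, scale$chunk_size, scale$voxel_offset, bounds)
  by_shard <- list()
  for (cb in chunks) {
    lo <- cb$minpt - scale$voxel_offset
    sz <- bbox_size(cb)
    sub <- data[lo[1] + seq_len(sz[1]), lo[2] + seq_len(sz[2]),
                lo[3] + seq_len(sz[3]), drop = FALSE]
    label <- chunk_grid_id(cb, scale)
    sh <- as.character(shard_location(label, scale$sharding)$shard)
    by_shard[[sh]] <- c(by_shard[[sh]],
                        stats::setNames(list(encode_chunk(sub, scale$encoding,
                                                          spec$data_type)),
                                        as.character(label)))
  }
  dir.create(file.path(root, scale$key), recursive = TRUE, showWarnings = FALSE)
  for (sh in names(by_shard)) {
    bytes <- build_shard(by_shard[[sh]], scale$sharding)
    writeBin(bytes,
             file.path(root, scale$key,
                       shard_filename(as.numeric(sh), scale$sharding)))
  }
  invisible(NULL)
}

#' List the chunk files of a scale
#'
#' @inheritParams region_io
#' @export
list_chunk_files <- function(root, spec, mip) {
  scale <- mip_scale(spec, mip)
  dir <- file.path(root, scale$key)
  if (!dir.exists(dir)) return(character(0))
  list.files(dir)
}
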
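#' Volume metadata (the Precomputed `info` file)
#'
#' A `volume_spec` mirrors the Precomputed info JSON: the voxel data type,
#' the layer kind (grayscale image or labeled segmentation) and an ordered
#' list of scales forming a resolution pyramid. `scales[[1]]` is mip 0, the
#' highest resolution; each further scale carries the cumulative downsample
#' in its resolution field.
#'
#' @param data_type one of `"uint8"`, `"uint16"`, `"uint32"`, `"uint64"`.
#' @param layer_kind `"image"` or `"segmentation"`.
#' @param scales list of [scale_spec()] objects, mip 0 first.
#' @param num_channels positive integer; only 1 is processed, larger values
#'   pass through untouched.
#' @param mesh_dir,skeleton_dir optional relative directory names advertised
#'   in the info file.
#' @return an object of class `volume_spec`.
#' @export
volume_spec <- function(data_type, layer_kind, scales,
                        num_channels = 1L,
                        mesh_dir = NULL, skeleton_dir = NULL) {
  spec <- structure(list(
    data_type = data_type,
    layer_kind = layer_kind,
    num_channels = as.integer(num_channels),
    scales = scales,
    mesh_dir = mesh_dir,
    skeleton_dir = skeleton_dir
  ), class = "volume_spec")
  validate_volume_spec(spec)
  spec
}

VALID_DTYPES <- c("uint8", "uint16", "uint32", "uint64")
IMAGE_ENCODINGS <- c("raw", "raw_deflate", "png", "jpeg")
SEG_ENCODINGS <- c("raw", "raw_deflate", "compressed_segmentation", "compresso")

dtype_bytes <- function(data_type) {
  switch(data_type,
         uint8 = 1L, uint16 = 2L, uint32 = 4L, uint64 = 8L,
         stop("unknown data_type: ", data_type))
}

#' One scale (mip level) of a volume
#'
#' @param key directory name of the scale, conventionally the resolution
#'   joined by underscores (e.g. `"32_32_40"`).
#' @param resolution nm-per-voxel 3-vector.
#' @param size volume extent in voxels at this scale.
#' @param chunk_size 3-vector chunk shape.
#' @param encoding chunk payload encoding; `png`/`jpeg` are legal only for
#'   image layers, `compressed_segmentation`/`compresso` only for
#'   segmentation layers. `raw_deflate` is raw wrapped in a gzip container.
#' @param voxel_offset 0-based origin of the voxel grid.
#' @param sharding optional [sharding_params()]; when present the scale is
#'   stored as write-once shard files instead of one file per chunk.
#' @export
scale_spec <- function(key, resolution, size, chunk_size,
                       encoding = "raw", voxel_offset = c(0, 0, 0),
                       sharding = NULL) {
  stopifnot(length(resolution) == 3, length(size) == 3,
            length(chunk_size) == 3, length(voxel_offset) == 3)
  if (any(size < 0)) stop("scale_spec: size components must be >= 0")
  if (any(chunk_size <= 0)) stop("scale_spec: chunk_size components must be positive")
  structure(list(
    key = as.character(key),
    resolution = as.numeric(resolution),
    size = as.numeric(size),
    chunk_size = as.numeric(chunk_size),
    encoding = encoding,
    voxel_offset = as.numeric(voxel_offset),
    sharding = sharding
  ), class = "scale_spec")
}

scale_bounds <- function(scale) {
  bbox3(scale$voxel_offset, scale$voxel_offset + scale$size)
}

validate_volume_spec <- function(spec) {
  if (!spec$data_type %in% VALID_DTYPES) {
    stop("invalid data_type: ", spec$data_type)
  }
  if (!spec$layer_kind %in% c("image", "segmentation")) {
    stop("invalid layer_kind: ", spec$layer_kind)
  }
  if (spec$num_channels < 1) stop("num_channels must be >= 1")
  if (length(spec$scales) < 1) stop("at least one scale required")
  legal <- if (spec$layer_kind == "image") IMAGE_ENCODINGS else SEG_ENCODINGS
  for (sc in spec$scales) {
    if (!inherits(sc, "scale_spec")) stop("scales must be scale_spec objects")
    if (!sc$encoding %in% legal) {
      stop(sprintf("encoding '%s' is not legal for layer_kind '%s'",
                   sc$encoding, spec$layer_kind))
    }
  }
  invisible(spec)
}

#' Append a downsampled scale to a spec
#'
#' The new scale's resolution is the source scale's resolution times
#' `factor`; its size is `ceiling(size / factor)` and its offset is the
#' source offset integer-divided by `factor` (grid-anchored).
#'
#' @param spec a `volume_spec`.
#' @param factor per-axis downsample factor of the new scale relative to the
#'   last existing scale.
#' @param chunk_size,encoding optional overrides; default to the source
#'   scale's values.
#' @return the `volume_spec` with one more scale.
#' @export
add_downsample_scale <- function(spec, factor, chunk_size = NULL, encoding = NULL) {
  src <- spec$scales[[length(spec$scales)]]
  res <- src$resolution * factor
  sc <- scale_spec(
    key = paste(format(res, trim = TRUE, scientific = FALSE), collapse = "_"),
    resolution = res,
    size = ceiling(src$size / factor),
    chunk_size = if (is.null(chunk_size)) src$chunk_size else chunk_size,
    encoding = if (is.null(encoding)) src$encoding else encoding,
    voxel_offset = floor(src$voxel_offset / factor)
  )
  spec$scales[[length(spec$scales) + 1L]] <- sc
  validate_volume_spec(spec)
  spec
}

#' Write / read the info JSON of a volume
#'
#' `write_info()` serializes a [volume_spec()] to `root/info`;
#' `read_info()` parses it back. The JSON follows the Precomputed field
#' names (`data_type`, `type`, `num_channels`, `scales`, `mesh`,
#' `skeletons`).
#'
#' @param spec a `volume_spec`.
#' @param root dataset root directory.
#' @export
write_info <- function(spec, root) {
  validate_volume_spec(spec)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  scales <- lapply(spec$scales, function(sc) {
    out <- list(
      key = sc$key,
      resolution = sc$resolution,
      size = sc$size,
      chunk_sizes = list(sc$chunk_size),
      encoding = sc$encoding,
      voxel_offset = sc$voxel_offset
    )
    if (!is.null(sc$sharding)) out$sharding <- unclass(sc$sharding)
    out
  })
  info <- list(
    type = spec$layer_kind,
    data_type = spec$data_type,
    num_channels = spec$num_channels,
    scales = scales
  )
  if (!is.null(spec$mesh_dir)) info$mesh <- spec$mesh_dir
  if (!is.null(spec$skeleton_dir)) info$skeletons <- spec$skeleton_dir
  jsonlite::write_json(info, file.path(root, "info"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @rdname write_info
#' @export
read_info <- function(root) {
  path <- file.path(root, "info")
  if (!file.exists(path)) stop("no info file at ", root)
  info <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  scales <- lapply(info$scales, function(sc) {
    sh <- NULL
    if (!is.null(sc$sharding)) {
      sh <- do.call(sharding_params, sc$sharding[
        names(sc$sharding) %in% names(formals(sharding_params))])
    }
    scale_spec(
      key = sc$key,
      resolution = sc$resolution,
      size = sc$size,
      chunk_size = as.numeric(unlist(sc$chunk_sizes))[1:3],
      encoding = sc$encoding,
      voxel_offset = if (is.null(sc$voxel_offset)) c(0, 0, 0) else sc$voxel_offset,
      sharding = sh
    )
  })
  volume_spec(
    data_type = info$data_type,
    layer_kind = info$type,
    scales = scales,
    num_channels = info$num_channels,
    mesh_dir = info$mesh,
    skeleton_dir = info$skeletons
  )
}

#' Canonical chunk filename for a grid-aligned bounding box
#'
#' Chunks are named by their half-open world extent,
#' `"x0-x1_y0-y1_z0-z1"`. The bbox must sit on the chunk grid anchored at
#' the scale's voxel offset; edge chunks may be truncated at the volume
#' bounds.
#'
#' @param bbox a grid-aligned `bbox3`.
#' @param scale the `scale_spec` the chunk belongs to.
#' @return the chunk filename (no directory part).
#' @export
chunk_name <- function(bbox, scale) {
  rel0 <- bbox$minpt - scale$voxel_offset
  if (any(rel0 %% scale$chunk_size != 0)) {
    stop("chunk_name: bbox ", format(bbox), " is not aligned to the chunk grid")
  }
  bounds <- scale_bounds(scale)
  expect_hi <- pmin(bbox$minpt + scale$chunk_size, bounds$maxpt)
  if (any(bbox$maxpt != expect_hi)) {
    stop("chunk_name: bbox ", format(bbox),
         " does not match the (possibly truncated) grid chunk extent")
  }
  format(bbox)
}
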
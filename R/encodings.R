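#' Encode / decode a chunk payload
#'
#' Chunk voxels travel in x-fastest (column-major) order, which is R's
#' native array order, so `raw` encoding is a straight dtype serialization.
#' `raw_deflate` wraps raw in a gzip container. `png` (8-bit image only)
#' and `jpeg` (8-bit image, lossy) stack the Z slices vertically into one
#' 2D image. `compressed_segmentation` and `compresso` are the
#' segmentation codecs from [seg_codecs].
#'
#' @param data 3D numeric array of unsigned integer voxel values.
#' @param encoding one of the scale encodings.
#' @param data_type voxel dtype string.
#' @return `encode_chunk`: raw vector. `decode_chunk`: 3D array of `dims`.
#' @export
encode_chunk <- function(data, encoding, data_type) {
  switch(encoding,
    raw = values_to_raw(as.vector(data), data_type),
    raw_deflate = memCompress(values_to_raw(as.vector(data), data_type), "gzip"),
    raw_brotli = stop("brotli second-stage compression is not available; ",
                      "use raw_deflate"),
    png = encode_png_chunk(data, data_type),
    jpeg = encode_jpeg_chunk(data, data_type),
    compressed_segmentation = cseg_encode(data, data_type = data_type),
    compresso = compresso_encode(data, data_type = data_type),
    stop("unknown encoding: ", encoding))
}

#' @rdname encode_chunk
#' @param bytes encoded payload.
#' @param dims expected chunk dims (x, y, z).
#' @export
decode_chunk <- function(bytes, encoding, data_type, dims) {
  out <- switch(encoding,
    raw = array(raw_to_values(bytes, data_type), dims),
    raw_deflate = array(raw_to_values(memDecompress(bytes, "gzip"), data_type), dims),
    png = decode_png_chunk(bytes, dims),
    jpeg = decode_jpeg_chunk(bytes, dims),
    compressed_segmentation = cseg_decode(bytes),
    compresso = compresso_decode(bytes),
    stop("unknown encoding: ", encoding))
  if (!identical(dim(out), as.integer(dims)) && !all(dim(out) == dims)) {
    stop("decoded chunk has dims ", paste(dim(out), collapse = "x"),
         ", expected ", paste(dims, collapse = "x"))
  }
  storage.mode(out) <- "double"
  out
}

encode_png_chunk <- function(data, data_type) {
  if (data_type != "uint8") {
    stop("png chunk encoding supports uint8 only")
  }
  dims <- dim(data)
  # stack z slices vertically: png matrices are [row = y, col = x]
  m <- matrix(0, dims[2] * dims[3], dims[1])
  for (z in seq_len(dims[3])) {
    m[(z - 1) * dims[2] + seq_len(dims[2]), ] <- t(data[, , z])
  }
  png::writePNG(m / 255)
}

decode_png_chunk <- function(bytes, dims) {
  m <- round(png::readPNG(bytes) * 255)
  out <- array(0, dims)
  for (z in seq_len(dims[3])) {
    out[, , z] <- t(m[(z - 1) * dims[2] + seq_len(dims[2]), , drop = FALSE])
  }
  out
}

encode_jpeg_chunk <- function(data, data_type, quality = 85) {
  if (data_type != "uint8") stop("jpeg chunk encoding supports uint8 only")
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("jpeg encoding requires the EBImage package")
  }
  dims <- dim(data)
  m <- matrix(0, dims[1], dims[2] * dims[3])  # EBImage grayscale is (x, y)
  for (z in seq_len(dims[3])) {
    m[, (z - 1) * dims[2] + seq_len(dims[2])] <- data[, , z]
  }
  f <- tempfile(fileext = ".jpg")
  on.exit(unlink(f))
  EBImage::writeImage(m / 255, f, quality = quality)
  readBin(f, "raw", n = file.info(f)$size)
}

decode_jpeg_chunk <- function(bytes, dims) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("jpeg decoding requires the EBImage package")
  }
  f <- tempfile(fileext = ".jpg")
  on.exit(unlink(f))
  writeBin(bytes, f)
  m <- round(EBImage::imageData(EBImage::readImage(f)) * 255)
  if (length(dim(m)) > 2) m <- m[, , 1]
  out <- array(0, dims)
  for (z in seq_len(dims[3])) {
    out[, , z] <- m[, (z - 1) * dims[2] + seq_len(dims[2])]
  }
  out
}
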
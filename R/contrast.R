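#' Pass 1: sample per-slice histograms
#'
#' Collects intensity histograms per Z slice from square patches laid on
#' a regular grid covering at least `coverage_fraction` of the slice
#' area (default 1%), and writes one JSON file per slice under
#' `root/levels/<mip>/<z>.json` recording the bin counts and the patch
#' geometry. Histograms have `2^bitdepth` bins.
#'
#' @param root dataset root.
#' @param spec a [volume_spec()] (8- or 16-bit image).
#' @param mip working mip.
#' @param coverage_fraction fraction of slice area to sample, in (0, 1].
#' @param patch_size square patch edge, voxels.
#' @return invisibly, the directory containing the JSONs.
#' @export
sample_slice_histograms <- function(root, spec, mip, coverage_fraction = 0.01,
                                    patch_size = 64) {
  if (coverage_fraction <= 0 || coverage_fraction > 1) {
    stop("coverage_fraction must be in (0, 1]")
  }
  if (!spec$data_type %in% c("uint8", "uint16")) {
    stop("contrast correction supports 8- and 16-bit images")
  }
  scale <- mip_scale(spec, mip)
  nx <- scale$size[1]; ny <- scale$size[2]; nz <- scale$size[3]
  patch <- pmin(patch_size, c(nx, ny))
  # grid spacing so that sampled area / slice area >= coverage_fraction
  n_needed <- max(1, ceiling(coverage_fraction * nx * ny / prod(patch)))
  gx <- max(1, round(sqrt(n_needed * nx / ny)))
  gy <- max(1, ceiling(n_needed / gx))
  x0 <- round(seq(0, nx - patch[1], length.out = gx))
  y0 <- round(seq(0, ny - patch[2], length.out = gy))
  nbins <- 2^(8 * dtype_bytes(spec$data_type))
  outdir <- file.path(root, "levels", mip)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  off <- scale$voxel_offset
  for (z in seq_len(nz) - 1) {
    counts <- numeric(nbins)
    for (px in unique(x0)) {
      for (py in unique(y0)) {
        bb <- bbox3(off + c(px, py, z), off + c(px + patch[1], py + patch[2], z + 1))
        vals <- read_region(root, spec, mip, bb)
        counts <- counts + tabulate(as.vector(vals) + 1, nbins)
      }
    }
    jsonlite::write_json(
      list(z = z, counts = counts, patch = patch,
           grid_x = x0, grid_y = y0, coverage = coverage_fraction),
      file.path(outdir, paste0(z + off[3], ".json")), digits = NA,
      auto_unbox = TRUE)
  }
  invisible(outdir)
}

# build the per-slice look-up table from a histogram with tail clipping:
# with F the normalized sample CDF, out(v) = floor((F(v) - clip_low) /
# (1 - clip_low - clip_high) * maxval) clamped to [0, maxval]; the
# clipped tails saturate at 0 / maxval
equalize_lut <- function(counts, clip_low, clip_high) {
  nbins <- length(counts)
  maxval <- nbins - 1
  total <- sum(counts)
  if (total == 0) return(seq_len(nbins) - 1)
  f <- cumsum(counts) / total
  span <- 1 - clip_low - clip_high
  if (span <= 0) stop("clip_low + clip_high must be < 1")
  lut <- floor((f - clip_low) / span * maxval)
  pmin(pmax(lut, 0), maxval)
}

#' Pass 2: per-slice histogram equalization
#'
#' Applies per-Z-slice histogram equalization with optional tail
#' clipping, using the pass-1 histogram JSONs. Each slice's mapping is
#' `out = round((CDF(v) - CDF_min) / (1 - CDF_min) * maxval)` over the
#' kept (unclipped) mass; clipped values saturate at 0 / maxval. Chunks
#' are processed independently (the mapping is a pure per-slice LUT, so
#' chunked application equals whole-slice application). An image pyramid
#' can be emitted from the corrected data in the same pass.
#'
#' @inheritParams sample_slice_histograms
#' @param clip_low,clip_high fractions of sampled mass clipped at each
#'   tail (default 0.01 each).
#' @param dst_root destination dataset root (defaults to rewriting in
#'   place).
#' @param downsample_mips number of averaged mips to emit from the
#'   corrected data.
#' @export
equalize_slices <- function(root, spec, mip, clip_low = 0.01,
                            clip_high = 0.01, dst_root = root,
                            downsample_mips = 0) {
  scale <- mip_scale(spec, mip)
  off <- scale$voxel_offset
  nz <- scale$size[3]
  luts <- vector("list", nz)
  for (z in seq_len(nz) - 1) {
    jpath <- file.path(root, "levels", mip, paste0(z + off[3], ".json"))
    if (!file.exists(jpath)) {
      stop("missing pass-1 histogram JSON for slice ", z + off[3])
    }
    h <- jsonlite::read_json(jpath, simplifyVector = TRUE)
    luts[[z + 1]] <- equalize_lut(h$counts, clip_low, clip_high)
  }
  if (!identical(dst_root, root)) write_info(spec, dst_root)
  bounds <- scale_bounds(scale)
  corrected <- NULL
  if (downsample_mips > 0) corrected <- array(0, scale$size)
  for (cb in grid_chunks(bounds, scale$chunk_size, off, bounds)) {
    chunk <- read_region(root, spec, mip, cb)
    for (zi in seq_len(dim(chunk)[3])) {
      z <- cb$minpt[3] - off[3] + zi
      chunk[, , zi] <- luts[[z]][chunk[, , zi] + 1]
    }
    write_region(dst_root, spec, mip, cb, chunk)
    if (!is.null(corrected)) {
      lo <- cb$minpt - off
      sz <- bbox_size(cb)
      corrected[lo[1] + seq_len(sz[1]), lo[2] + seq_len(sz[2]),
                lo[3] + seq_len(sz[3])] <- chunk
    }
  }
  if (downsample_mips > 0) {
    spec2 <- read_info(dst_root)
    mips <- avg_pool_pyramid(corrected, c(2, 2, 1), downsample_mips,
                             mode = "accumulate")
    for (k in seq_len(downsample_mips)) {
      spec2 <- add_downsample_scale(spec2, c(2, 2, 1))
      write_info(spec2, dst_root)
      sc <- spec2$scales[[length(spec2$scales)]]
      write_region(dst_root, spec2, length(spec2$scales) - 1,
                   scale_bounds(sc), mips[[k]])
    }
  }
  invisible(NULL)
}
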
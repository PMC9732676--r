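#' Axis-aligned 3D bounding box
#'
#' Half-open voxel bounding box `[minpt, maxpt)` in 0-based world voxel
#' coordinates. All grid arithmetic in the package goes through these
#' helpers so coordinate conventions live in one place.
#'
#' @param minpt,maxpt integer 3-vectors, `minpt <= maxpt` componentwise.
#' @return an object of class `bbox3`.
#' @export
bbox3 <- function(minpt, maxpt) {
  minpt <- as.numeric(minpt)
  maxpt <- as.numeric(maxpt)
  stopifnot(length(minpt) == 3, length(maxpt) == 3)
  if (any(maxpt < minpt)) {
    stop("bbox3: maxpt must be >= minpt componentwise")
  }
  structure(list(minpt = minpt, maxpt = maxpt), class = "bbox3")
}

#' @export
format.bbox3 <- function(x, ...) {
  sprintf("%d-%d_%d-%d_%d-%d",
          x$minpt[1], x$maxpt[1],
          x$minpt[2], x$maxpt[2],
          x$minpt[3], x$maxpt[3])
}

#' @export
print.bbox3 <- function(x, ...) {
  cat("<bbox3 ", format(x), ">\n", sep = "")
  invisible(x)
}

#' @rdname bbox3
#' @param bbox a `bbox3`.
#' @export
bbox_size <- function(bbox) bbox$maxpt - bbox$minpt

#' @rdname bbox3
#' @export
bbox_volume <- function(bbox) prod(bbox_size(bbox))

#' Intersect two bounding boxes
#'
#' @param a,b `bbox3` objects.
#' @return the intersection `bbox3`, or `NULL` if they do not overlap.
#' @export
bbox_intersect <- function(a, b) {
  lo <- pmax(a$minpt, b$minpt)
  hi <- pmin(a$maxpt, b$maxpt)
  if (any(hi <= lo)) return(NULL)
  bbox3(lo, hi)
}

bbox_contains <- function(outer, inner) {
  all(inner$minpt >= outer$minpt) && all(inner$maxpt <= outer$maxpt)
}

#' Enumerate grid-aligned chunks intersecting a bounding box
#'
#' The chunk grid is anchored at `offset` with spacing `chunk_size`; chunks
#' at the volume edge are truncated to `bounds`.
#'
#' @param bbox region of interest (`bbox3`).
#' @param chunk_size integer 3-vector grid spacing.
#' @param offset grid anchor (the scale's `voxel_offset`).
#' @param bounds full extent of the volume at this scale (`bbox3`).
#' @return list of `bbox3`, one per intersecting grid chunk.
#' @export
grid_chunks <- function(bbox, chunk_size, offset, bounds) {
  bbox <- bbox_intersect(bbox, bounds)
  if (is.null(bbox)) return(list())
  g0 <- floor((bbox$minpt - offset) / chunk_size)
  g1 <- ceiling((bbox$maxpt - offset) / chunk_size) - 1
  out <- list()
  for (gz in g0[3]:g1[3]) {
    for (gy in g0[2]:g1[2]) {
      for (gx in g0[1]:g1[1]) {
        lo <- offset + c(gx, gy, gz) * chunk_size
        hi <- pmin(lo + chunk_size, bounds$maxpt)
        out[[length(out) + 1L]] <- bbox3(lo, hi)
      }
    }
  }
  out
}
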
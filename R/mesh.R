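#' Mesh quality control
#'
#' Census of the mesh's edge incidence and orientation, plus
#' divergence-theorem volume and centroid. A mesh is watertight when
#' every undirected edge borders exactly two triangles, and consistently
#' wound when each shared edge is traversed in opposite directions by its
#' two triangles. For a watertight, consistently wound mesh the signed
#' volume is well-defined; positive means outward-facing normals.
#'
#' @param mesh list with `vertices` (n x 3 nm) and `triangles` (m x 3,
#'   1-based).
#' @return list: `watertight`, `consistent_winding`, `volume` (signed,
#'   nm^3), `centroid` (nm).
#' @export
mesh_qc <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (nrow(tr) == 0) {
    return(list(watertight = FALSE, consistent_winding = FALSE,
                volume = 0, centroid = c(NA, NA, NA)))
  }
  he_from <- c(tr[, 1], tr[, 2], tr[, 3])
  he_to <- c(tr[, 2], tr[, 3], tr[, 1])
  ekey <- paste(pmin(he_from, he_to), pmax(he_from, he_to))
  cnt <- table(ekey)
  watertight <- all(cnt == 2)
  # opposite traversal: each directed half-edge appears exactly once
  dkey <- paste(he_from, he_to)
  consistent <- watertight && !anyDuplicated(dkey) &&
    all(dkey %in% paste(he_to, he_from))
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  crossbc <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
                   b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
                   b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  svol <- sum(rowSums(a * crossbc)) / 6
  # centroid of the enclosed solid via the tetrahedron decomposition
  tet_vol <- rowSums(a * crossbc) / 6
  tet_cen <- (a + b + cc) / 4
  centroid <- if (abs(svol) > 0) colSums(tet_cen * tet_vol) / sum(tet_vol)
              else colMeans(v)
  list(watertight = watertight, consistent_winding = consistent,
       volume = svol, centroid = as.numeric(centroid))
}

#' Merge mesh fragments of one label
#'
#' Fragments produced under the one-voxel positive-face overlap convention
#' share bit-identical boundary vertices, so merging is concatenation,
#' exact-coordinate vertex dedup, triangle remap, and exact-duplicate
#' triangle removal. An object fully interior to the union of tasks is
#' watertight after merge.
#'
#' @param fragments list of mesh fragments (same label).
#' @return one merged mesh.
#' @export
merge_fragments <- function(fragments) {
  fragments <- fragments[vapply(fragments, function(f) nrow(f$triangles) > 0,
                                logical(1))]
  if (length(fragments) == 0) {
    return(list(vertices = matrix(0, 0, 3), triangles = matrix(0L, 0, 3)))
  }
  verts <- do.call(rbind, lapply(fragments, `[[`, "vertices"))
  offs <- cumsum(c(0, vapply(fragments, function(f) nrow(f$vertices),
                             numeric(1))))
  tris <- do.call(rbind, Map(function(f, o) f$triangles + o,
                             fragments, offs[-length(offs)]))
  key <- paste(verts[, 1], verts[, 2], verts[, 3])  # exact float equality
  ukey <- !duplicated(key)
  remap <- match(key, key[ukey])
  verts <- verts[ukey, , drop = FALSE]
  tris <- matrix(remap[tris], ncol = 3)
  tkey <- apply(tris, 1, function(t) paste(sort(t), collapse = " "))
  tris <- tris[!duplicated(tkey), , drop = FALSE]
  out <- list(vertices = verts, triangles = tris)
  if (!is.null(fragments[[1]]$label)) out$label <- fragments[[1]]$label
  out
}

#' Quadric edge-collapse simplification with a topological guard
#'
#' Iterative Garland–Heckbert quadric-error edge collapses. A candidate
#' collapse is rejected as unsound when it would (a) flip the normal of
#' any surviving incident triangle, (b) create an edge bordered by other
#' than two triangles in a closed mesh, or (c) exceed `max_error_nm`
#' of quadric error. Collapsing stops at `original / target_reduction_factor`
#' triangles or when no legal collapse remains; the triangle count never
#' increases.
#'
#' @param mesh mesh fragment.
#' @param target_reduction_factor divide the triangle count by this.
#' @param max_error_nm maximum allowed quadric error, in nm.
#' @param frozen_vertices indices of vertices that must not move
#'   (fragment-boundary vertices when simplifying before merge).
#' @return simplified mesh.
#' @export
simplify_mesh <- function(mesh, target_reduction_factor, max_error_nm = 40,
                          frozen_vertices = integer(0)) {
  if (target_reduction_factor <= 1 || nrow(mesh$triangles) == 0) return(mesh)
  v <- mesh$vertices
  tris <- mesh$triangles
  target <- max(4L, floor(nrow(tris) / target_reduction_factor))
  max_err2 <- max_error_nm^2
  frozen <- logical(nrow(v)); frozen[frozen_vertices] <- TRUE

  # per-vertex quadrics: sum of plane quadrics of incident triangles
  quadric_of <- function(tri_rows) {
    Q <- vector("list", nrow(v))
    a <- v[tri_rows[, 1], , drop = FALSE]
    b <- v[tri_rows[, 2], , drop = FALSE]
    cc <- v[tri_rows[, 3], , drop = FALSE]
    n <- cbind((b - a)[, 2] * (cc - a)[, 3] - (b - a)[, 3] * (cc - a)[, 2],
               (b - a)[, 3] * (cc - a)[, 1] - (b - a)[, 1] * (cc - a)[, 3],
               (b - a)[, 1] * (cc - a)[, 2] - (b - a)[, 2] * (cc - a)[, 1])
    len <- sqrt(rowSums(n^2))
    ok <- len > 0
    n[ok, ] <- n[ok, ] / len[ok]
    d <- -rowSums(n * a)
    for (t in which(ok)) {
      p <- c(n[t, ], d[t])
      K <- outer(p, p)
      for (vi in tri_rows[t, ]) {
        Q[[vi]] <- if (is.null(Q[[vi]])) K else Q[[vi]] + K
      }
    }
    Q
  }
  Q <- quadric_of(tris)
  for (i in seq_len(nrow(v))) if (is.null(Q[[i]])) Q[[i]] <- matrix(0, 4, 4)

  tri_alive <- rep(TRUE, nrow(tris))
  n_alive <- nrow(tris)
  vert_tris <- vector("list", nrow(v))
  for (t in seq_len(nrow(tris))) {
    for (vi in tris[t, ]) vert_tris[[vi]] <- c(vert_tris[[vi]], t)
  }

  qerr <- function(Qm, p) as.numeric(c(p, 1) %*% Qm %*% c(p, 1))
  tri_normal <- function(t) {
    a <- v[tris[t, 1], ]; b <- v[tris[t, 2], ]; cc <- v[tris[t, 3], ]
    cross3(b - a, cc - a)
  }

  progress <- TRUE
  while (n_alive > target && progress) {
    progress <- FALSE
    # candidate edges of live triangles, cheapest first
    live <- which(tri_alive)
    ef <- c(tris[live, 1], tris[live, 2], tris[live, 3])
    et <- c(tris[live, 2], tris[live, 3], tris[live, 1])
    eu <- pmin(ef, et); ev <- pmax(ef, et)
    keep <- !duplicated(paste(eu, ev)) & !frozen[eu] & !frozen[ev]
    eu <- eu[keep]; ev <- ev[keep]
    if (length(eu) == 0) break
    costs <- vapply(seq_along(eu), function(i) {
      Qe <- Q[[eu[i]]] + Q[[ev[i]]]
      min(qerr(Qe, v[eu[i], ]), qerr(Qe, v[ev[i], ]),
          qerr(Qe, (v[eu[i], ] + v[ev[i], ]) / 2))
    }, numeric(1))
    dirty <- logical(nrow(v))  # commit batches per sweep on stale costs
    for (i in order(costs)) {
      if (n_alive <= target) break
      if (costs[i] > max_err2) break
      a <- eu[i]; b <- ev[i]
      if (dirty[a] || dirty[b]) next
      ta <- vert_tris[[a]]; tb <- vert_tris[[b]]
      ta <- ta[tri_alive[ta]]; tb <- tb[tri_alive[tb]]
      if (length(ta) == 0 || length(tb) == 0) next
      shared <- intersect(ta, tb)
      if (length(shared) != 2) next  # non-manifold or boundary edge
      # link condition: vertices adjacent to both a and b must be exactly
      # the two opposite vertices of the shared triangles, else the
      # collapse pinches the surface
      nbr <- function(ts, x) setdiff(unique(as.vector(tris[ts, , drop = FALSE])), x)
      common <- intersect(nbr(ta, a), nbr(tb, b))
      opp <- setdiff(unique(as.vector(tris[shared, , drop = FALSE])), c(a, b))
      if (!setequal(common, opp)) next
      Qe <- Q[[a]] + Q[[b]]
      cand <- rbind(v[a, ], v[b, ], (v[a, ] + v[b, ]) / 2)
      errs <- apply(cand, 1, function(p) qerr(Qe, p))
      pos <- cand[which.min(errs), ]
      # normal-flip guard on surviving triangles
      surv <- setdiff(union(ta, tb), shared)
      flip <- FALSE
      old_v <- rbind(v[a, ], v[b, ])
      for (t in surv) {
        n0 <- tri_normal(t)
        va <- v[a, ]; vb <- v[b, ]
        v[a, ] <- pos; v[b, ] <- pos
        n1 <- tri_normal(t)
        v[a, ] <- va; v[b, ] <- vb
        if (sum(n0 * n1) <= 0) { flip <- TRUE; break }
      }
      if (flip) next
      # commit: b folds into a
      v[a, ] <- pos
      tri_alive[shared] <- FALSE
      n_alive <- n_alive - length(shared)
      for (t in tb) {
        if (!tri_alive[t]) next
        tris[t, ][tris[t, ] == b] <- a
      }
      vert_tris[[a]] <- union(surv, integer(0))
      vert_tris[[b]] <- integer(0)
      Q[[a]] <- Qe
      dirty[c(a, b, common)] <- TRUE
      progress <- TRUE
    }
  }
  live <- which(tri_alive)
  tr <- tris[live, , drop = FALSE]
  used <- sort(unique(as.vector(tr)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  out <- list(vertices = v[used, , drop = FALSE],
              triangles = matrix(remap[tr], ncol = 3))
  if (!is.null(mesh$label)) out$label <- mesh$label
  out
}

#' Plan meshing tasks over a grid
#'
#' Each task bbox is extended by one voxel on the +x, +y and +z faces
#' (clamped at volume bounds) so neighboring fragments share the voxels
#' that make their boundary vertices coincide.
#'
#' @param root dataset root (carried into the task payloads).
#' @param spec a [volume_spec()].
#' @param mip working mip (meshing normally runs at a near-isotropic mip).
#' @param task_shape 3-vector task size in voxels.
#' @return list of [task_record()]s of kind `"mesh"`.
#' @export
plan_mesh_tasks <- function(root, spec, mip, task_shape = c(64, 64, 64)) {
  scale <- mip_scale(spec, mip)
  bounds <- scale_bounds(scale)
  lapply(grid_chunks(bounds, task_shape, scale$voxel_offset, bounds),
         function(cb) {
           ext <- bbox3(cb$minpt, pmin(cb$maxpt + 1, bounds$maxpt))
           task_record("mesh", list(root = root, mip = mip,
                                    bbox_min = ext$minpt,
                                    bbox_max = ext$maxpt,
                                    core_max = cb$maxpt))
         })
}

#' Serialize a mesh fragment (single-resolution triangle soup)
#'
#' Binary layout: u32 vertex count, float32 x,y,z triples in nm, then
#' u32 vertex-index triples (0-based).
#'
#' @param mesh mesh fragment.
#' @return raw vector.
#' @export
serialize_mesh <- function(mesh) {
  nv <- nrow(mesh$vertices)
  c(u32_to_raw(nv),
    f32_to_raw(as.vector(t(mesh$vertices))),
    u32_to_raw(as.vector(t(mesh$triangles - 1L))))
}

#' @rdname serialize_mesh
#' @param bytes serialized fragment.
#' @export
parse_mesh <- function(bytes) {
  nv <- raw_to_u32(bytes[1:4])
  vend <- 4 + 12 * nv
  verts <- matrix(raw_to_f32(bytes[5:vend]), ncol = 3, byrow = TRUE)
  rest <- bytes[seq(vend + 1, length.out = length(bytes) - vend)]
  tris <- if (length(rest)) {
    matrix(raw_to_u32(rest) + 1L, ncol = 3, byrow = TRUE)
  } else matrix(0L, 0, 3)
  if (nv == 0) verts <- matrix(0, 0, 3)
  list(vertices = verts, triangles = tris)
}

#' Mesh manifests
#'
#' The fragments of a label are advertised by a manifest JSON at the
#' well-known filename `"<label>:0"`.
#'
#' @param mesh_dir mesh directory path.
#' @param label segment label.
#' @param fragment_names character vector of fragment filenames.
#' @export
write_mesh_manifest <- function(mesh_dir, label, fragment_names) {
  jsonlite::write_json(list(fragments = fragment_names),
                       file.path(mesh_dir, sprintf("%s:0", format_label(label))),
                       auto_unbox = FALSE, digits = NA)
  invisible(NULL)
}

#' @rdname write_mesh_manifest
#' @export
read_mesh_manifest <- function(mesh_dir, label) {
  jsonlite::read_json(file.path(mesh_dir, sprintf("%s:0", format_label(label))),
                      simplifyVector = TRUE)$fragments
}

format_label <- function(label) format(label, scientific = FALSE, trim = TRUE)
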
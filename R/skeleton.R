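#' TEASAR skeletonization parameters
#'
#' Controls path invalidation and soma handling. After each traced path,
#' all voxels within `scale * dbf(v) + const` nm of a path vertex `v` are
#' invalidated (a rolling ball along the path); larger values absorb more
#' side structure and yield fewer branches. Objects whose peak
#' distance-to-boundary reaches `soma_detect` are re-examined and, at
#' `soma_accept`, skeletonized in soma mode: the root moves to the
#' distance-field peak, the soma ball is invalidated with
#' `soma_scale`/`soma_const`, and paths radiate from the center.
#'
#' Defaults follow a parameterization proven on cortical segmentation at
#' 16-40 nm working resolutions.
#'
#' @param scale dimensionless multiplier of the local radius.
#' @param const additive invalidation radius, nm.
#' @param pdrf_exponent exponent of the penalty field.
#' @param soma_detect,soma_accept nm radius thresholds (accept >= detect).
#' @param soma_scale,soma_const soma-mode invalidation parameters.
#' @param dust_threshold minimum object size in voxels; smaller objects
#'   are skipped.
#' @param tick_threshold minimum terminal branch length in nm kept during
#'   post-processing (0 disables pruning).
#' @export
teasar_params <- function(scale = 3, const = 50, pdrf_exponent = 16,
                          soma_detect = 1100, soma_accept = 3500,
                          soma_scale = 1, soma_const = 300,
                          dust_threshold = 0, tick_threshold = 0) {
  stopifnot(scale >= 0, const >= 0, soma_accept >= soma_detect)
  structure(list(scale = scale, const = const, pdrf_exponent = pdrf_exponent,
                 soma_detect = soma_detect, soma_accept = soma_accept,
                 soma_scale = soma_scale, soma_const = soma_const,
                 dust_threshold = dust_threshold,
                 tick_threshold = tick_threshold),
            class = "teasar_params")
}

#' Skeleton objects
#'
#' An undirected vertex graph: `vertices` are nm positions, `edges`
#' 1-based index pairs, `radii` the distance-to-boundary at each vertex
#' and `vertex_types` a per-vertex byte (0 undefined, 1 soma).
#'
#' @param vertices n x 3 matrix (nm).
#' @param edges m x 2 matrix of 1-based vertex indices.
#' @param radii nm per vertex.
#' @param vertex_types integer per vertex.
#' @export
skeleton <- function(vertices = matrix(0, 0, 3),
                     edges = matrix(0L, 0, 2),
                     radii = numeric(nrow(vertices)),
                     vertex_types = integer(nrow(vertices))) {
  if (nrow(edges) > 0) {
    if (any(edges[, 1] == edges[, 2])) stop("skeleton: self-edge")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("skeleton: duplicate edge")
  }
  structure(list(vertices = vertices, edges = edges, radii = radii,
                 vertex_types = as.integer(vertex_types)),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton: %d vertices, %d edges, cable %.1f nm>\n",
              nrow(x$vertices), nrow(x$edges), cable_length(x)))
  invisible(x)
}

#' Total cable length of a skeleton
#'
#' Sum of the Euclidean lengths of all edges, in nm.
#' @param skel a [skeleton()].
#' @export
cable_length <- function(skel) {
  if (nrow(skel$edges) == 0) return(0)
  d <- skel$vertices[skel$edges[, 1], , drop = FALSE] -
    skel$vertices[skel$edges[, 2], , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

FACE_NAMES <- c("-x", "+x", "-y", "+y", "-z", "+z")

face_slice_index <- function(face, dims) {
  ax <- match(substr(face, 2, 2), c("x", "y", "z"))
  idx <- if (substr(face, 1, 1) == "-") 1 else dims[ax]
  list(axis = ax, index = idx)
}

#' Deterministic border targets on a task face
#'
#' For each 2D 4-connected component of each label's cross-section on a
#' task face, the target is the peak of the component's 2D distance
#' transform. Ties are broken in precedence order: closest to the
#' component centroid, then to the face center, then to the image
#' corners, then to the image edge — all mirror-invariant metrics, so the
#' task on the other side of the face (which sees the same slice through
#' the one-voxel overlap) selects the same world voxel. A residual tie
#' falls back to the smallest world coordinate lexicographically.
#'
#' @param chunk 3D label array (task cutout including overlap).
#' @param face one of `"-x","+x","-y","+y","-z","+z"`.
#' @param anisotropy nm per voxel.
#' @param offset world voxel coordinate of the chunk origin.
#' @return data.frame: label, face, voxel index triple (1-based, chunk
#'   frame) and world nm position per target.
#' @export
border_targets <- function(chunk, face, anisotropy = c(1, 1, 1),
                           offset = c(0, 0, 0)) {
  dims <- dim(chunk)
  fs <- face_slice_index(face, dims)
  sl <- slice_axis(chunk, fs$axis, fs$index)
  inplane <- setdiff(1:3, fs$axis)
  w2d <- anisotropy[inplane]
  n2d <- dims[inplane]
  out <- NULL
  for (lab in setdiff(sort(unique(as.vector(sl))), 0)) {
    comp <- label_components_2d(sl == lab)
    for (ci in seq_len(attr(comp, "n"))) {
      mask <- !is.na(comp) & comp == ci
      d <- edt_binary(mask, w2d)
      peak <- max(d[mask])
      cand <- which(mask & d == peak, arr.ind = TRUE)
      if (nrow(cand) > 1) {
        pos <- sweep(cand, 2, w2d, "*")
        cvox <- which(mask, arr.ind = TRUE)
        centroid <- colMeans(sweep(cvox, 2, w2d, "*"))
        fcenter <- (n2d + 1) / 2 * w2d
        corners <- rbind(c(1, 1), c(n2d[1], 1), c(1, n2d[2]), n2d)
        corners <- sweep(corners, 2, w2d, "*")
        crit1 <- rowSums(sweep(pos, 2, centroid, "-")^2)
        crit2 <- rowSums(sweep(pos, 2, fcenter, "-")^2)
        crit3 <- apply(pos, 1, function(p) min(rowSums(sweep(corners, 2, p)^2)))
        crit4 <- pmin((cand[, 1] - 1) * w2d[1], (n2d[1] - cand[, 1]) * w2d[1],
                      (cand[, 2] - 1) * w2d[2], (n2d[2] - cand[, 2]) * w2d[2])
        # world-lexicographic residual tie-break
        wv <- cand
        ord <- order(crit1, crit2, crit3, crit4, wv[, 1], wv[, 2])
        cand <- cand[ord[1], , drop = FALSE]
      }
      voxel <- numeric(3)
      voxel[inplane] <- cand[1, ]
      voxel[fs$axis] <- fs$index
      world <- (voxel - 1 + offset) * anisotropy
      out <- rbind(out, data.frame(label = lab, face = face,
                                   vx = voxel[1], vy = voxel[2], vz = voxel[3],
                                   wx = world[1], wy = world[2], wz = world[3]))
    }
  }
  if (is.null(out)) {
    out <- data.frame(label = numeric(0), face = character(0),
                      vx = numeric(0), vy = numeric(0), vz = numeric(0),
                      wx = numeric(0), wy = numeric(0), wz = numeric(0))
  }
  out
}

# 26-connected voxel graph of a mask with anisotropic nm step lengths
voxel_graph <- function(voxidx, dims, anisotropy) {
  n <- length(voxidx)
  rank <- rep(NA_integer_, prod(dims))
  rank[voxidx] <- seq_len(n)
  coord <- arrayInd(voxidx, dims)
  ef <- integer(0); et <- integer(0); elen <- numeric(0)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dx < 0 || (dx == 0 && dy < 0) || (dx == 0 && dy == 0 && dz < 0)) next
    nb <- coord + matrix(rep(c(dx, dy, dz), each = n), n)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- (nb[ok, 3] - 1) * dims[1] * dims[2] + (nb[ok, 2] - 1) * dims[1] + nb[ok, 1]
    to <- rank[lin]
    keep <- !is.na(to)
    ef <- c(ef, which(ok)[keep]); et <- c(et, to[keep])
    elen <- c(elen, rep(sqrt(sum((c(dx, dy, dz) * anisotropy)^2)), sum(keep)))
  }
  g <- igraph::make_graph(rbind(ef, et), n = n, directed = FALSE)
  igraph::E(g)$steplen <- elen
  g
}

walk_predecessors <- function(pred, from_rank) {
  path <- from_rank
  while (!is.na(pred[path[1]])) path <- c(pred[path[1]], path)
  path
}

#' TEASAR centerline extraction for one connected object
#'
#' Traces minimal-penalty paths through a distance-to-boundary field
#' (DBF). The penalty field `P(v) = 1 + M * (1 - dbf(v)/max(dbf))^p`
#' pushes paths toward the object's medial axis; `M = 1e5` keeps the
#' penalty term dominant over step count. The root is the first border
#' target when targets exist (fragment paths then radiate from the
#' shared task boundary), otherwise the voxel geodesically farthest from
#' an arbitrary seed. Paths are traced first
#' to every border target (so fragments from adjacent tasks meet at
#' deterministic voxels), then repeatedly to the farthest voxel not yet
#' invalidated, with rolling-ball invalidation after each path, until all
#' voxels are invalidated. Soma-mode objects (peak DBF >=
#' `soma_accept`) instead root at the DBF peak and radiate.
#'
#' @param voxidx linear indices (into `dims`) of the object's voxels.
#' @param dims dims of the chunk frame.
#' @param dbf nm distance-to-boundary per object voxel (same order as
#'   `voxidx`).
#' @param params [teasar_params()].
#' @param targets matrix/data.frame of border-target voxel triples
#'   (1-based, chunk frame), possibly empty.
#' @param anisotropy nm per voxel.
#' @param offset world voxel coordinate of the chunk origin.
#' @return a [skeleton()] (empty if the object is dust).
#' @export
teasar <- function(voxidx, dims, dbf, params = teasar_params(),
                   targets = NULL, anisotropy = c(1, 1, 1),
                   offset = c(0, 0, 0)) {
  n <- length(voxidx)
  if (n == 0 || n < params$dust_threshold) return(skeleton())
  coord <- arrayInd(voxidx, dims)
  world <- sweep(sweep(coord - 1, 2, offset, "+"), 2, anisotropy, "*")
  if (n == 1) {
    return(skeleton(vertices = world, edges = matrix(0L, 0, 2),
                    radii = dbf, vertex_types = 0L))
  }
  g <- voxel_graph(voxidx, dims, anisotropy)
  maxdbf <- max(dbf)
  soma <- maxdbf >= params$soma_accept
  M <- 1e5
  pen <- 1 + M * (1 - dbf / maxdbf)^params$pdrf_exponent
  e <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$pweight <- igraph::E(g)$steplen * (pen[e[, 1]] + pen[e[, 2]]) / 2

  rank <- rep(NA_integer_, prod(dims)); rank[voxidx] <- seq_len(n)
  target_ranks <- integer(0)
  if (!is.null(targets) && NROW(targets) > 0) {
    tlin <- (targets[, 3] - 1) * dims[1] * dims[2] +
      (targets[, 2] - 1) * dims[1] + targets[, 1]
    target_ranks <- rank[tlin]
    target_ranks <- target_ranks[!is.na(target_ranks)]
  }
  if (soma) {
    root <- which.max(dbf)
  } else if (length(target_ranks) > 0) {
    # chunk fragments root at their first border target: paths radiate
    # from the shared task boundary, so no stub is left hanging where
    # the root would otherwise sit next to a target
    root <- target_ranks[1]
  } else {
    d0 <- igraph::distances(g, v = 1, weights = igraph::E(g)$steplen)[1, ]
    root <- which.max(d0)
  }
  dphys <- igraph::distances(g, v = root, weights = igraph::E(g)$steplen)[1, ]
  sp <- igraph::shortest_paths(g, from = root, to = igraph::V(g),
                               weights = igraph::E(g)$pweight,
                               predecessors = TRUE)
  pred <- as.integer(sp$predecessors)
  pred[root] <- NA_integer_

  valid <- rep(TRUE, n)
  inval_radius <- params$scale * dbf + params$const
  if (soma) {
    # invalidate the soma ball and mark the root a soma vertex
    soma_r <- params$soma_scale * dbf[root] + params$soma_const
    d2root <- rowSums(sweep(world, 2, world[root, ], "-")^2)
    valid[d2root <= soma_r^2] <- FALSE
    inval_radius <- params$soma_scale * dbf + params$soma_const
  }

  edges <- NULL
  used <- logical(n)
  used[root] <- TRUE
  trace_to <- function(target_rank) {
    path <- walk_predecessors(pred, target_rank)
    if (length(path) > 1) {
      edges <<- rbind(edges, cbind(path[-length(path)], path[-1]))
    }
    used[path] <<- TRUE
    # rolling-ball invalidation around the path
    vidx <- which(valid)
    if (length(vidx)) {
      for (pv in path) {
        if (length(vidx) == 0) break
        d2 <- rowSums(sweep(world[vidx, , drop = FALSE], 2, world[pv, ], "-")^2)
        vidx <- vidx[d2 > inval_radius[pv]^2]
      }
      drop <- setdiff(which(valid), vidx)
      valid[drop] <<- FALSE
    }
    valid[path] <<- FALSE
  }

  # border targets first, then the normal farthest-point phase
  for (tr in target_ranks) trace_to(tr)
  valid[root] <- FALSE
  while (any(valid)) {
    target <- which(valid)[which.max(dphys[valid])]
    trace_to(target)
  }

  keep <- which(used)
  remap <- integer(n); remap[keep] <- seq_along(keep)
  edges <- unique(edges)
  if (!is.null(edges)) {
    edges <- matrix(remap[edges], ncol = 2)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  } else edges <- matrix(0L, 0, 2)
  types <- integer(length(keep))
  if (soma) types[remap[root]] <- 1L
  sk <- skeleton(vertices = world[keep, , drop = FALSE], edges = edges,
                 radii = dbf[keep], vertex_types = types)
  attr(sk, "soma") <- soma
  sk
}

#' Skeletonize every object of a chunk (forge pass)
#'
#' Computes the per-label anisotropic distance-to-boundary field, finds
#' border targets on all six faces, and runs [teasar()] per 26-connected
#' component per label.
#'
#' @param chunk 3D label array (with the one-voxel overlap when part of a
#'   task grid).
#' @param anisotropy nm per voxel.
#' @param offset world voxel coordinate of the chunk origin.
#' @param params [teasar_params()].
#' @return named list label -> list of skeleton fragments.
#' @export
forge_skeletons <- function(chunk, anisotropy = c(1, 1, 1),
                            offset = c(0, 0, 0), params = teasar_params()) {
  dims <- dim(chunk)
  dbf_all <- anisotropic_edt(chunk, anisotropy)
  targets <- do.call(rbind, lapply(FACE_NAMES, function(f) {
    border_targets(chunk, f, anisotropy, offset)
  }))
  out <- list()
  for (lab in setdiff(sort(unique(as.vector(chunk))), 0)) {
    voxidx <- which(chunk == lab)
    g <- voxel_graph(voxidx, dims, anisotropy)
    memb <- igraph::components(g)$membership
    frags <- list()
    ttab <- targets[targets$label == lab, , drop = FALSE]
    for (ci in seq_len(max(memb))) {
      vi <- voxidx[memb == ci]
      if (length(vi) < max(1, params$dust_threshold)) next
      # targets belonging to this component
      tl <- (ttab$vz - 1) * dims[1] * dims[2] + (ttab$vy - 1) * dims[1] + ttab$vx
      tsel <- ttab[tl %in% vi, c("vx", "vy", "vz"), drop = FALSE]
      sk <- teasar(vi, dims, dbf_all[vi], params,
                   targets = as.matrix(tsel), anisotropy = anisotropy,
                   offset = offset)
      if (nrow(sk$vertices) > 0) frags[[length(frags) + 1L]] <- sk
    }
    if (length(frags)) out[[as.character(lab)]] <- frags
  }
  out
}

#' Plan skeletonization tasks over a grid
#'
#' Default task size is 512^3 voxels at the working (near-isotropic) mip;
#' each task bbox gains the one-voxel positive-face overlap so border
#' targets coincide between neighbors.
#'
#' @param root dataset root.
#' @param spec a [volume_spec()].
#' @param mip working mip.
#' @param task_shape task size in voxels.
#' @param params [teasar_params()].
#' @return list of [task_record()]s of kind `"skeleton"`.
#' @export
plan_skeleton_tasks <- function(root, spec, mip,
                                task_shape = c(512, 512, 512),
                                params = teasar_params()) {
  scale <- mip_scale(spec, mip)
  bounds <- scale_bounds(scale)
  lapply(grid_chunks(bounds, task_shape, scale$voxel_offset, bounds),
         function(cb) {
           ext <- bbox3(cb$minpt, pmin(cb$maxpt + 1, bounds$maxpt))
           task_record("skeleton", list(root = root, mip = mip,
                                        bbox_min = ext$minpt,
                                        bbox_max = ext$maxpt,
                                        core_max = cb$maxpt,
                                        params = unclass(params)))
         })
}

#' Merge skeleton fragments of one label
#'
#' Fuses vertices with identical world coordinates (guaranteed at
#' chunk borders by border-target determinism), removes cycles by keeping
#' the maximum spanning forest under edge weight = mean endpoint radius
#' (thick centerline paths survive, the thin redundant loop edges go),
#' prunes terminal branches shorter than `tick_threshold`, and joins
#' connected components whose minimum pairwise vertex distance is smaller
#' than both components' distances to the volume boundary. The result is
#' a forest.
#'
#' @param fragments list of [skeleton()]s of one label.
#' @param params [teasar_params()].
#' @param volume_bounds_nm optional 2 x 3 matrix (min; max nm corner of
#'   the dataset); enables the component-join rule.
#' @return a merged [skeleton()].
#' @export
merge_skeletons <- function(fragments, params = teasar_params(),
                            volume_bounds_nm = NULL) {
  fragments <- fragments[vapply(fragments, function(f) nrow(f$vertices) > 0,
                                logical(1))]
  if (length(fragments) == 0) return(skeleton())
  verts <- do.call(rbind, lapply(fragments, `[[`, "vertices"))
  radii <- do.call(c, lapply(fragments, `[[`, "radii"))
  types <- do.call(c, lapply(fragments, `[[`, "vertex_types"))
  offs <- cumsum(c(0, vapply(fragments, function(f) nrow(f$vertices),
                             numeric(1))))
  edges <- do.call(rbind, Map(function(f, o) {
    if (nrow(f$edges)) f$edges + o else NULL
  }, fragments, offs[-length(offs)]))
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  ukey <- !duplicated(key)
  remap <- match(key, key[ukey])
  # fused vertices keep the larger radius / the soma type if any copy had it
  nv <- sum(ukey)
  radii_u <- vapply(seq_len(nv), function(i) max(radii[remap == i]), numeric(1))
  types_u <- vapply(seq_len(nv), function(i) max(types[remap == i]), integer(1))
  verts <- verts[ukey, , drop = FALSE]
  if (!is.null(edges)) {
    edges <- matrix(remap[edges], ncol = 2)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[!duplicated(ek), , drop = FALSE]
  } else edges <- matrix(0L, 0, 2)

  # cycle removal: maximum spanning forest on mean endpoint radius
  if (nrow(edges) > 0) {
    g <- igraph::make_graph(t(edges), n = nv, directed = FALSE)
    w <- (radii_u[edges[, 1]] + radii_u[edges[, 2]]) / 2
    forest <- igraph::mst(g, weights = -w)
    edges <- igraph::as_edgelist(forest, names = FALSE)
    storage.mode(edges) <- "integer"
  }

  sk <- skeleton(verts, edges, radii_u, types_u)
  if (params$tick_threshold > 0) sk <- prune_ticks(sk, params$tick_threshold)
  if (!is.null(volume_bounds_nm)) sk <- join_close_components(sk, volume_bounds_nm)
  sk
}

# remove terminal branches shorter than threshold nm whose far end is a
# junction (degree >= 3); repeats until stable
prune_ticks <- function(sk, threshold) {
  repeat {
    nv <- nrow(sk$vertices)
    if (nv == 0 || nrow(sk$edges) == 0) return(sk)
    deg <- tabulate(as.vector(sk$edges), nv)
    adj <- vector("list", nv)
    for (i in seq_len(nrow(sk$edges))) {
      a <- sk$edges[i, 1]; b <- sk$edges[i, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    elen <- function(a, b) sqrt(sum((sk$vertices[a, ] - sk$vertices[b, ])^2))
    drop_vs <- integer(0)
    for (leaf in which(deg == 1)) {
      path <- leaf; prev <- 0L; cur <- leaf; len <- 0
      repeat {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) != 1) break
        len <- len + elen(cur, nxt)
        prev <- cur; cur <- nxt
        if (deg[cur] >= 3) break
        path <- c(path, cur)
      }
      if (deg[cur] >= 3 && len < threshold) drop_vs <- c(drop_vs, path)
    }
    drop_vs <- unique(drop_vs)
    if (length(drop_vs) == 0) return(sk)
    keep <- setdiff(seq_len(nv), drop_vs)
    remap <- integer(nv); remap[keep] <- seq_along(keep)
    e <- sk$edges[sk$edges[, 1] %in% keep & sk$edges[, 2] %in% keep, ,
                  drop = FALSE]
    sk <- skeleton(sk$vertices[keep, , drop = FALSE],
                   matrix(remap[e], ncol = 2),
                   sk$radii[keep], sk$vertex_types[keep])
  }
}

# join components whose minimum pairwise distance is below both
# components' distance to the volume boundary
join_close_components <- function(sk, volume_bounds_nm) {
  repeat {
    nv <- nrow(sk$vertices)
    if (nv == 0) return(sk)
    g <- igraph::make_graph(t(sk$edges), n = nv, directed = FALSE)
    memb <- igraph::components(g)$membership
    ncomp <- max(memb)
    if (ncomp < 2) return(sk)
    bdist <- vapply(seq_len(ncomp), function(ci) {
      v <- sk$vertices[memb == ci, , drop = FALSE]
      lo <- sweep(v, 2, volume_bounds_nm[1, ], "-")
      hi <- sweep(-v, 2, volume_bounds_nm[2, ], "+")
      min(pmin(apply(lo, 1, min), apply(hi, 1, min)))
    }, numeric(1))
    best <- NULL
    for (a in 1:(ncomp - 1)) {
      va <- which(memb == a)
      for (b in (a + 1):ncomp) {
        vb <- which(memb == b)
        d2 <- outer(seq_along(va), seq_along(vb), function(i, j) {
          rowSums((sk$vertices[va[i], , drop = FALSE] -
                   sk$vertices[vb[j], , drop = FALSE])^2)
        })
        mn <- which.min(d2)
        dmin <- sqrt(d2[mn])
        if (dmin < min(bdist[a], bdist[b]) &&
            (is.null(best) || dmin < best$d)) {
          i <- (mn - 1) %% length(va) + 1; j <- (mn - 1) %/% length(va) + 1
          best <- list(d = dmin, a = va[i], b = vb[j])
        }
      }
    }
    if (is.null(best)) return(sk)
    sk$edges <- rbind(sk$edges, c(best$a, best$b))
  }
}

#' Serialize / parse a skeleton
#'
#' Binary layout: u32 vertex count, u32 edge count, float32 vertex
#' triples (nm), u32 edge pairs (0-based), then per-vertex attributes:
#' float32 radius and uint8 vertex type.
#'
#' @param skel a [skeleton()].
#' @export
serialize_skeleton <- function(skel) {
  c(u32_to_raw(nrow(skel$vertices)), u32_to_raw(nrow(skel$edges)),
    f32_to_raw(as.vector(t(skel$vertices))),
    u32_to_raw(as.vector(t(skel$edges - 1L))),
    f32_to_raw(skel$radii),
    as.raw(skel$vertex_types))
}

#' @rdname serialize_skeleton
#' @param bytes serialized skeleton.
#' @export
parse_skeleton <- function(bytes) {
  nv <- raw_to_u32(bytes[1:4]); ne <- raw_to_u32(bytes[5:8])
  p <- 8
  verts <- matrix(raw_to_f32(bytes[p + seq_len(12 * nv)]), ncol = 3,
                  byrow = TRUE)
  p <- p + 12 * nv
  edges <- matrix(raw_to_u32(bytes[p + seq_len(8 * ne)]) + 1L, ncol = 2,
                  byrow = TRUE)
  p <- p + 8 * ne
  radii <- raw_to_f32(bytes[p + seq_len(4 * nv)])
  p <- p + 4 * nv
  types <- as.integer(bytes[p + seq_len(nv)])
  if (nv == 0) { verts <- matrix(0, 0, 3); radii <- numeric(0); types <- integer(0) }
  if (ne == 0) edges <- matrix(0L, 0, 2)
  skeleton(verts, edges, radii, types)
}

#' Export a skeleton to SWC
#'
#' Roots each tree at its highest-radius vertex and writes the standard
#' 7-column SWC table. Cyclic input is an error (SWC is tree-based).
#'
#' @param skel a [skeleton()].
#' @param path optional file; when omitted the SWC lines are returned.
#' @export
swc_export <- function(skel, path = NULL) {
  nv <- nrow(skel$vertices)
  if (nv == 0) {
    lines <- character(0)
  } else {
    g <- igraph::make_graph(t(skel$edges), n = nv, directed = FALSE)
    comp <- igraph::components(g)
    if (igraph::ecount(g) > nv - comp$no) {
      stop("swc_export: skeleton contains a cycle; SWC is tree-based")
    }
    memb <- comp$membership
    parent <- rep(-1L, nv)
    for (ci in seq_len(max(memb))) {
      vs <- which(memb == ci)
      root <- vs[which.max(skel$radii[vs])]
      bfs <- igraph::bfs(g, root = root, unreachable = FALSE, father = TRUE)
      f <- as.integer(bfs$father)
      reach <- !is.na(bfs$order)
      parent[vs] <- ifelse(is.na(f[vs]), -1L, f[vs])
    }
    lines <- sprintf("%d %d %g %g %g %g %d",
                     seq_len(nv), skel$vertex_types,
                     skel$vertices[, 1], skel$vertices[, 2],
                     skel$vertices[, 3], skel$radii, parent)
  }
  if (is.null(path)) return(lines)
  writeLines(c("# SWC export", lines), path)
  invisible(NULL)
}
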
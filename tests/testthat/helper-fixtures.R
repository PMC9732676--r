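# shared helpers: fixtures are built in code at test time

# canonical form of a mesh: triangles as sorted coordinate-key strings,
# invariant to vertex and triangle ordering
mesh_canonical <- function(mesh) {
  k <- paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  sort(apply(mesh$triangles, 1, function(t) paste(sort(k[t]), collapse = "|")))
}

# a 12-triangle unit cube with outward winding
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0, normal -z
    c(5, 6, 7), c(6, 8, 7),  # z = 1, normal +z
    c(1, 2, 5), c(2, 6, 5),  # y = 0, normal -y
    c(3, 7, 4), c(4, 7, 8),  # y = 1, normal +y
    c(1, 5, 3), c(3, 5, 7),  # x = 0, normal -x
    c(2, 4, 6), c(4, 8, 6))  # x = 1, normal +x
  list(vertices = unname(v), triangles = tri)
}

# random smooth dense segmentation (Voronoi) used across codec tests
smooth_labels_fixture <- function(shape = c(32, 32, 16), n = 12, seed = 42) {
  make_dense_labels(shape, n, seed = seed)
}

# count cycles of a skeleton graph
skeleton_cycles <- function(sk) {
  if (nrow(sk$vertices) == 0) return(0)
  g <- igraph::make_graph(t(sk$edges), n = nrow(sk$vertices), directed = FALSE)
  igraph::ecount(g) - (nrow(sk$vertices) - igraph::components(g)$no)
}

skeleton_components <- function(sk) {
  if (nrow(sk$vertices) == 0) return(0)
  g <- igraph::make_graph(t(sk$edges), n = nrow(sk$vertices), directed = FALSE)
  igraph::components(g)$no
}

# snapshot a directory tree as filename -> md5, for idempotency audits
tree_digest <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, full.names = FALSE))
  vapply(files, function(f) {
    unname(tools::md5sum(file.path(root, f)))
  }, character(1))
}

make_image_volume <- function(root, img, chunk_size = c(32, 32, 8),
                              encoding = "raw", resolution = c(8, 8, 40)) {
  sc <- scale_spec(paste(resolution, collapse = "_"), resolution,
                   dim(img), chunk_size, encoding = encoding)
  spec <- volume_spec("uint8", "image", list(sc))
  write_info(spec, root)
  write_region(root, spec, 0, bbox3(c(0, 0, 0), dim(img)), img)
  spec
}

make_seg_volume <- function(root, lab, chunk_size = c(32, 32, 16),
                            encoding = "compresso",
                            resolution = c(32, 32, 40),
                            data_type = "uint64") {
  sc <- scale_spec(paste(resolution, collapse = "_"), resolution,
                   dim(lab), chunk_size, encoding = encoding)
  spec <- volume_spec(data_type, "segmentation", list(sc),
                      mesh_dir = "mesh", skeleton_dir = "skeletons")
  write_info(spec, root)
  write_region(root, spec, 0, bbox3(c(0, 0, 0), dim(lab)), lab)
  spec
}
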
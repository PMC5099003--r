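#' Triangulated lumen surface mesh
#'
#' Constructs a `tri_mesh`, the container used throughout the package for
#' lumen wall geometry: node coordinates in mm, a triangle index matrix, and
#' per-node outward unit normals recomputed from the geometry (area-weighted
#' average of incident facet normals).
#'
#' @param nodes numeric matrix, n x 3, node coordinates (mm).
#' @param triangles integer matrix, m x 3, 1-based node indices per facet.
#'   Winding is assumed consistent; normals follow the right-hand rule.
#' @param recompute_normals logical; if `TRUE` (default) normals are derived
#'   from the triangle geometry.
#' @return object of class `tri_mesh` with components `nodes`, `triangles`,
#'   `normals`.
#' @export
tri_mesh <- function(nodes, triangles, recompute_normals = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (nrow(triangles) > 0L &&
      (min(triangles) < 1L || max(triangles) > nrow(nodes)))
    stop("triangle indices out of range")
  m <- structure(list(nodes = nodes, triangles = triangles, normals = NULL),
                 class = "tri_mesh")
  if (recompute_normals) m$normals <- compute_node_normals(m)
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d nodes, %d triangles\n",
              nrow(x$nodes), nrow(x$triangles)))
  invisible(x)
}

# Per-triangle (unnormalized) normals: cross product of edge vectors, whose
# magnitude is twice the facet area. Used for both facet normals and the
# area weighting of node normals.
triangle_cross <- function(mesh) {
  v1 <- mesh$nodes[mesh$triangles[, 1L], , drop = FALSE]
  v2 <- mesh$nodes[mesh$triangles[, 2L], , drop = FALSE]
  v3 <- mesh$nodes[mesh$triangles[, 3L], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
        e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
        e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

compute_node_normals <- function(mesh) {
  cr <- triangle_cross(mesh)
  n <- matrix(0, nrow(mesh$nodes), 3L)
  for (j in 1:3) {
    idx <- mesh$triangles[, j]
    for (k in 1:3)
      n[, k] <- n[, k] + rowsum_safe(cr[, k], idx, nrow(mesh$nodes))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# rowsum over a fixed number of bins, returning a dense vector.
rowsum_safe <- function(x, idx, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Total surface area of a triangulated mesh (mm^2)
#' @param mesh a `tri_mesh`.
#' @return numeric scalar.
#' @export
mesh_area <- function(mesh) {
  sum(sqrt(rowSums(triangle_cross(mesh)^2))) / 2
}

#' Build a structured tube mesh
#'
#' Generates a straight tube along the z axis with a (possibly varying)
#' radius profile, triangulated as `n_axial` rings of `n_circ` nodes with no
#' end caps. Outward normals are recomputed from the geometry.
#'
#' @param radius_profile function of arc length s (mm) returning the tube
#'   radius R(s) in mm, or a single number for a cylinder.
#' @param length axial extent (mm).
#' @param n_axial number of rings (>= 2).
#' @param n_circ nodes per ring (>= 3).
#' @return a `tri_mesh` of `n_axial * n_circ` nodes.
#' @examples
#' tube <- build_tube_mesh(0.3, 10, 21, 12)
#' @export
build_tube_mesh <- function(radius_profile, length, n_axial, n_circ) {
  if (is.numeric(radius_profile)) {
    r0 <- radius_profile
    radius_profile <- function(s) rep_len(r0, base::length(s))
  }
  if (n_axial < 2L) stop("n_axial must be >= 2")
  if (n_circ < 3L) stop("n_circ must be >= 3")
  s <- seq(0, length, length.out = n_axial)
  R <- radius_profile(s)
  if (any(!is.finite(R)) || any(R <= 0))
    stop("radius profile must be positive over [0, length]")
  theta <- seq(0, 2 * pi, length.out = n_circ + 1L)[seq_len(n_circ)]
  # node order: ring-major, node index = (i_ring - 1) * n_circ + i_theta
  nodes <- cbind(
    x = rep(R, each = n_circ) * cos(rep_len(theta, n_axial * n_circ)),
    y = rep(R, each = n_circ) * sin(rep_len(theta, n_axial * n_circ)),
    z = rep(s, each = n_circ))
  tri <- vector("list", n_axial - 1L)
  for (i in seq_len(n_axial - 1L)) {
    a <- (i - 1L) * n_circ + seq_len(n_circ)          # ring i
    b <- i * n_circ + seq_len(n_circ)                 # ring i + 1
    an <- c(a[-1L], a[1L])                            # next-around-ring
    bn <- c(b[-1L], b[1L])
    # winding chosen so cross(e1, e2) points radially outward
    tri[[i]] <- rbind(cbind(a, an, b), cbind(an, bn, b))
  }
  tri_mesh(nodes, do.call(rbind, tri))
}

#' Read a surface mesh from an STL file
#'
#' Reads ASCII or binary STL (auto-detected). STL stores a triangle soup, so
#' vertices are merged within a tolerance of 1e-6 mm to recover shared-node
#' connectivity; file normals are discarded and recomputed from the geometry.
#' Degenerate (zero-area) facets are dropped with a message.
#'
#' @param path path to an STL file.
#' @return a `tri_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80L)
  close(con)
  is_ascii <- FALSE
  txt5 <- rawToChar(head80[1:5])
  if (identical(tolower(txt5), "solid")) {
    # could still be a binary file whose header starts with "solid";
    # verify by size arithmetic
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    close(con); on.exit()
    expected <- 84 + 50 * as.numeric(ntri)
    if (!isTRUE(file.size(path) == expected)) is_ascii <- TRUE
  }
  if (is_ascii) stl_from_ascii(path) else stl_from_binary(path)
}

stl_from_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ASCII STL (vertex count ", length(vl),
         " not a multiple of 3) in ", path)
  toks <- strsplit(trimws(lines[vl]), "\\s+")
  bad <- which(vapply(toks, base::length, 1L) != 4L)
  if (length(bad))
    stop("malformed ASCII STL at line ", vl[bad[1L]], " of ", path)
  verts <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (any(!is.finite(verts)))
    stop("malformed ASCII STL: non-numeric vertex in ", path)
  mesh_from_soup(verts)
}

stl_from_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(ntri) == 0L || ntri < 0L)
    stop("malformed binary STL header in ", path)
  expected <- 84 + 50 * as.numeric(ntri)
  if (!isTRUE(file.size(path) == expected))
    stop("malformed binary STL: expected ", expected, " bytes (",
         ntri, " facets), found ", file.size(path), " in ", path)
  raw <- readBin(con, "raw", 50L * ntri)
  if (ntri == 0L) stop("binary STL contains zero facets: ", path)
  dim(raw) <- c(50L, ntri)
  # each record: 12 float32 (normal + 3 vertices) + uint16 attribute
  fl <- readBin(as.vector(raw[1:48, , drop = FALSE]), "double",
                n = 12L * ntri, size = 4L, endian = "little")
  fl <- matrix(fl, nrow = 12L)
  verts <- matrix(NA_real_, 3L * ntri, 3L)
  for (v in 1:3) {
    rows <- 3L * v + 1:3   # skip the facet normal (rows 1:3)
    verts[seq(v, by = 3L, length.out = ntri), ] <- t(fl[rows, , drop = FALSE])
  }
  mesh_from_soup(verts)
}

# Collapse a triangle soup (3 consecutive rows per facet) into a shared-node
# mesh, merging coordinates within `tol` mm and dropping zero-area facets.
mesh_from_soup <- function(verts, tol = 1e-6) {
  key <- paste(round(verts[, 1L] / tol), round(verts[, 2L] / tol),
               round(verts[, 3L] / tol))
  idx <- match(key, key)                 # representative row per vertex
  uniq <- sort(unique(idx))
  remap <- match(idx, uniq)
  nodes <- verts[uniq, , drop = FALSE]
  tri <- matrix(remap, ncol = 3L, byrow = TRUE)
  degen <- tri[, 1L] == tri[, 2L] | tri[, 2L] == tri[, 3L] |
    tri[, 1L] == tri[, 3L]
  mzero <- rowSums(triangle_cross(
    list(nodes = nodes, triangles = tri))^2) == 0
  drop <- degen | mzero
  if (any(drop)) {
    message("read_stl: dropped ", sum(drop), " degenerate facet(s)")
    tri <- tri[!drop, , drop = FALSE]
  }
  if (nrow(tri) == 0L) stop("STL contains no non-degenerate facets")
  keep <- sort(unique(as.vector(tri)))
  tri_mesh(nodes[keep, , drop = FALSE],
           matrix(match(as.vector(tri), keep), ncol = 3L))
}

#' Write a mesh to binary STL
#'
#' @param mesh a `tri_mesh` with at least one triangle.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$triangles) == 0L) stop("refusing to write an empty mesh")
  cr <- triangle_cross(mesh)
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- 1
  fn <- cr / len
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(mesh$triangles)), con, size = 4L,
           endian = "little")
  v1 <- mesh$nodes[mesh$triangles[, 1L], , drop = FALSE]
  v2 <- mesh$nodes[mesh$triangles[, 2L], , drop = FALSE]
  v3 <- mesh$nodes[mesh$triangles[, 3L], , drop = FALSE]
  rec <- t(cbind(fn, v1, v2, v3))        # 12 floats per facet, column-major
  payload <- writeBin(as.vector(rec), raw(), size = 4L, endian = "little")
  dim(payload) <- c(48L, nrow(mesh$triangles))
  full <- rbind(payload, matrix(as.raw(0L), 2L, nrow(mesh$triangles)))
  writeBin(as.vector(full), con)
  invisible(path)
}

#' Cylindrical parameterization of a tubular mesh
#'
#' Assigns each node an axial arc-length coordinate s (projection onto a
#' straight axis, shifted so min(s) = 0) and a circumferential angle theta in
#' [0, 2*pi). The synthetic vessels are straight tubes; real input is assumed
#' pre-straightened.
#'
#' @param mesh a `tri_mesh`.
#' @param axis unit 3-vector of the tube direction (normalized internally).
#' @param origin 3-vector subtracted from node coordinates before projection.
#' @return object of class `centerline_frame`: list with per-node `s` (mm),
#'   `theta` (rad), and total axial extent `length` (mm).
#' @export
parameterize <- function(mesh, axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  p <- sweep(mesh$nodes, 2L, origin)
  s <- drop(p %*% axis)
  s <- s - min(s)
  # in-plane basis: start from the coordinate axis least aligned with `axis`
  seed <- diag(3)[, which.min(abs(axis))]
  e1 <- seed - sum(seed * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2L] * e1[3L] - axis[3L] * e1[2L],
          axis[3L] * e1[1L] - axis[1L] * e1[3L],
          axis[1L] * e1[2L] - axis[2L] * e1[1L])
  u <- drop(p %*% e1)
  v <- drop(p %*% e2)
  r <- sqrt(u^2 + v^2)
  if (any(r < 1e-12))
    stop("node lies exactly on the axis; theta undefined")
  theta <- atan2(v, u) %% (2 * pi)
  structure(list(s = s, theta = theta, length = max(s)),
            class = "centerline_frame")
}

#' Edge adjacency of mesh nodes
#'
#' @param mesh a `tri_mesh`.
#' @return list of integer vectors; element j holds the node indices sharing
#'   an edge with node j. Symmetric by construction.
#' @export
node_neighbors <- function(mesh) {
  tr <- mesh$triangles
  edges <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  # both directions, unique pairs
  all_e <- unique(rbind(edges, edges[, c(2L, 1L)]))
  adj <- split(all_e[, 2L], factor(all_e[, 1L], levels = seq_len(nrow(mesh$nodes))))
  unname(lapply(adj, function(v) sort(unname(v))))
}
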
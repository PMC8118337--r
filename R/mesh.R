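#' Triangle mesh of a cell isosurface
#'
#' A closed triangle mesh in micrometres with the coordinate origin at the
#' center of its axis-aligned bounding box (the convention that makes the
#' downstream shape descriptor translation invariant).
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (um).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param provenance free-text note on where the mesh came from.
#' @param center if `TRUE` (default) translate so the bounding-box center is
#'   the origin.
#' @return an object of class `rbc_mesh` with elements `vertices`, `faces`,
#'   `provenance`.
#' @export
rbc_mesh <- function(vertices, faces, provenance = "", center = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    .stop_erythro("vertices and faces must have 3 columns", "mesh_error")
  if (nrow(vertices) < 4L || nrow(faces) < 4L)
    .stop_erythro("mesh is empty or degenerate", "mesh_error")
  if (max(faces) > nrow(vertices) || min(faces) < 1L)
    .stop_erythro("face indices out of range", "mesh_error")
  m <- structure(list(vertices = vertices, faces = faces,
                      provenance = provenance),
                 class = "rbc_mesh")
  if (center) m <- center_mesh(m)
  m
}

#' @export
print.rbc_mesh <- function(x, ...) {
  cat(sprintf("<rbc_mesh> %d vertices, %d faces, volume %.2f um^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Center a mesh on its bounding box
#'
#' @param mesh an [rbc_mesh()].
#' @return the mesh translated so that (max + min)/2 per axis is 0.
#' @export
center_mesh <- function(mesh) {
  v <- mesh$vertices
  ctr <- (apply(v, 2, max) + apply(v, 2, min)) / 2
  mesh$vertices <- sweep(v, 2, ctr)
  mesh
}

#' Enclosed volume of a closed mesh
#'
#' Signed sum of origin-anchored tetrahedra; the absolute value is returned
#' so the result does not depend on the winding convention.
#'
#' @param mesh an [rbc_mesh()].
#' @return volume in um^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  abs(sum(det6)) / 6
}

#' Volume centroid (center of mass) of a closed mesh
#'
#' Signed-tetrahedron centroid; rotation covariant, unlike the bounding-box
#' center, which is why the shape descriptor re-centers on it.
#'
#' @param mesh an [rbc_mesh()].
#' @return length-3 numeric centroid (um).
#' @export
mesh_centroid <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  colSums((a + b + c3) / 4 * det6) / sum(det6)
}

#' Surface area of a mesh
#' @param mesh an [rbc_mesh()].
#' @return area in um^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Sphericity of a closed mesh
#'
#' pi^(1/3) (6V)^(2/3) / A; equals 1 for a perfect sphere.
#' @param mesh an [rbc_mesh()].
#' @export
mesh_sphericity <- function(mesh) {
  pi^(1 / 3) * (6 * mesh_volume(mesh))^(2 / 3) / mesh_area(mesh)
}

#' Is every mesh edge shared by exactly two faces?
#' @param mesh an [rbc_mesh()].
#' @return `TRUE` for a closed (watertight) mesh.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Area-weighted vertex normals
#' @param mesh an [rbc_mesh()].
#' @return matrix of unit normals, one row per vertex.
#' @keywords internal
mesh_vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, k], f[, j])
      n[as.integer(rownames(acc)), k] <- n[as.integer(rownames(acc)), k] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  # orient outward: the average normal of a closed mesh built here points
  # outward when the signed volume is positive
  n <- n / len
  sgn <- sign(sum(rowSums(n * v)))
  if (sgn < 0) n <- -n
  n
}

#' Apply a rotation matrix to a mesh
#' @param mesh an [rbc_mesh()].
#' @param rot 3x3 rotation matrix.
#' @return rotated, re-centered mesh.
#' @export
rotate_mesh <- function(mesh, rot) {
  rbc_mesh(mesh$vertices %*% t(rot), mesh$faces,
           provenance = mesh$provenance)
}

#' Uniform random rotation matrix
#'
#' Drawn from the Haar measure on SO(3) via QR of a Gaussian matrix; uses
#' the current RNG state.
#' @return 3x3 rotation matrix.
#' @export
random_rotation_matrix <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Unit icosphere (subdivided icosahedron)
#'
#' The fixed spherical grid used for the shared radial parameterization of
#' meshes (remeshing and morphing). Memoised per subdivision level.
#'
#' @param subdivisions number of 4-to-1 face subdivisions (0 = icosahedron).
#' @return an `rbc_mesh` on the unit sphere (not bounding-box centered:
#'   vertices lie exactly on the sphere about the origin).
#' @export
icosphere <- function(subdivisions = 4L) {
  key <- paste0("icosphere_", subdivisions)
  hit <- .erythro_cache[[key]]
  if (!is.null(hit)) return(hit)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(parent = emptyenv())
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key2 <- paste(min(i, j), max(i, j))
      hit2 <- midcache[[key2]]
      if (!is.null(hit2)) return(hit2)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      id <- nv + length(newv)
      midcache[[key2]] <- id
      id
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[(t - 1) * 4 + 1, ] <- c(a, ab, ca)
      newf[(t - 1) * 4 + 2, ] <- c(b, bc, ab)
      newf[(t - 1) * 4 + 3, ] <- c(c3, ca, bc)
      newf[(t - 1) * 4 + 4, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  out <- structure(list(vertices = v, faces = f,
                        provenance = sprintf("icosphere(%d)", subdivisions)),
                   class = "rbc_mesh")
  .erythro_cache[[key]] <- out
  out
}

#' One-ring vertex adjacency of a mesh
#' @param mesh an [rbc_mesh()].
#' @return list of integer vectors of neighbor indices per vertex.
#' @keywords internal
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, c(2, 1)])
  split(e[, 2], factor(e[, 1], levels = seq_len(nrow(mesh$vertices))))
}

#' Remesh a star-shaped mesh onto the shared icosphere grid
#'
#' Casts a ray from the origin along every icosphere vertex direction and
#' keeps the farthest intersection, producing a mesh with fixed vertex count
#' and connectivity (the shared parameterization used for morphs).
#'
#' @param mesh an [rbc_mesh()], star shaped with respect to the origin.
#' @param subdivisions icosphere subdivision level (default 4).
#' @return remeshed `rbc_mesh`.
#' @export
remesh_radial <- function(mesh, subdivisions = 4L) {
  ico <- icosphere(subdivisions)
  r <- cpp_ray_radial(mesh$vertices, mesh$faces, ico$vertices)
  if (any(r <= 0))
    .stop_erythro(
      sprintf("mesh '%s' is not star-shaped about the origin (%d rays missed)",
              mesh$provenance, sum(r <= 0)), "morph_failure")
  rbc_mesh(ico$vertices * r, ico$faces,
           provenance = paste0("remeshed:", mesh$provenance), center = FALSE)
}

#' Taubin lambda/mu mesh smoothing
#'
#' Alternating shrink (lambda) and inflate (mu) Laplacian passes -- the
#' standard low-pass filter for voxel-scale staircase roughness on
#' marching-cubes output; unlike plain Laplacian smoothing it preserves
#' volume to a fraction of a percent.
#'
#' @param mesh an [rbc_mesh()].
#' @param iterations lambda+mu passes (default 15).
#' @param lambda,mu Taubin coefficients (defaults 0.5 / -0.53).
#' @return the smoothed, re-centered mesh.
#' @export
taubin_smooth <- function(mesh, iterations = 15L, lambda = 0.5,
                          mu = -0.53) {
  if (iterations < 1L) return(mesh)
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  mesh$vertices <- cpp_taubin(mesh$vertices, e[, 1], e[, 2],
                              as.integer(iterations), lambda, mu)
  center_mesh(mesh)
}

#' Write a mesh as ASCII Wavefront OBJ
#' @param mesh an [rbc_mesh()].
#' @param path output file.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# erythroshape mesh", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read an ASCII Wavefront OBJ mesh
#' @param path input file.
#' @param center center the bounding box on the origin (default `TRUE`).
#' @return an [rbc_mesh()].
#' @export
read_obj <- function(path, center = TRUE) {
  ln <- readLines(path, warn = FALSE)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  if (!length(vl) || !length(fl))
    .stop_erythro(sprintf("'%s' contains no mesh", path), "format_error")
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                             function(x) as.integer(sub("/.*", "", x[1:3]))))
  rbc_mesh(v, f, provenance = basename(path), center = center)
}

#' Write a mesh as ASCII PLY
#' @param mesh an [rbc_mesh()].
#' @param path output file.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment erythroshape mesh",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path input file.
#' @param center center the bounding box on the origin (default `TRUE`).
#' @return an [rbc_mesh()].
#' @export
read_ply <- function(path, center = TRUE) {
  ln <- readLines(path, warn = FALSE)
  if (!length(ln) || ln[1] != "ply")
    .stop_erythro(sprintf("'%s' is not an ascii PLY file", path),
                  "format_error")
  hdr_end <- which(ln == "end_header")[1]
  if (is.na(hdr_end))
    .stop_erythro(sprintf("'%s' has no end_header", path), "format_error")
  hdr <- ln[seq_len(hdr_end)]
  nv <- as.integer(sub(".*element vertex ", "",
                       hdr[grepl("^element vertex", hdr)]))
  nf <- as.integer(sub(".*element face ", "",
                       hdr[grepl("^element face", hdr)]))
  body <- ln[(hdr_end + 1):length(ln)]
  v <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                             function(x) as.integer(x[2:4]) + 1L))
  rbc_mesh(v, f, provenance = basename(path), center = center)
}
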
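#' Triangle surface mesh
#'
#' Lightweight triangle-soup container used for implant articular surfaces.
#' Coordinates are millimetres.  Faces are stored with a winding such that the
#' geometric normal `cross(v2 - v1, v3 - v1)` equals the stored outward unit
#' normal; rigid transforms preserve this.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm)
#' @param faces integer m x 3 matrix of 1-based vertex indices
#' @param outward_normals optional m x 3 matrix of reference outward directions;
#'   faces are rewound so their geometric normals align with these
#' @return object of class `surface_mesh` with fields `vertices`, `faces`,
#'   `normals` (per-face outward unit normals), `areas` (per-face, mm^2)
#' @export
surface_mesh <- function(vertices, faces, outward_normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  if (min(faces) < 1 || max(faces) > nrow(vertices)) stop("face index out of range")

  geom <- face_geometry(vertices, faces)
  if (!is.null(outward_normals)) {
    flip <- rowSums(geom$normals * outward_normals) < 0
    if (any(flip)) {
      faces[flip, 2:3] <- faces[flip, 3:2]
      geom <- face_geometry(vertices, faces)
    }
  }
  if (any(geom$areas <= 0)) stop("every face must have positive area")
  structure(list(vertices = vertices, faces = faces,
                 normals = geom$normals, areas = geom$areas),
            class = "surface_mesh")
}

face_geometry <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  cr <- cross3m(v2 - v1, v3 - v1)
  len <- sqrt(rowSums(cr * cr))
  list(normals = cr / len, areas = len / 2)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces,",
      sprintf("total area %.1f mm^2\n", sum(x$areas)))
  invisible(x)
}

#' Face centroids of a mesh
#' @param mesh a [surface_mesh()]
#' @return m x 3 matrix of face centroids (mm)
#' @export
face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

#' Rigidly transform a mesh
#'
#' @param mesh a [surface_mesh()]
#' @param R 3x3 rotation matrix
#' @param t length-3 translation (mm)
#' @return transformed `surface_mesh`
#' @export
transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  mesh$vertices <- transform_points(mesh$vertices, R, t)
  mesh$normals <- mesh$normals %*% t(R)
  mesh
}

# Build a surface_mesh from a parametric grid of points.
# pts: list with x, y, z matrices (nu x nv); outward: function(iu, iv) -> n x 3
# normals at grid nodes, or a precomputed nu x nv x 3 array.
mesh_from_grid <- function(px, py, pz, normal_fun = NULL) {
  nu <- nrow(px); nv <- ncol(px)
  vertices <- cbind(as.vector(px), as.vector(py), as.vector(pz))
  idx <- matrix(seq_len(nu * nv), nu, nv)
  f <- vector("list", (nu - 1) * (nv - 1))
  k <- 1
  for (j in seq_len(nv - 1)) {
    for (i in seq_len(nu - 1)) {
      a <- idx[i, j]; b <- idx[i + 1, j]; cc <- idx[i + 1, j + 1]; d <- idx[i, j + 1]
      f[[k]] <- rbind(c(a, b, cc), c(a, cc, d))
      k <- k + 1
    }
  }
  faces <- do.call(rbind, f)
  outn <- NULL
  if (!is.null(normal_fun)) {
    vn <- normal_fun(vertices)  # per-vertex outward directions
    outn <- (vn[faces[, 1], ] + vn[faces[, 2], ] + vn[faces[, 3], ]) / 3
  }
  surface_mesh(vertices, faces, outward_normals = outn)
}

#' Sphere and plane meshes (contact-model oracles)
#'
#' `mesh_sphere` builds a full or partial latitude/longitude sphere;
#' `mesh_plane` a rectangular grid in the y = `y0` plane with outward normal
#' `+Y` or `-Y`.  These are the fixtures used to verify the elastic-foundation
#' contact model against the closed-form sphere-on-plane solution.
#'
#' @param radius sphere radius (mm)
#' @param center sphere centre (mm)
#' @param n_theta,n_phi angular resolution
#' @param theta_max polar cap half-angle (rad); pi for a full sphere
#' @param pole direction of the cap pole, `"down"` (-Y) or `"up"`
#' @return a [surface_mesh()]
#' @export
mesh_sphere <- function(radius = 20, center = c(0, 0, 0), n_theta = 24,
                        n_phi = 48, theta_max = pi, pole = "down") {
  th <- seq(1e-4, theta_max, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-1]
  g <- expand.grid(th = th, ph = ph)
  sgn <- if (pole == "down") -1 else 1
  # polar axis along Y
  px <- matrix(radius * sin(g$th) * cos(g$ph), n_theta, n_phi)
  py <- matrix(sgn * radius * cos(g$th), n_theta, n_phi)
  pz <- matrix(radius * sin(g$th) * sin(g$ph), n_theta, n_phi)
  # close the seam by appending first column
  px <- cbind(px, px[, 1]); py <- cbind(py, py[, 1]); pz <- cbind(pz, pz[, 1])
  m <- mesh_from_grid(px + center[1], py + center[2], pz + center[3],
                      normal_fun = function(v) {
                        n <- sweep(v, 2, center)
                        n / sqrt(rowSums(n * n))
                      })
  m
}

#' @rdname mesh_sphere
#' @param half_x,half_z plane half-extents (mm)
#' @param nx,nz grid resolution (cells per side)
#' @param y0 plane height (mm)
#' @param normal `"+y"` or `"-y"` outward normal
#' @export
mesh_plane <- function(half_x = 10, half_z = 10, nx = 16, nz = 16, y0 = 0,
                       normal = "+y") {
  xs <- seq(-half_x, half_x, length.out = nx + 1)
  zs <- seq(-half_z, half_z, length.out = nz + 1)
  px <- matrix(xs, nx + 1, nz + 1)
  pz <- matrix(zs, nx + 1, nz + 1, byrow = TRUE)
  py <- matrix(y0, nx + 1, nz + 1)
  ny <- if (normal == "+y") c(0, 1, 0) else c(0, -1, 0)
  mesh_from_grid(px, py, pz,
                 normal_fun = function(v) matrix(ny, nrow(v), 3, byrow = TRUE))
}

#' Mesh file I/O (OBJ and binary STL)
#'
#' Minimal readers/writers for the two interchange formats used for implant
#' surfaces.  OBJ is plain text (`v`/`f` records); STL is the usual 80-byte
#' header + little-endian binary triangle records.  Coordinates are mm.
#'
#' @param mesh a [surface_mesh()]
#' @param path file path
#' @return `read_*` return a [surface_mesh()]; writers return `path` invisibly
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
read_mesh_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  vm <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[2:4])))
  fm <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p) {
    as.integer(sub("/.*", "", p[2:4]))
  }))
  surface_mesh(vm, fm)
}

#' @rdname write_mesh_obj
#' @export
write_mesh_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(formatC("kneeslope binary STL", width = -80)), con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(mesh$faces))) {
    writeBin(as.numeric(mesh$normals[i, ]), con, size = 4, endian = "little")
    for (j in 1:3)
      writeBin(as.numeric(mesh$vertices[mesh$faces[i, j], ]), con,
               size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
read_mesh_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  verts <- matrix(0, nf * 3, 3)
  norms <- matrix(0, nf, 3)
  for (i in seq_len(nf)) {
    v <- readBin(con, "numeric", 12, size = 4, endian = "little")
    invisible(readBin(con, "raw", 2))
    norms[i, ] <- v[1:3]
    verts[(3 * i - 2):(3 * i), ] <- matrix(v[4:12], 3, 3, byrow = TRUE)
  }
  faces <- matrix(seq_len(nf * 3), ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces, outward_normals = norms)
}
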
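#' Elastic-foundation material specification
#'
#' The articular contact model treats the polyethylene surface as a bed of
#' independent springs of depth `h` on a rigid backing: local pressure depends
#' only on local penetration.  The foundation modulus is
#' `K = E (1 - nu) / ((1 + nu)(1 - 2 nu))`.  Two pressure laws are available:
#' linear `p = K d / h` and the logarithmic (nonlinear) variant
#' `p = -K log(1 - d / h)`, which agree to first order for shallow penetration.
#'
#' Defaults are conventional UHMWPE-like elastic-foundation parameters
#' (E = 463 MPa, nu = 0.46, h = 6 mm, linear law).
#'
#' @param E elastic modulus (MPa)
#' @param nu Poisson ratio (0 <= nu < 0.5)
#' @param h foundation depth (mm)
#' @param law `"linear"` or `"nonlinear"`
#' @return object of class `material_spec`; field `K` holds the foundation
#'   modulus (MPa)
#' @export
material_spec <- function(E = 463, nu = 0.46, h = 6, law = c("linear", "nonlinear")) {
  law <- match.arg(law)
  if (!is.finite(E) || E <= 0) stop("E must be positive")
  if (nu < 0 || nu >= 0.5) stop("nu must be in [0, 0.5)")
  if (!is.finite(h) || h <= 0) stop("h must be positive")
  K <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  structure(list(E = E, nu = nu, h = h, law = law, K = K),
            class = "material_spec")
}

#' Elastic-foundation pressure law
#'
#' @param d penetration depth(s) (mm), `0 <= d < h`
#' @param mat a [material_spec()]
#' @return pressure (MPa), zero at zero depth and strictly increasing
#' @export
pressure_law <- function(d, mat) {
  if (any(d < 0)) stop("penetration depth must be non-negative")
  if (mat$law == "nonlinear") {
    if (any(d >= mat$h)) stop("domain error: d >= h under the nonlinear law")
    -mat$K * log(1 - d / mat$h)
  } else {
    mat$K * d / mat$h
  }
}

#' Penetration depths by normal ray casting
#'
#' For each face centroid of `target`, a ray is cast along the inward face
#' normal (into the target's material); where the opposing surface has
#' interpenetrated, the ray exits through the opposing surface from inside its
#' solid, and the distance to that first intersection is the local penetration
#' depth.  Separated regions report zero.
#'
#' @param target [surface_mesh()] carrying the elastic foundation (depths are
#'   measured at its face centroids)
#' @param opposing [surface_mesh()] of the rigid counter-body, same frame
#' @param h foundation depth (mm); depths reaching `h` are nonphysical and
#'   raise a foundation-exhausted error naming the face
#' @return numeric vector of per-face depths `d_i >= 0` (mm)
#' @export
penetration_depths <- function(target, opposing, h = 6) {
  orig <- face_centroids(target)
  dirs <- -target$normals
  # prune opposing faces against the union AABB of all ray segments
  lo <- pmin(apply(orig, 2, min), apply(orig + dirs * h * 1.001, 2, min)) - 1e-9
  hi <- pmax(apply(orig, 2, max), apply(orig + dirs * h * 1.001, 2, max)) + 1e-9
  fc <- opposing$faces
  vx <- opposing$vertices
  keep <- rep(TRUE, nrow(fc))
  for (j in 1:3) {
    cmin <- pmin(vx[fc[, 1], j], vx[fc[, 2], j], vx[fc[, 3], j])
    cmax <- pmax(vx[fc[, 1], j], vx[fc[, 2], j], vx[fc[, 3], j])
    keep <- keep & cmax >= lo[j] & cmin <= hi[j]
  }
  if (!any(keep)) return(numeric(nrow(orig)))
  # cast slightly beyond the foundation depth so nonphysical penetrations
  # (d >= h) are detected rather than silently missed
  d <- .raycast_depths(orig, dirs, vx, fc[keep, , drop = FALSE], h * 1.001)
  if (any(d >= h - 1e-12)) {
    stop(sprintf("foundation exhausted: penetration >= h on face(s) %s",
                 paste(utils::head(which(d >= h - 1e-12), 5), collapse = ", ")))
  }
  d
}

#' Elastic-foundation contact between two surfaces
#'
#' Computes per-face pressures on `target` via [penetration_depths()] and
#' [pressure_law()], then every contact quantity reported by the analysis:
#' the total contact force vector (the force exerted by the target surface on
#' the opposing body, tibial-frame components anterior/superior/lateral), the
#' contact moment about the tibial frame origin (N m), medial and lateral
#' compartment axial forces, per-compartment and overall centres of pressure,
#' contact area and mean/peak pressure.
#'
#' Compartments split at Z = 0 exactly: a face centroid with Z = 0 counts as
#' medial.  With no contact, forces and area are zero and the CoPs are `NA`
#' (flagged, not an error).
#'
#' @param target,opposing [surface_mesh()] objects in a common frame; `target`
#'   carries the foundation
#' @param mat a [material_spec()]
#' @param frame a [tibial_frame()] about whose origin moments are taken
#' @return object of class `contact_result`
#' @export
compute_contact <- function(target, opposing, mat = material_spec(),
                            frame = tibial_frame()) {
  d <- penetration_depths(target, opposing, mat$h)
  p <- pressure_law(d, mat)
  A <- target$areas
  n <- target$normals
  x <- face_centroids(target)
  f <- p * A * n                                 # per-face force vectors (N)
  F_total <- colSums(f)
  M_total <- colSums(cross3m(sweep(x, 2, frame$origin), f)) / 1000  # N m

  act <- p > 0
  med <- x[, 3] <= 0
  pa <- p * A
  F_med <- sum(f[med, 2])
  F_lat <- sum(f[!med, 2])
  cop <- function(sel) {
    w <- pa[sel]
    if (sum(w) <= 0) return(c(NA_real_, NA_real_, NA_real_))
    colSums(x[sel, , drop = FALSE] * w) / sum(w)
  }
  area <- sum(A[act])
  axial <- F_total[2]
  structure(list(
    pressure = p,
    depth = d,
    force = f,
    F_total = F_total,
    F_medial_PD = F_med,
    F_lateral_PD = F_lat,
    M_total = M_total,
    CoP_medial = cop(act & med),
    CoP_lateral = cop(act & !med),
    CoP_overall = cop(act),
    area = area,
    mean_pressure = if (area > 0) axial / area else 0,
    peak_pressure = if (any(act)) max(p) else 0,
    n_active = sum(act)
  ), class = "contact_result")
}

#' @export
print.contact_result <- function(x, ...) {
  cat("contact_result:\n")
  cat(sprintf("  F_total (A-P, P-D, L-M): %.1f, %.1f, %.1f N\n",
              x$F_total[1], x$F_total[2], x$F_total[3]))
  cat(sprintf("  F_medial/lateral P-D: %.1f / %.1f N\n",
              x$F_medial_PD, x$F_lateral_PD))
  cat(sprintf("  M (A-A, I-E, F-E): %.2f, %.2f, %.2f N m\n",
              x$M_total[1], x$M_total[2], x$M_total[3]))
  cat(sprintf("  area %.1f mm^2, mean p %.2f MPa, peak p %.2f MPa, %d faces\n",
              x$area, x$mean_pressure, x$peak_pressure, x$n_active))
  invisible(x)
}

#' Export a pressure map as per-face CSV
#'
#' Writes `face_id, cx, cy, cz, depth_mm, pressure_MPa` for visualization or
#' downstream processing.
#'
#' @param target the mesh the contact was computed on
#' @param result a [compute_contact()] result
#' @param path output CSV path
#' @export
write_pressure_map <- function(target, result, path) {
  x <- face_centroids(target)
  df <- data.frame(face_id = seq_len(nrow(x)), cx = x[, 1], cy = x[, 2],
                   cz = x[, 3], depth_mm = result$depth,
                   pressure_MPa = result$pressure)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
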
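#' Parametric TKA implant geometry
#'
#' Default geometric parameters for the parametric implant assembly: a
#' femoral component with two biconvex torus-patch condyles and an anterior
#' trochlear groove, a polyethylene tibial inlay with two matching concave
#' dishes, and a spherical-dome patellar button.  All lengths in mm, angles in
#' degrees.  The tibial-inlay dishes are more weakly curved than the condyles
#' (`dish_radius_* >= condyle_radius_*`), reproducing the highly congruent
#' character of the implant system modelled.
#'
#' `elements_per_condyle_width` sets the mesh resolution: the number of
#' elements across the frontal (medio-lateral) width of one condyle; sagittal
#' element counts are derived to give approximately square elements.
#'
#' @param condyle_radius_sag,condyle_radius_fro femoral condyle sagittal and
#'   frontal radii (mm); sagittal must exceed frontal
#' @param dish_radius_sag,dish_radius_fro inlay dish radii (mm); each must be
#'   at least the corresponding condylar radius (congruency)
#' @param condyle_spacing distance between condyle (and dish) centre planes (mm)
#' @param dish_half_angle_sag,dish_half_angle_fro angular half-extents of each
#'   dish patch (deg)
#' @param condyle_alpha_range sagittal angular range of the condylar patch
#'   (deg; 0 = straight down at full extension, negative = posterior)
#' @param condyle_half_angle_fro frontal half-extent of each condyle (deg)
#' @param trochlea_radius radius of the trochlear groove floor from the femoral
#'   flexion axis (mm)
#' @param trochlea_groove_radius transverse radius of the groove (mm); must be
#'   at least `button_radius`
#' @param trochlea_gamma_range sagittal angular range of the groove (deg;
#'   90 = straight anterior)
#' @param trochlea_half_angle_fro frontal half-extent of the groove (deg)
#' @param button_radius patellar button dome radius (mm)
#' @param button_half_angle dome cap half-angle (deg)
#' @param button_station sagittal station of the patella at full extension
#'   (deg, same convention as `trochlea_gamma_range`)
#' @param inlay_thickness_h inlay thickness from baseplate to rim (mm)
#' @param dish_bottom_y height of the dish floor above the baseplate plane (mm)
#' @param varus_deg coronal tilt of the inlay (deg); default 0 isolates
#'   sagittal effects
#' @param elements_per_condyle_width mesh resolution (>= 8)
#' @return a list of class `geometry_params`
#' @export
geometry_params <- function(condyle_radius_sag = 30,
                            condyle_radius_fro = 20,
                            dish_radius_sag = 32,
                            dish_radius_fro = 22,
                            condyle_spacing = 46,
                            dish_half_angle_sag = 40,
                            dish_half_angle_fro = 40,
                            condyle_alpha_range = c(-140, 60),
                            condyle_half_angle_fro = 45,
                            trochlea_radius = 32,
                            trochlea_groove_radius = 18,
                            trochlea_gamma_range = c(-30, 100),
                            trochlea_half_angle_fro = 45,
                            button_radius = 12,
                            button_half_angle = 65,
                            button_station = 75,
                            inlay_thickness_h = 12,
                            dish_bottom_y = 6,
                            varus_deg = 0,
                            elements_per_condyle_width = 12) {
  p <- as.list(environment())
  # YAML round trips deliver length-2 ranges as lists; normalise
  p$condyle_alpha_range <- as.numeric(unlist(p$condyle_alpha_range))
  p$trochlea_gamma_range <- as.numeric(unlist(p$trochlea_gamma_range))
  class(p) <- "geometry_params"
  validate_geometry_params(p)
  p
}

validate_geometry_params <- function(p) {
  pos <- c("condyle_radius_sag", "condyle_radius_fro", "dish_radius_sag",
           "dish_radius_fro", "condyle_spacing", "trochlea_radius",
           "trochlea_groove_radius", "button_radius", "inlay_thickness_h")
  for (nm in pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("invalid parameter: ", nm, " must be positive")
  if (p$condyle_radius_sag <= p$condyle_radius_fro)
    stop("invalid parameter: condyle sagittal radius must exceed frontal radius")
  if (p$dish_radius_sag < p$condyle_radius_sag ||
      p$dish_radius_fro < p$condyle_radius_fro)
    stop("congruency error: dish radii must be at least the condyle radii")
  if (p$trochlea_groove_radius < p$button_radius)
    stop("congruency error: trochlear groove radius must be at least the button radius")
  if (p$elements_per_condyle_width < 8)
    stop("invalid parameter: at least 8 elements per condyle width required")
  invisible(p)
}

#' Tibial reference frame
#'
#' Right-handed orthonormal frame fixed to the tibial component: X anterior,
#' Y superior, Z lateral (right knee).  Contact moments are reported about its
#' origin, which the parametric builder places at the centroid of the inlay
#' superior rim projected onto the baseplate plane.
#'
#' @param origin 3-vector (mm)
#' @param axes 3x3 matrix whose columns are the X, Y, Z directions
#' @return object of class `tibial_frame`
#' @export
tibial_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  stopifnot(length(origin) == 3, all(dim(axes) == c(3, 3)))
  if (max(abs(crossprod(axes) - diag(3))) > 1e-10)
    stop("frame axes must be orthonormal")
  if (det(axes) < 0)
    stop("frame must be right-handed")
  structure(list(origin = as.numeric(origin), axes = axes),
            class = "tibial_frame")
}

#' Alignment specification
#'
#' @param pts_deg posterior tibial slope (deg; positive tilts the posterior
#'   inlay edge inferiorly).  Guard-railed to +/- 30 deg.
#' @param varus_deg coronal tilt (deg)
#' @param baseline_pts_deg reference slope for sweep reporting (deg)
#' @return object of class `alignment_spec`
#' @export
alignment_spec <- function(pts_deg = 0, varus_deg = 0, baseline_pts_deg = 7) {
  if (abs(pts_deg) > 30) stop("guard rail: |pts_deg| must not exceed 30 degrees")
  structure(list(pts_deg = pts_deg, varus_deg = varus_deg,
                 baseline_pts_deg = baseline_pts_deg),
            class = "alignment_spec")
}

# sagittal radial direction: r_hat(a) points straight down at a = 0 and
# anteriorly at a = +90 deg
r_hat <- function(a) cbind(sin(a), -cos(a), 0)

# Torus patch about an axis parallel to Z through (0, yc, zc): sagittal angles
# alpha, frontal (tube) angles psi.  Three articular types:
#   convex: femoral condyle, main radius a0, tube rt, material inside the tube;
#   dish:   same surface as convex but material outside (tibial dish, normals
#           point up toward the tube centre circle);
#   groove: trochlear channel, floor at radius a0 from the axis, transverse
#           radius rt whose cross-section centre lies outside at a0 + rt
#           (convex sagittally, concave transversely).
torus_patch <- function(a0, rt, alpha, psi, yc, zc,
                        type = c("convex", "dish", "groove")) {
  type <- match.arg(type)
  na <- length(alpha); np <- length(psi)
  A <- matrix(alpha, na, np)
  P <- matrix(psi, na, np, byrow = TRUE)
  rad <- if (type == "groove") a0 + rt * (1 - cos(P)) else a0 + rt * cos(P)
  px <- rad * sin(A)
  py <- yc - rad * cos(A)
  pz <- zc + rt * sin(P)
  normal_fun <- function(v) {
    x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
    aa <- atan2(x, -(y - yc))
    rr <- sqrt(x^2 + (y - yc)^2)
    sp <- (z - zc) / rt
    if (type == "groove") {
      cp <- (a0 + rt - rr) / rt
      n <- cbind(cp * sin(aa), -cp * cos(aa), -sp)
    } else {
      cp <- (rr - a0) / rt
      n <- cbind(cp * sin(aa), -cp * cos(aa), sp)
      if (type == "dish") n <- -n
    }
    n / sqrt(rowSums(n * n))
  }
  mesh_from_grid(px, py, pz, normal_fun = normal_fun)
}

angular_counts <- function(arc_mm, cell_mm) max(4L, as.integer(ceiling(arc_mm / cell_mm)))

#' Build the parametric implant assembly
#'
#' Constructs the femoral component (two condyles + trochlear groove), tibial
#' inlay (two dishes), and patellar button as triangle meshes, expressed in
#' the tibial frame, at the as-built pose: knee at full extension, condyles
#' exactly touching the dish floors, button exactly touching the groove floor,
#' posterior tibial slope 0.  Use [apply_pts()] for virtual implantation at a
#' commanded slope.
#'
#' The femoral component is meshed in femur-local coordinates (origin on the
#' flexion axis midway between the condyles) and stored posed at extension;
#' the femur-local meshes are kept alongside for efficient re-posing.
#'
#' @param geom a [geometry_params()] list
#' @return object of class `implant_assembly` with fields `femoral`, `inlay`,
#'   `patellar_button`, `frame`, `alignment`, `inlay_thickness_h`, plus
#'   femur-local part meshes under `$local` and key landmark coordinates under
#'   `$landmarks`
#' @export
build_parametric_assembly <- function(geom = geometry_params()) {
  if (!inherits(geom, "geometry_params")) geom <- do.call(geometry_params, geom)
  validate_geometry_params(geom)
  g <- geom
  cell <- (2 * deg2rad(g$condyle_half_angle_fro) * g$condyle_radius_fro) /
    g$elements_per_condyle_width

  a_c <- g$condyle_radius_sag - g$condyle_radius_fro
  a_d <- g$dish_radius_sag - g$dish_radius_fro
  s2 <- g$condyle_spacing / 2

  # femoral condyles, femur-local (flexion axis = local Z through origin)
  ar <- deg2rad(g$condyle_alpha_range)
  n_as <- angular_counts(diff(ar) * g$condyle_radius_sag, cell)
  n_fr <- angular_counts(2 * deg2rad(g$condyle_half_angle_fro) * g$condyle_radius_fro, cell)
  alpha_c <- seq(ar[1], ar[2], length.out = n_as + 1)
  psi_c <- seq(-deg2rad(g$condyle_half_angle_fro), deg2rad(g$condyle_half_angle_fro),
               length.out = n_fr + 1)
  med_condyle <- torus_patch(a_c, g$condyle_radius_fro, alpha_c, psi_c, 0, -s2)
  lat_condyle <- torus_patch(a_c, g$condyle_radius_fro, alpha_c, psi_c, 0, +s2)

  # trochlear groove, femur-local (concave channel for the patellar button)
  gr <- deg2rad(g$trochlea_gamma_range)
  n_gs <- angular_counts(diff(gr) * g$trochlea_radius, cell)
  n_gf <- angular_counts(2 * deg2rad(g$trochlea_half_angle_fro) * g$trochlea_groove_radius, cell)
  gamma_t <- seq(gr[1], gr[2], length.out = n_gs + 1)
  psi_t <- seq(-deg2rad(g$trochlea_half_angle_fro), deg2rad(g$trochlea_half_angle_fro),
               length.out = n_gf + 1)
  trochlea <- torus_patch(g$trochlea_radius, g$trochlea_groove_radius,
                          gamma_t, psi_t, 0, 0, type = "groove")

  # tibial inlay dishes (tibial frame); dish floor at y = dish_bottom_y
  dr <- deg2rad(g$dish_half_angle_sag)
  n_ds <- angular_counts(2 * dr * g$dish_radius_sag, cell)
  n_df <- angular_counts(2 * deg2rad(g$dish_half_angle_fro) * g$dish_radius_fro, cell)
  alpha_d <- seq(-dr, dr, length.out = n_ds + 1)
  psi_d <- seq(-deg2rad(g$dish_half_angle_fro), deg2rad(g$dish_half_angle_fro),
               length.out = n_df + 1)
  yc_d <- g$dish_bottom_y + g$dish_radius_sag
  med_dish <- torus_patch(a_d, g$dish_radius_fro, alpha_d, psi_d, yc_d, -s2,
                          type = "dish")
  lat_dish <- torus_patch(a_d, g$dish_radius_fro, alpha_d, psi_d, yc_d, +s2,
                          type = "dish")
  if (g$varus_deg != 0) {
    Rv <- rot_x(deg2rad(g$varus_deg))
    med_dish <- transform_mesh(med_dish, Rv)
    lat_dish <- transform_mesh(lat_dish, Rv)
  }
  inlay <- merge_meshes(med_dish, lat_dish)

  # patellar button, patella-local: dome about -X (posterior-facing)
  bh <- deg2rad(g$button_half_angle)
  n_bt <- angular_counts(bh * g$button_radius, cell / 1.5)
  th <- seq(1e-4, bh, length.out = n_bt + 1)
  ph <- seq(0, 2 * pi, length.out = 4 * n_bt + 1)
  TH <- matrix(th, length(th), length(ph))
  PH <- matrix(ph, length(th), length(ph), byrow = TRUE)
  bx <- -g$button_radius * cos(TH)
  by <- g$button_radius * sin(TH) * cos(PH)
  bz <- g$button_radius * sin(TH) * sin(PH)
  button <- mesh_from_grid(bx, by, bz,
                           normal_fun = function(v) v / sqrt(rowSums(v * v)))

  # reference pose at full extension: condyle floors touch dish floors
  femur_origin <- c(0, g$dish_bottom_y + g$condyle_radius_sag, 0)
  # patella base pose (femur-local): button centre nested on the groove floor
  g0 <- deg2rad(g$button_station)
  patella_base_pos <- as.numeric((g$trochlea_radius + g$button_radius) * r_hat(g0))
  patella_base_rot <- rot_z(g0 - pi / 2)

  frame <- tibial_frame()
  landmarks <- list(
    femur_origin = femur_origin,
    patella_base_pos = patella_base_pos,
    patella_base_rot = patella_base_rot,
    epicondyle_z = s2 + g$condyle_radius_fro + 4,
    condyle_spacing = g$condyle_spacing
  )

  local <- list(med_condyle = med_condyle, lat_condyle = lat_condyle,
                condyles = merge_meshes(med_condyle, lat_condyle),
                trochlea = trochlea, button = button)
  pose0 <- list(R = diag(3), t = femur_origin)
  femoral <- transform_mesh(merge_meshes(med_condyle, lat_condyle, trochlea),
                            pose0$R, pose0$t)

  cache <- list(inlay_med = mesh_cache(med_dish), inlay_lat = mesh_cache(lat_dish),
                med_condyle = mesh_cache(med_condyle),
                lat_condyle = mesh_cache(lat_condyle),
                trochlea = mesh_cache(trochlea), button = mesh_cache(button))

  structure(list(femoral = femoral,
                 inlay = inlay,
                 patellar_button = button,
                 frame = frame,
                 alignment = alignment_spec(pts_deg = 0, varus_deg = g$varus_deg),
                 inlay_thickness_h = g$inlay_thickness_h,
                 local = local,
                 cache = cache,
                 landmarks = landmarks,
                 geom = g),
            class = "implant_assembly")
}

merge_meshes <- function(...) {
  parts <- list(...)
  off <- 0L
  verts <- list(); faces <- list()
  for (m in parts) {
    verts[[length(verts) + 1]] <- m$vertices
    faces[[length(faces) + 1]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  v <- do.call(rbind, verts)
  f <- do.call(rbind, faces)
  n <- do.call(rbind, lapply(parts, `[[`, "normals"))
  surface_mesh(v, f, outward_normals = n)
}

#' @export
print.implant_assembly <- function(x, ...) {
  cat("implant_assembly (parametric TKA components, tibial frame, mm)\n")
  cat(sprintf("  femoral:  %d faces | inlay: %d faces | button: %d faces\n",
              nrow(x$femoral$faces), nrow(x$inlay$faces),
              nrow(x$patellar_button$faces)))
  cat(sprintf("  alignment: PTS %.1f deg (baseline %.1f), varus %.1f deg\n",
              x$alignment$pts_deg, x$alignment$baseline_pts_deg,
              x$alignment$varus_deg))
  invisible(x)
}

#' Virtual implantation at a commanded posterior tibial slope
#'
#' Rigidly rotates the tibial inlay about the tibial frame's Z (medio-lateral)
#' axis through the frame origin, so that for positive `pts_deg` a point on
#' the posterior inlay edge moves inferiorly.  The femoral component and
#' patellar button are untouched.  The rotation is incremental (a group
#' action): applying `+5` then `-5` degrees restores the original mesh.
#'
#' @param assembly an [build_parametric_assembly()] result
#' @param pts_deg slope increment to apply (deg); guard-railed to +/- 30
#' @return the assembly with rotated inlay and updated `alignment$pts_deg`
#' @export
apply_pts <- function(assembly, pts_deg) {
  stopifnot(inherits(assembly, "implant_assembly"))
  if (abs(pts_deg) > 30) stop("guard rail: |pts_deg| must not exceed 30 degrees")
  R <- rot_z(deg2rad(pts_deg))
  o <- assembly$frame$origin
  t <- o - as.numeric(R %*% o)
  assembly$inlay <- transform_mesh(assembly$inlay, R, t)
  for (nm in c("inlay_med", "inlay_lat")) {
    cc <- assembly$cache[[nm]]
    cc$V <- transform_points(cc$V, R, t)
    cc$C <- transform_points(cc$C, R, t)
    cc$N <- cc$N %*% t(R)
    assembly$cache[[nm]] <- cc
  }
  assembly$alignment$pts_deg <- assembly$alignment$pts_deg + pts_deg
  assembly
}

#' Posterior-tibial-slope sweep values
#'
#' Arithmetic sequence of slope angles centred on a baseline implantation,
#' e.g. `sweep_alignments(7, 12, 2)` spans -5 to 19 degrees in 13 steps.
#'
#' @param baseline_pts baseline slope (deg)
#' @param half_range half-width of the sweep (deg); must be a multiple of `step`
#' @param step increment (deg), > 0
#' @return ascending numeric vector of slope angles (deg)
#' @export
sweep_alignments <- function(baseline_pts = 7, half_range = 12, step = 2) {
  if (!is.finite(step) || step <= 0) stop("invalid parameter: step must be > 0")
  if (abs(half_range / step - round(half_range / step)) > 1e-9)
    stop("invalid parameter: half_range must be a multiple of step")
  seq(baseline_pts - half_range, baseline_pts + half_range, by = step)
}
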
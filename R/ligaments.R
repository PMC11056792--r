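#' Ligament bundle
#'
#' One soft-tissue structure modelled as parallel tension-only nonlinear
#' strands (Blankevoort-type piecewise force law).  Attachment coordinates are
#' body-local: tibial points in the tibial frame, femoral points in the
#' femur-local frame (origin on the flexion axis), patellar points in the
#' patella-local frame (origin at the button dome centre).
#'
#' @param name bundle name (sMCL, dMCL, ITB, pCAP, PFL, POL, LCL, mPFL, lPFL, PT)
#' @param origin_body,insertion_body `"femur"`, `"tibia"` or `"patella"`
#' @param origin,insertion n x 3 matrices of strand attachment points (mm)
#' @param k per-strand stiffness (N per unit strain), recycled to n strands
#' @param eps_l transition strain of the piecewise law (dimensionless)
#' @param eps_ref reference strain the bundle is calibrated to carry at full
#'   extension
#' @param l0 per-strand slack lengths (mm); `NA` until calibrated
#' @return object of class `ligament_bundle`
#' @export
ligament_bundle <- function(name, origin_body, origin, insertion_body, insertion,
                            k, eps_l = 0.03, eps_ref = 0.02, l0 = NA_real_) {
  origin <- matrix(as.numeric(origin), ncol = 3)
  insertion <- matrix(as.numeric(insertion), ncol = 3)
  n <- nrow(origin)
  stopifnot(nrow(insertion) == n, n >= 1)
  k <- rep_len(k, n)
  l0 <- rep_len(l0, n)
  if (any(k <= 0)) stop("stiffness k must be positive")
  if (eps_l <= 0 || eps_l >= 0.1) stop("transition strain must be in (0, 0.1)")
  if (any(!is.na(l0) & l0 <= 0)) stop("slack lengths must be positive")
  structure(list(name = name, origin_body = origin_body, origin = origin,
                 insertion_body = insertion_body, insertion = insertion,
                 k = k, eps_l = eps_l, eps_ref = eps_ref, l0 = l0),
            class = "ligament_bundle")
}

#' Blankevoort piecewise strand force
#'
#' Tension-only spring with a quadratic toe region blending into a linear
#' branch: with strain `e = (length - l0) / l0`,
#' `f = 0` for `e <= 0`; `f = k e^2 / (4 eps_l)` for `0 < e <= 2 eps_l`;
#' `f = k (e - eps_l)` beyond.  Value and first derivative are continuous at
#' the transition.
#'
#' @param k stiffness (N per unit strain)
#' @param l0 slack length (mm)
#' @param eps_l transition strain
#' @param length current strand length (mm), > 0
#' @return force (N), >= 0
#' @export
strand_force <- function(k, l0, eps_l, length) {
  if (any(length <= 0)) stop("strand length must be positive")
  e <- (length - l0) / l0
  f <- ifelse(e <= 0, 0,
              ifelse(e <= 2 * eps_l, k * e^2 / (4 * eps_l), k * (e - eps_l)))
  pmax(f, 0)
}

#' Default soft-tissue set for the parametric knee
#'
#' Places the ten modelled structures (sMCL, dMCL, ITB, pCAP, PFL, POL, LCL,
#' mPFL, lPFL, PT) parametrically on the implant assembly: collaterals at the
#' epicondylar planes derived from the condyle spacing, posterior structures
#' behind the flexion axis, patellar ligaments between the epicondyles and the
#' button rim, and a three-strand patellar tendon to the tibial tuberosity.
#' Stiffnesses are literature-order defaults and fully configurable; the
#' calibration step (not the raw stiffness table) fixes the operating point.
#'
#' @param assembly a [build_parametric_assembly()] result
#' @param stiffness optional named list overriding per-strand stiffnesses (N
#'   per unit strain)
#' @return named list of [ligament_bundle()] objects
#' @export
default_ligaments <- function(assembly, stiffness = list()) {
  ez <- assembly$landmarks$epicondyle_z     # lateral epicondyle |z|
  kdef <- list(sMCL = 917, dMCL = 500, LCL = 2000, POL = 750, pCAP = 500,
               PFL = 1000, ITB = 2000, mPFL = 400, lPFL = 400, PT = 1333)
  for (nm in names(stiffness)) kdef[[nm]] <- stiffness[[nm]]

  b <- list()
  b$sMCL <- ligament_bundle("sMCL", "femur",
    cbind(c(-5, 0, 5), 2, -ez), "tibia", cbind(c(-5, 0, 5), -30, -(ez - 3)),
    k = kdef$sMCL)
  b$dMCL <- ligament_bundle("dMCL", "femur",
    cbind(c(-3, 3), 0, -(ez - 1)), "tibia", cbind(c(-3, 3), -12, -(ez - 2)),
    k = kdef$dMCL)
  b$LCL <- ligament_bundle("LCL", "femur",
    cbind(0, 2, ez), "tibia", cbind(-5, -35, ez - 1), k = kdef$LCL)
  b$POL <- ligament_bundle("POL", "femur",
    cbind(c(-8, -12), 0, -(ez - 2)), "tibia", cbind(c(-15, -18), -15, -(ez - 7)),
    k = kdef$POL)
  b$pCAP <- ligament_bundle("pCAP", "femur",
    cbind(-18, 0, c(-30, -10, 10, 30)), "tibia", cbind(-22, -10, c(-30, -10, 10, 30)),
    k = kdef$pCAP)
  b$PFL <- ligament_bundle("PFL", "femur",
    cbind(-5, 0, ez - 2), "tibia", cbind(-12, -30, ez - 3), k = kdef$PFL)
  b$ITB <- ligament_bundle("ITB", "femur",
    cbind(0, 60, ez + 1), "tibia", cbind(15, -20, ez - 7), k = kdef$ITB)
  b$mPFL <- ligament_bundle("mPFL", "femur",
    cbind(0, c(5, -2), -ez), "patella", cbind(0, c(4, -4), -13), k = kdef$mPFL)
  b$lPFL <- ligament_bundle("lPFL", "femur",
    cbind(0, c(5, -2), ez), "patella", cbind(0, c(4, -4), 13), k = kdef$lPFL)
  b$PT <- ligament_bundle("PT", "patella",
    cbind(0, -15, c(-6, 0, 6)), "tibia", cbind(35, -30, c(-4.8, 0, 4.8)),
    k = kdef$PT)
  b
}

# world coordinates of a body-local point set given body poses; the tibia is
# normally the ground (identity pose) but is transformed like any other body
# so that whole-model frame indifference holds
map_points <- function(points, body, poses) {
  p <- poses[[body]]
  transform_points(points, p$R, p$t)
}

# strand lengths of one bundle at given poses
bundle_lengths <- function(bundle, poses) {
  o <- map_points(bundle$origin, bundle$origin_body, poses)
  i <- map_points(bundle$insertion, bundle$insertion_body, poses)
  sqrt(rowSums((o - i)^2))
}

#' Calibrate slack lengths to the reference strain at full extension
#'
#' Sets every strand's slack length to `L_fe / (1 + eps_ref)`, where `L_fe` is
#' the strand length at the full-extension pose, so the recomputed strain at
#' that pose equals the reference strain exactly.  Idempotent: the
#' full-extension lengths do not depend on `l0`.
#'
#' @param bundles named list of [ligament_bundle()] objects
#' @param full_extension_poses body poses at the full-extension reference pose
#'   (as produced by [body_poses()] at the zero state)
#' @param eps_ref reference strain (default 0.02, i.e. 2 percent)
#' @return the bundle list with `l0` filled in
#' @export
calibrate_slack_lengths <- function(bundles, full_extension_poses, eps_ref = 0.02) {
  lapply(bundles, function(b) {
    L <- bundle_lengths(b, full_extension_poses)
    if (any(L <= 0)) stop("geometry error: zero strand length at full extension")
    b$l0 <- L / (1 + eps_ref)
    b$eps_ref <- eps_ref
    b
  })
}

# per-strand force entries for the equilibrium assembly: returns a list of
# force applications (body, point, force) for femur/patella attachments, and
# per-bundle total tension
ligament_force_entries <- function(bundles, poses) {
  apps <- list()
  tension <- setNames(numeric(length(bundles)), names(bundles))
  for (nm in names(bundles)) {
    b <- bundles[[nm]]
    if (any(is.na(b$l0))) stop("ligaments not calibrated (l0 missing in ", nm, ")")
    o <- map_points(b$origin, b$origin_body, poses)
    i <- map_points(b$insertion, b$insertion_body, poses)
    d <- o - i
    L <- sqrt(rowSums(d^2))
    if (any(L <= 0)) stop("geometry error: coincident ligament endpoints in ", nm)
    f <- strand_force(b$k, b$l0, b$eps_l, L)
    tension[nm] <- sum(f)
    u <- d / L
    for (s in seq_len(nrow(o))) {
      if (f[s] == 0) next
      if (b$insertion_body != "tibia")
        apps[[length(apps) + 1]] <- list(body = b$insertion_body,
                                         point = i[s, ], force = f[s] * u[s, ])
      if (b$origin_body != "tibia")
        apps[[length(apps) + 1]] <- list(body = b$origin_body,
                                         point = o[s, ], force = -f[s] * u[s, ])
    }
  }
  list(applications = apps, tension = tension)
}

#' Net ligament wrench about the tibial frame origin
#'
#' Sums per-strand forces (directed along the insertion-to-origin unit vector,
#' applied at the insertion) over all bundles, for the insertion bodies.
#'
#' @param bundles named list of calibrated [ligament_bundle()] objects
#' @param poses body poses (see [body_poses()])
#' @param frame a [tibial_frame()]
#' @return list with `force` (N), `moment` (N m, about the frame origin) and
#'   `per_bundle` total tensions (N)
#' @export
total_ligament_wrench <- function(bundles, poses, frame = tibial_frame()) {
  F <- c(0, 0, 0); M <- c(0, 0, 0)
  tension <- setNames(numeric(length(bundles)), names(bundles))
  for (nm in names(bundles)) {
    b <- bundles[[nm]]
    o <- map_points(b$origin, b$origin_body, poses)
    i <- map_points(b$insertion, b$insertion_body, poses)
    d <- o - i
    L <- sqrt(rowSums(d^2))
    if (any(L <= 0)) stop("geometry error: coincident ligament endpoints in ", nm)
    f <- strand_force(b$k, b$l0, b$eps_l, L)
    tension[nm] <- sum(f)
    u <- d / L
    for (s in seq_len(nrow(o))) {
      fs <- f[s] * u[s, ]
      F <- F + fs
      M <- M + cross3(i[s, ] - frame$origin, fs)
    }
  }
  list(force = F, moment = M / 1000, per_bundle = tension)
}

#' Ligament table I/O
#'
#' Round-trips the bundle set as a plain CSV with one row per strand:
#' `name, strand, origin_body, ox, oy, oz, insertion_body, ix, iy, iz, k,
#' eps_l, eps_ref, l0`.
#'
#' @param bundles named list of [ligament_bundle()]s
#' @param path CSV path
#' @export
write_ligament_table <- function(bundles, path) {
  rows <- lapply(bundles, function(b) {
    data.frame(name = b$name, strand = seq_len(nrow(b$origin)),
               origin_body = b$origin_body,
               ox = b$origin[, 1], oy = b$origin[, 2], oz = b$origin[, 3],
               insertion_body = b$insertion_body,
               ix = b$insertion[, 1], iy = b$insertion[, 2], iz = b$insertion[, 3],
               k = b$k, eps_l = b$eps_l, eps_ref = b$eps_ref, l0 = b$l0)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ligament_table
#' @export
read_ligament_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (nm in unique(df$name)) {
    d <- df[df$name == nm, , drop = FALSE]
    out[[nm]] <- ligament_bundle(nm, d$origin_body[1],
                                 cbind(d$ox, d$oy, d$oz), d$insertion_body[1],
                                 cbind(d$ix, d$iy, d$iz), k = d$k,
                                 eps_l = d$eps_l[1], eps_ref = d$eps_ref[1],
                                 l0 = d$l0)
  }
  out
}
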
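#' Muscle actuator
#'
#' Knee-crossing muscle-tendon unit with a geometric path (ordered
#' body-attached points, optional cylinder wrap), rigid tendon and
#' activation-proportional force `F = a Fmax`.
#'
#' @param name actuator name
#' @param Fmax maximum isometric force (N)
#' @param path data.frame with columns `body` (`"femur"`, `"tibia"`,
#'   `"patella"`), `x`, `y`, `z` (body-local mm), in origin-to-insertion order
#' @param wrap optional cylinder wrap: list with `body`, `point` (3-vector on
#'   the axis), `axis` (3-vector direction), `radius` (mm), `between`
#'   (indices of the two path points the wrap acts between)
#' @param via_patella logical; TRUE for extensor-mechanism muscles inserting
#'   on the patella (their knee-flexion moment arm is evaluated through the
#'   patellar tendon excursion, see the package vignette)
#' @param const_moment_arm_mm optional fixed knee-flexion moment arm (mm)
#'   bypassing the geometric path; used for reduced test models
#' @return object of class `muscle_actuator`
#' @export
muscle_actuator <- function(name, Fmax, path = NULL, wrap = NULL,
                            via_patella = FALSE, const_moment_arm_mm = NULL) {
  if (!is.finite(Fmax) || Fmax <= 0) stop("Fmax must be positive")
  if (is.null(const_moment_arm_mm)) {
    stopifnot(is.data.frame(path), nrow(path) >= 2,
              all(c("body", "x", "y", "z") %in% names(path)))
  }
  if (!is.null(wrap)) {
    if (wrap$radius <= 0) stop("wrap radius must be positive")
    wrap$axis <- unitize(wrap$axis)
  }
  structure(list(name = name, Fmax = Fmax, path = path, wrap = wrap,
                 via_patella = via_patella,
                 const_moment_arm_mm = const_moment_arm_mm),
            class = "muscle_actuator")
}

#' Default knee-crossing actuator set
#'
#' Reduced actuator set acting across the knee: lumped vasti and rectus
#' femoris (inserting on the patella, wrapping the anterior femur), medial and
#' lateral hamstrings, and medial and lateral gastrocnemius.  Only
#' knee-crossing units enter the knee equilibrium; proximal segments are
#' abstracted into femur-fixed origins.  Maximum isometric forces are
#' configurable defaults, not ground truth.
#'
#' @param assembly a [build_parametric_assembly()] result
#' @param Fmax optional named list overriding maximum isometric forces (N)
#' @return named list of [muscle_actuator()] objects
#' @export
default_muscles <- function(assembly, Fmax = list()) {
  fdef <- list(vasti = 6000, rectus_femoris = 1200, hamstrings_med = 1500,
               hamstrings_lat = 1500, gastroc_med = 1500, gastroc_lat = 1500)
  for (nm in names(Fmax)) fdef[[nm]] <- Fmax[[nm]]
  quad_wrap <- list(body = "femur", point = c(0, 0, 0), axis = c(0, 0, 1),
                    radius = assembly$geom$trochlea_radius + 2, between = c(1, 2))
  path <- function(...) {
    m <- rbind(...)
    data.frame(body = m[, 1], x = as.numeric(m[, 2]), y = as.numeric(m[, 3]),
               z = as.numeric(m[, 4]), stringsAsFactors = FALSE)
  }
  list(
    vasti = muscle_actuator("vasti", fdef$vasti,
      path(c("femur", 10, 70, 0), c("patella", 0, 15, 0)),
      wrap = quad_wrap, via_patella = TRUE),
    rectus_femoris = muscle_actuator("rectus_femoris", fdef$rectus_femoris,
      path(c("femur", 14, 80, 0), c("patella", 0, 15, 0)),
      wrap = quad_wrap, via_patella = TRUE),
    hamstrings_med = muscle_actuator("hamstrings_med", fdef$hamstrings_med,
      path(c("femur", -15, 70, -8), c("tibia", -25, -25, -18))),
    hamstrings_lat = muscle_actuator("hamstrings_lat", fdef$hamstrings_lat,
      path(c("femur", -15, 70, 8), c("tibia", -25, -25, 18))),
    gastroc_med = muscle_actuator("gastroc_med", fdef$gastroc_med,
      path(c("femur", -20, 5, -16), c("tibia", -15, -80, -5))),
    gastroc_lat = muscle_actuator("gastroc_lat", fdef$gastroc_lat,
      path(c("femur", -20, 5, 16), c("tibia", -15, -80, 5)))
  )
}

# Shortest path from p1 to p2 around a cylinder (axis through c0 along u_axis,
# radius r), obstacle-set style: work in the plane perpendicular to the axis,
# straight tangents plus a circular arc, with the axial coordinate distributed
# over the in-plane arc length.  Returns list(length, nodes) where nodes are
# the 3D tangent points (NULL if the wrap is not engaged).
cylinder_wrap_path <- function(p1, p2, c0, u_axis, r) {
  e1 <- unitize(if (abs(u_axis[1]) < 0.9) cross3(u_axis, c(1, 0, 0)) else
                  cross3(u_axis, c(0, 1, 0)))
  e1 <- unitize(cross3(e1, u_axis))
  e2 <- cross3(u_axis, e1)
  q1 <- c(sum((p1 - c0) * e1), sum((p1 - c0) * e2))
  q2 <- c(sum((p2 - c0) * e1), sum((p2 - c0) * e2))
  z1 <- sum((p1 - c0) * u_axis); z2 <- sum((p2 - c0) * u_axis)

  # endpoints must lie outside the cylinder; shallow violations (a moving
  # attachment grazing the surface during equilibrium iterations) are clamped
  # radially, deep ones are a genuine path-construction error
  for (qn in c("q1", "q2")) {
    q <- get(qn)
    rho <- sqrt(sum(q^2))
    if (rho < r) {
      if (rho < 0.8 * r)
        stop("geometry error: muscle path point inside wrap cylinder")
      assign(qn, q * (1.001 * r / rho))
    }
  }
  # distance from the 2D segment q1-q2 to the origin
  dq <- q2 - q1
  tt <- max(0, min(1, -sum(q1 * dq) / sum(dq * dq)))
  dmin <- sqrt(sum((q1 + tt * dq)^2))
  if (dmin >= r)
    return(list(length = sqrt(sum((p2 - p1)^2)), nodes = NULL, engaged = FALSE))

  tangent_pts <- function(q) {
    d2 <- sum(q^2); d <- sqrt(d2)
    l <- sqrt(d2 - r^2)
    # angles of the two tangent points
    base <- atan2(q[2], q[1])
    dphi <- acos(r / d)
    list(phi = c(base + dphi, base - dphi), tangent_len = l)
  }
  t1 <- tangent_pts(q1); t2 <- tangent_pts(q2)
  best <- NULL
  for (ph1 in t1$phi) for (ph2 in t2$phi) {
    w1q <- r * c(cos(ph1), sin(ph1)); w2q <- r * c(cos(ph2), sin(ph2))
    u1 <- unitize(c(w1q - q1, 0))[1:2]   # travel direction entering the arc
    u2 <- unitize(c(q2 - w2q, 0))[1:2]   # travel direction leaving the arc
    darc <- (ph2 - ph1) %% (2 * pi)
    for (arc in c(darc, darc - 2 * pi)) {
      if (abs(arc) < 1e-12) next
      s <- sign(arc)
      # tangency consistency: straight parts must blend C1 into the arc
      tan1 <- s * c(-sin(ph1), cos(ph1))
      tan2 <- s * c(-sin(ph2), cos(ph2))
      if (sum(u1 * tan1) < 0.999 || sum(u2 * tan2) < 0.999) next
      Ltot <- t1$tangent_len + t2$tangent_len + r * abs(arc)
      if (is.null(best) || Ltot < best$L) best <- list(L = Ltot, ph1 = ph1,
                                                       ph2 = ph2, arc = arc)
    }
  }
  if (is.null(best))
    return(list(length = sqrt(sum((p2 - p1)^2)), nodes = NULL, engaged = FALSE))
  w1 <- c0 + r * cos(best$ph1) * e1 + r * sin(best$ph1) * e2
  w2 <- c0 + r * cos(best$ph2) * e1 + r * sin(best$ph2) * e2
  # distribute the axial travel over the in-plane path length
  L2d <- best$L
  s1 <- t1$tangent_len / L2d
  s2 <- (t1$tangent_len + r * abs(best$arc)) / L2d
  dz <- z2 - z1
  w1 <- w1 + (z1 + s1 * dz) * u_axis
  w2 <- w2 + (z1 + s2 * dz) * u_axis
  len3d <- sqrt(L2d^2 + dz^2)
  list(length = len3d, nodes = rbind(w1, w2), engaged = TRUE,
       arc_mid_axial = z1 + (s1 + s2) / 2 * dz)
}

# world-space node list of a muscle path: list(points = n x 3, bodies =
# character, length).  Wrap tangent points belong to the wrap body.
muscle_nodes <- function(muscle, poses) {
  P <- as.matrix(muscle$path[, c("x", "y", "z")])
  bodies <- muscle$path$body
  W <- t(vapply(seq_len(nrow(P)),
                function(i) as.numeric(map_points(P[i, , drop = FALSE],
                                                  bodies[i], poses)),
                numeric(3)))
  arc_extra <- 0
  if (!is.null(muscle$wrap)) {
    w <- muscle$wrap
    cp <- as.numeric(map_points(matrix(w$point, 1), w$body, poses))
    ax <- as.numeric(poses[[w$body]]$R %*% w$axis)
    i1 <- w$between[1]; i2 <- w$between[2]
    wp <- cylinder_wrap_path(W[i1, ], W[i2, ], cp, ax, w$radius)
    if (wp$engaged) {
      # the path between the tangent nodes follows the arc, not the chord
      arc_extra <- wp$length -
        (vnorm(wp$nodes[1, ] - W[i1, ]) + vnorm(wp$nodes[2, ] - wp$nodes[1, ]) +
           vnorm(W[i2, ] - wp$nodes[2, ]))
      W <- rbind(W[seq_len(i1), , drop = FALSE], wp$nodes,
                 W[i2:nrow(W), , drop = FALSE])
      bodies <- c(bodies[seq_len(i1)], w$body, w$body, bodies[i2:length(bodies)])
    }
  }
  seg <- diff(W)
  list(points = W, bodies = bodies,
       length = sum(sqrt(rowSums(seg^2))) + arc_extra)
}

#' Muscle path length at a knee state
#'
#' Sum of straight segments plus the geodesic arc over an engaged wrap
#' cylinder; smooth in the state coordinates away from engagement boundaries.
#'
#' @param muscle a [muscle_actuator()]
#' @param poses body poses (see [body_poses()])
#' @return length (mm)
#' @export
path_length <- function(muscle, poses) {
  if (!is.null(muscle$const_moment_arm_mm))
    stop("path_length undefined for a constant-moment-arm actuator")
  muscle_nodes(muscle, poses)$length
}

#' Tendon-excursion moment arm
#'
#' Central finite difference of the path length with respect to a model
#' coordinate; rotational coordinates are perturbed in radians so the result
#' is in mm.
#'
#' @param muscle a [muscle_actuator()]
#' @param model a [knee_model()]
#' @param state knee state vector (see [knee_state()])
#' @param coordinate coordinate name (e.g. `"flexion"`, `"ap"`)
#' @param delta finite-difference half-step (rad or mm)
#' @return moment arm (mm); positive if the path shortens as the coordinate
#'   increases
#' @export
moment_arm <- function(muscle, model, state, coordinate, delta = 1e-4) {
  if (delta <= 0) stop("numeric error: finite-difference step underflow")
  qp <- state; qm <- state
  qp[coordinate] <- qp[coordinate] + delta
  qm[coordinate] <- qm[coordinate] - delta
  Lp <- path_length(muscle, body_poses(model, qp))
  Lm <- path_length(muscle, body_poses(model, qm))
  -(Lp - Lm) / (2 * delta)
}

#' Muscle force from activation
#'
#' Rigid-tendon activation-to-force mapping `F = a Fmax`.
#'
#' @param muscle a [muscle_actuator()]
#' @param a activation in `[0, 1]`
#' @return force (N)
#' @export
muscle_force <- function(muscle, a) {
  if (any(a < 0 | a > 1)) stop("bounds error: activation must lie in [0, 1]")
  a * muscle$Fmax
}

# force applications of one muscle at tension Tf: endpoint and via/wrap node
# forces on femur/patella bodies (tibia is ground and skipped)
muscle_force_entries <- function(muscle, poses, Tf) {
  if (Tf == 0 || !is.null(muscle$const_moment_arm_mm)) return(list())
  nd <- muscle_nodes(muscle, poses)
  W <- nd$points; bodies <- nd$bodies
  n <- nrow(W)
  apps <- list()
  for (i in seq_len(n)) {
    if (bodies[i] == "tibia") next
    f <- c(0, 0, 0)
    if (i > 1) f <- f + Tf * unitize(W[i - 1, ] - W[i, ])
    if (i < n) f <- f + Tf * unitize(W[i + 1, ] - W[i, ])
    apps[[length(apps) + 1]] <- list(body = bodies[i], point = W[i, ], force = f)
  }
  apps
}

#' Muscle table I/O
#'
#' Round-trips the actuator set as CSV with one row per path point:
#' `name, Fmax, seq, body, x, y, z, via_patella, wrap_*`.
#'
#' @param muscles named list of [muscle_actuator()]s
#' @param path CSV path
#' @export
write_muscle_table <- function(muscles, path) {
  rows <- lapply(muscles, function(m) {
    if (!is.null(m$const_moment_arm_mm)) return(NULL)
    d <- data.frame(name = m$name, Fmax = m$Fmax, seq = seq_len(nrow(m$path)),
                    body = m$path$body, x = m$path$x, y = m$path$y, z = m$path$z,
                    via_patella = m$via_patella)
    if (!is.null(m$wrap)) {
      d$wrap_body <- m$wrap$body; d$wrap_radius <- m$wrap$radius
      d$wrap_px <- m$wrap$point[1]; d$wrap_py <- m$wrap$point[2]
      d$wrap_pz <- m$wrap$point[3]
      d$wrap_ax <- m$wrap$axis[1]; d$wrap_ay <- m$wrap$axis[2]
      d$wrap_az <- m$wrap$axis[3]
      d$wrap_i1 <- m$wrap$between[1]; d$wrap_i2 <- m$wrap$between[2]
    } else {
      d$wrap_body <- NA; d$wrap_radius <- NA
      d$wrap_px <- NA; d$wrap_py <- NA; d$wrap_pz <- NA
      d$wrap_ax <- NA; d$wrap_ay <- NA; d$wrap_az <- NA
      d$wrap_i1 <- NA; d$wrap_i2 <- NA
    }
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_muscle_table
#' @export
read_muscle_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (nm in unique(df$name)) {
    d <- df[df$name == nm, , drop = FALSE]
    d <- d[order(d$seq), , drop = FALSE]
    wrap <- NULL
    if (!is.na(d$wrap_body[1])) {
      wrap <- list(body = d$wrap_body[1],
                   point = c(d$wrap_px[1], d$wrap_py[1], d$wrap_pz[1]),
                   axis = c(d$wrap_ax[1], d$wrap_ay[1], d$wrap_az[1]),
                   radius = d$wrap_radius[1],
                   between = c(d$wrap_i1[1], d$wrap_i2[1]))
    }
    out[[nm]] <- muscle_actuator(nm, d$Fmax[1],
                                 data.frame(body = d$body, x = d$x, y = d$y,
                                            z = d$z, stringsAsFactors = FALSE),
                                 wrap = wrap, via_patella = d$via_patella[1])
  }
  out
}
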
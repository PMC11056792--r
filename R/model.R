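#' Build a knee model
#'
#' Assembles the parametric implant geometry, elastic-foundation material,
#' ligament bundles and muscle actuators into a single model object, the
#' central container every simulation operates on.  The model is built at the
#' full-extension reference pose (flexion 0, all secondary coordinates zero,
#' condyles exactly touching the dish floors, button exactly touching the
#' trochlear groove) and must be calibrated with [calibrate_model()] before
#' simulation.
#'
#' @param geometry a [geometry_params()] list (or a plain list of overrides)
#' @param material a [material_spec()]
#' @param ligaments named list of [ligament_bundle()]s; default
#'   [default_ligaments()] on the assembly
#' @param muscles named list of [muscle_actuator()]s; default
#'   [default_muscles()]
#' @param mass_kg subject mass for body-weight normalization (kg)
#' @param control solver control overrides, see [solver_control()]
#' @return object of class `knee_model`
#' @export
knee_model <- function(geometry = geometry_params(),
                       material = material_spec(),
                       ligaments = NULL, muscles = NULL,
                       mass_kg = 95.6, control = list()) {
  assembly <- build_parametric_assembly(geometry)
  if (is.null(ligaments)) ligaments <- default_ligaments(assembly)
  if (is.null(muscles)) muscles <- default_muscles(assembly)
  ctrl <- do.call(solver_control, control)
  m <- structure(list(assembly = assembly, material = material,
                      ligaments = ligaments, muscles = muscles,
                      mass_kg = mass_kg, control = ctrl,
                      calibrated = FALSE,
                      secondary = c("aa", "ie", "ap", "pd", "lm",
                                    "pflex", "prot", "ptilt",
                                    "pap", "ppd", "plm")),
                 class = "knee_model")
  m
}

#' Solver control parameters
#'
#' @param tol_force secondary-equilibrium force tolerance (N)
#' @param tol_moment secondary-equilibrium moment tolerance (N m)
#' @param tol_flexion_moment primary (flexion) moment-balance tolerance (N m)
#' @param max_iter maximum Newton iterations per equilibrium solve
#' @param max_outer maximum concurrent (activation/kinematics) iterations
#' @param fd_step finite-difference step (mm or rad)
#' @param damping initial Newton damping factor
#' @param tol_coord outer-loop secondary-coordinate convergence (mm or deg)
#' @param tol_activation outer-loop activation convergence
#' @param activation_floor antagonist activation floor
#' @param guard_translation translation guard rail (mm)
#' @param method `"concurrent"` solves the secondary coordinates and the
#'   activation multiplier as one root problem; `"alternating"` is the
#'   classic fixed point between the redundancy problem and the equilibrium
#' @return list of class `solver_control`
#' @export
solver_control <- function(tol_force = 0.5, tol_moment = 0.05,
                           tol_flexion_moment = 0.05,
                           max_iter = 100, max_outer = 50,
                           fd_step = 1e-4, damping = 0.5,
                           tol_coord = 1e-3, tol_activation = 1e-4,
                           activation_floor = 0,
                           guard_translation = 50,
                           method = c("concurrent", "alternating")) {
  method <- match.arg(method)
  structure(as.list(environment()), class = "solver_control")
}

#' Knee state vector
#'
#' Twelve coordinates: the prescribed tibiofemoral flexion (primary), five
#' secondary tibiofemoral coordinates (abduction-adduction `aa`,
#' internal-external rotation `ie`, anterior-posterior `ap`, proximal-distal
#' `pd`, lateral-medial `lm` translations of the femoral component relative to
#' the tibial component), and six patellofemoral coordinates of the patella
#' relative to the femoral component (`pflex`, `prot`, `ptilt` rotations and
#' `pap`, `ppd`, `plm` translations, measured from the as-built seated pose).
#' Internally rotations are radians and translations mm; the constructor takes
#' degrees for rotations.
#'
#' @param flexion_deg knee flexion (deg)
#' @param aa_deg,ie_deg secondary rotations (deg)
#' @param ap_mm,pd_mm,lm_mm secondary translations (mm)
#' @param pflex_deg,prot_deg,ptilt_deg patellar rotations (deg)
#' @param pap_mm,ppd_mm,plm_mm patellar translations (mm)
#' @return named numeric state vector (internal units)
#' @export
knee_state <- function(flexion_deg = 0, aa_deg = 0, ie_deg = 0, ap_mm = 0,
                       pd_mm = 0, lm_mm = 0, pflex_deg = 0, prot_deg = 0,
                       ptilt_deg = 0, pap_mm = 0, ppd_mm = 0, plm_mm = 0) {
  c(flexion = deg2rad(flexion_deg), aa = deg2rad(aa_deg), ie = deg2rad(ie_deg),
    ap = ap_mm, pd = pd_mm, lm = lm_mm,
    pflex = deg2rad(pflex_deg), prot = deg2rad(prot_deg),
    ptilt = deg2rad(ptilt_deg), pap = pap_mm, ppd = ppd_mm, plm = plm_mm)
}

state_coord_names <- c("flexion", "aa", "ie", "ap", "pd", "lm",
                       "pflex", "prot", "ptilt", "pap", "ppd", "plm")
rot_coords <- c("flexion", "aa", "ie", "pflex", "prot", "ptilt")

#' Body poses at a knee state
#'
#' Maps the state vector to rigid poses of the femoral component and patella
#' in the tibial frame.  Femur: rotation `Rz(flexion) Rx(aa) Ry(ie)` about its
#' origin on the flexion axis, translated by the secondary translations from
#' the as-built position.  Patella: the as-built seated pose in femur-local
#' coordinates composed with its six perturbation coordinates, carried by the
#' femur.
#'
#' @param model a [knee_model()]
#' @param state a [knee_state()] vector
#' @return list with `femur`, `patella`, `tibia` poses (`R` 3x3, `t` 3-vector)
#' @export
body_poses <- function(model, state) {
  lm <- model$assembly$landmarks
  Rf <- rot_z(state[["flexion"]]) %*% rot_x(state[["aa"]]) %*% rot_y(state[["ie"]])
  tf <- lm$femur_origin + c(state[["ap"]], state[["pd"]], state[["lm"]])
  Rrel <- lm$patella_base_rot %*% rot_z(state[["pflex"]]) %*%
    rot_x(state[["prot"]]) %*% rot_y(state[["ptilt"]])
  prel <- lm$patella_base_pos + c(state[["pap"]], state[["ppd"]], state[["plm"]])
  Rp <- Rf %*% Rrel
  tp <- as.numeric(Rf %*% prel) + tf
  list(femur = list(R = Rf, t = tf),
       patella = list(R = Rp, t = tp),
       tibia = list(R = diag(3), t = c(0, 0, 0)))
}

#' Calibrate the model's ligament slack lengths
#'
#' Applies the reference-strain rule at the full-extension pose: every strand's
#' slack length is set so its strain at that pose equals `eps_ref` (default
#' 2 percent).  The pose used is the as-built reference (flexion 0, secondary
#' coordinates zero), which is an equilibrium of the uncalibrated model (no
#' penetration, no ligament force, no load).  Calibration is performed once at
#' the baseline alignment; the slack lengths are then frozen across alignment
#' sweeps so that implantation changes express themselves as soft-tissue
#' loading changes.
#'
#' @param model a [knee_model()]
#' @param eps_ref reference strain
#' @return the calibrated model
#' @export
calibrate_model <- function(model, eps_ref = 0.02) {
  pose0 <- body_poses(model, knee_state())
  model$ligaments <- calibrate_slack_lengths(model$ligaments, pose0, eps_ref)
  model$calibrated <- TRUE
  model$calibration_pose <- pose0
  model
}

#' @export
print.knee_model <- function(x, ...) {
  cat("knee_model: parametric TKA musculoskeletal knee\n")
  cat(sprintf("  implant: PTS %.1f deg (baseline %.1f), varus %.1f deg\n",
              x$assembly$alignment$pts_deg, x$assembly$alignment$baseline_pts_deg,
              x$assembly$alignment$varus_deg))
  cat(sprintf("  material: E %.0f MPa, nu %.2f, h %.1f mm, %s law (K = %.0f MPa)\n",
              x$material$E, x$material$nu, x$material$h, x$material$law,
              x$material$K))
  cat(sprintf("  %d ligament bundles (%d strands), %d muscles, mass %.1f kg\n",
              length(x$ligaments),
              sum(vapply(x$ligaments, function(b) nrow(b$origin), 1L)),
              length(x$muscles), x$mass_kg))
  cat(sprintf("  calibrated: %s\n", x$calibrated))
  invisible(x)
}

#' @export
summary.knee_model <- function(object, ...) {
  print(object)
  if (object$calibrated) {
    pose0 <- object$calibration_pose
    cat("  strand strains at full extension:\n")
    for (nm in names(object$ligaments)) {
      b <- object$ligaments[[nm]]
      L <- bundle_lengths(b, pose0)
      cat(sprintf("    %-5s %s\n", nm,
                  paste(sprintf("%.4f", (L - b$l0) / b$l0), collapse = " ")))
    }
  }
  invisible(object)
}

#' Reduced single-extensor test model
#'
#' One extensor with a fixed knee-flexion moment arm, no articular contact and
#' no ligaments: the smallest model on which the concurrent solver's
#' moment-balance and redundancy machinery can be exercised against hand
#' statics (activation = demand / (Fmax x arm)).
#'
#' @param moment_arm_mm extensor moment arm (mm)
#' @param Fmax maximum isometric force (N)
#' @param n_extensors number of identical extensors sharing the demand
#' @return a calibrated `knee_model` with no secondary coordinates
#' @export
toy_extensor_model <- function(moment_arm_mm = 40, Fmax = 4000, n_extensors = 1) {
  muscles <- lapply(seq_len(n_extensors), function(i) {
    muscle_actuator(paste0("extensor", i), Fmax,
                    const_moment_arm_mm = moment_arm_mm)
  })
  names(muscles) <- vapply(muscles, `[[`, "", "name")
  m <- structure(list(assembly = NULL, material = NULL, ligaments = list(),
                      muscles = muscles, mass_kg = 95.6,
                      control = solver_control(), calibrated = TRUE,
                      secondary = character(0)),
                 class = "knee_model")
  m
}
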
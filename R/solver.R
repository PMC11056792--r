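#' External load wrench
#'
#' Intersegmental load applied to the femoral component, expressed in the
#' tibial frame: the force acts at the femur origin (on the flexion axis) and
#' the moment is a free vector.  This wrench is the declared stand-in for the
#' marker/ground-reaction-driven inverse dynamics of a full-body gait model.
#'
#' @param force 3-vector (N), tibial-frame components (anterior, superior,
#'   lateral)
#' @param moment 3-vector (N m); the Z component is the external
#'   flexion-extension demand the muscles must balance
#' @return list of class `external_load`
#' @export
external_load <- function(force = c(0, 0, 0), moment = c(0, 0, 0)) {
  stopifnot(all(is.finite(force)), all(is.finite(moment)))
  structure(list(force = as.numeric(force), moment = as.numeric(moment)),
            class = "external_load")
}

# Assemble all force contributions at a state.  Returns world wrenches about
# the global (tibial-frame) origin for the femur system (femur + patella,
# internal patellofemoral actions cancelling) and the patella alone, plus the
# per-source bookkeeping the reporting layer needs.  Units N, N mm.
assemble_forces <- function(model, state, activations, load,
                            need_contact_detail = FALSE) {
  poses <- body_poses(model, state)
  asm <- model$assembly
  mat <- model$material

  Wf <- list(F = c(0, 0, 0), M = c(0, 0, 0))   # on femur (incl. PF contact)
  Wp <- list(F = c(0, 0, 0), M = c(0, 0, 0))   # on patella
  add <- function(W, F, M) list(F = W$F + F, M = W$M + M)
  add_pt <- function(W, point, force) {
    list(F = W$F + force, M = W$M + cross3(point, force))
  }

  # tibiofemoral contact: inlay foundation vs posed condyles (per compartment)
  tf <- tf_contact_fast(asm, mat, poses$femur$R, poses$femur$t,
                        detail = need_contact_detail)
  Wf <- add(Wf, tf$F_total, tf$M0)

  # patellofemoral contact: button foundation vs posed trochlea
  pf <- pf_contact_fast(asm, mat, poses$patella$R, poses$patella$t,
                        poses$femur$R, poses$femur$t,
                        detail = need_contact_detail)
  Wf <- add(Wf, pf$F_total, pf$M0)
  Wp <- add(Wp, -pf$F_total, -pf$M0)

  # ligaments
  lig <- ligament_wrench_fast(model$ligaments, poses)
  Wf <- add(Wf, lig$Ff, lig$Mf)
  Wp <- add(Wp, lig$Fp, lig$Mp)

  # muscles
  muscle_F <- setNames(numeric(length(model$muscles)), names(model$muscles))
  for (nm in names(model$muscles)) {
    mu <- model$muscles[[nm]]
    Tf <- muscle_force(mu, activations[[nm]])
    muscle_F[nm] <- Tf
    if (Tf > 0 && is.null(mu$const_moment_arm_mm)) {
      for (ap in muscle_force_entries(mu, poses, Tf)) {
        if (ap$body == "femur") Wf <- add_pt(Wf, ap$point, ap$force)
        else if (ap$body == "patella") Wp <- add_pt(Wp, ap$point, ap$force)
      }
    }
  }

  # external load: force at the femur origin, free moment (N m -> N mm)
  Wf <- add_pt(Wf, poses$femur$t, load$force)
  Wf <- add(Wf, c(0, 0, 0), load$moment * 1000)

  out <- list(Wf = Wf, Wp = Wp, poses = poses,
              ligament_forces = lig$tension, muscle_forces = muscle_F)
  if (need_contact_detail) {
    out$tf <- tf
    out$pf <- pf
  }
  out
}

# generalized forces on the secondary coordinates (N for translations,
# N mm for rotations), order = model$secondary
secondary_residual <- function(model, state, activations, load,
                               forces = NULL) {
  fr <- forces %||% assemble_forces(model, state, activations, load)
  Rf <- fr$poses$femur$R
  tf <- fr$poses$femur$t
  tp <- fr$poses$patella$t
  Fsys <- fr$Wf$F + fr$Wp$F
  Msys <- fr$Wf$M + fr$Wp$M
  M_at_tf <- Msys - cross3(tf, Fsys)
  M_at_tp <- fr$Wp$M - cross3(tp, fr$Wp$F)

  Rz_fl <- rot_z(state[["flexion"]])
  ax_aa <- as.numeric(Rz_fl %*% c(1, 0, 0))
  ax_ie <- as.numeric(Rz_fl %*% rot_x(state[["aa"]]) %*% c(0, 1, 0))

  lmk <- model$assembly$landmarks
  Rb <- lmk$patella_base_rot
  ax_pflex <- as.numeric(Rf %*% Rb %*% c(0, 0, 1))
  ax_prot <- as.numeric(Rf %*% Rb %*% rot_z(state[["pflex"]]) %*% c(1, 0, 0))
  ax_ptilt <- as.numeric(Rf %*% Rb %*% rot_z(state[["pflex"]]) %*%
                           rot_x(state[["prot"]]) %*% c(0, 1, 0))

  q <- c(aa = sum(ax_aa * M_at_tf),
         ie = sum(ax_ie * M_at_tf),
         ap = Fsys[1], pd = Fsys[2], lm = Fsys[3],
         pflex = sum(ax_pflex * M_at_tp),
         prot = sum(ax_prot * M_at_tp),
         ptilt = sum(ax_ptilt * M_at_tp),
         pap = sum((Rf %*% c(1, 0, 0)) * fr$Wp$F),
         ppd = sum((Rf %*% c(0, 1, 0)) * fr$Wp$F),
         plm = sum((Rf %*% c(0, 0, 1)) * fr$Wp$F))
  q[model$secondary]
}

# flexion-axis generalized force (N mm) on the femur system, all sources
flexion_moment <- function(model, state, activations, load, forces = NULL) {
  fr <- forces %||% assemble_forces(model, state, activations, load)
  Fsys <- fr$Wf$F + fr$Wp$F
  Msys <- fr$Wf$M + fr$Wp$M
  (Msys - cross3(fr$poses$femur$t, Fsys))[3]
}

#' Secondary-coordinate mechanical equilibrium
#'
#' Finds the root of the generalized forces on the secondary tibiofemoral and
#' patellofemoral coordinates (contact + ligaments + muscles + external load)
#' at a prescribed flexion angle and fixed muscle activations.  Damped Newton
#' with a forward-difference Jacobian, Broyden rank-one updates between
#' iterations, and automatic Jacobian refresh on stagnation.
#'
#' @param model calibrated [knee_model()]
#' @param flexion flexion angle (rad)
#' @param activations named activations in `[0, 1]`
#' @param load an [external_load()]
#' @param guess starting [knee_state()] vector (its flexion entry is replaced)
#' @param J optional initial Jacobian to warm-start from
#' @param control a [solver_control()]
#' @return list with `state`, `converged`, `iterations`, `residual` (named,
#'   N / N mm), `J` (final Jacobian, reusable)
#' @export
secondary_equilibrium <- function(model, flexion, activations, load,
                                  guess = knee_state(), J = NULL,
                                  control = model$control) {
  sec <- model$secondary
  if (length(sec) == 0) {
    st <- guess; st[["flexion"]] <- flexion
    return(list(state = st, converged = TRUE, iterations = 0L,
                residual = numeric(0), J = NULL))
  }
  state <- guess
  state[["flexion"]] <- flexion
  tolv <- ifelse(sec %in% rot_coords, control$tol_moment * 1000, control$tol_force)
  trans_coords <- sec[!(sec %in% rot_coords)]

  resid_x <- function(x) {
    st <- state
    st[sec] <- x
    secondary_residual(model, st, activations, load)
  }

  res <- newton_core(resid_x, state[sec], tolv,
                     caps = ifelse(sec %in% rot_coords, 0.25, 1.5),
                     guard = function(x) all(abs(x[trans_coords]) <=
                                               control$guard_translation),
                     control = control, J = J)
  state[sec] <- res$x
  conv <- res$converged
  list(state = state, converged = conv, iterations = res$iterations,
       residual = setNames(res$residual, sec), J = res$J)
}

# Generic damped-Newton root solver with forward-difference Jacobian,
# Broyden updates, trust-region step caps, a tolerance-scaled line search and
# deterministic nudges off non-smooth points.  x is a named numeric vector;
# resid(x) returns a residual of the same length; tolv are per-component
# tolerances; caps are per-component step limits; guard() vetoes states.
newton_core <- function(resid_x, x0, tolv, caps, guard, control, J = NULL) {
  x <- x0
  R0 <- resid_x(x)
  err <- function(R) max(abs(R) / tolv)          # convergence measure
  merit <- function(R) sum((R / tolv)^2)         # smoother line-search merit
  e0 <- err(R0)
  m0 <- merit(R0)
  fd_jacobian <- function(x, R0) {
    n <- length(x)
    Jm <- matrix(0, n, n)
    for (j in seq_len(n)) {
      xp <- x
      xp[j] <- xp[j] + control$fd_step
      Jm[, j] <- (resid_x(xp) - R0) / control$fd_step
    }
    Jm
  }
  fresh <- FALSE
  jitters <- 0L
  slow_steps <- 0L
  iter <- 0L
  # nonmonotone acceptance window on the L2 merit: the residual is piecewise
  # smooth (faces enter and leave contact), and insisting on strict descent
  # stalls at the kinks; steps may rise above the current merit as long as
  # they stay below the recent-history maximum
  ehist <- rep(m0, 4)
  while (e0 >= 1 && iter < control$max_iter) {
    iter <- iter + 1L
    if (is.null(J)) {
      J <- fd_jacobian(x, R0); fresh <- TRUE
    }
    # stiffness floor: coordinates whose restraints are all slack (an
    # unloaded patella, an authority-less multiplier) leave near-null
    # directions; a ridge at the tolerance/cap scale bounds their steps
    # without measurably altering stiff directions or the converged root
    ridge <- diag(-tolv / caps, length(x))
    dq <- tryCatch(solve(J + ridge, -R0), error = function(e) NULL)
    if (is.null(dq)) {
      if (!fresh) { J <- NULL; next }
      # perturb-and-retry once on a singular fresh Jacobian
      x <- x + 1e-6
      R0 <- resid_x(x)
      J <- fd_jacobian(x, R0); fresh <- TRUE
      dq <- tryCatch(solve(J + ridge, -R0), error = function(e)
        stop("singular equilibrium Jacobian"))
    }
    # trust-region cap: the contact stiffness is strongly state-dependent, so
    # long extrapolated steps are unreliable (and can exhaust the foundation)
    sc <- min(1, min(caps / pmax(abs(dq), 1e-12)))
    dq <- dq * sc
    # damped line search on the scaled residual norm
    alpha <- if (iter == 1 && !fresh) control$damping else 1
    improved <- FALSE
    for (k in 1:12) {
      x_try <- x + alpha * dq
      if (!guard(x_try)) { alpha <- alpha / 2; next }
      R_try <- tryCatch(resid_x(x_try), error = function(e) NULL)
      if (!is.null(R_try) && merit(R_try) < 0.98 * max(ehist)) {
        dR <- R_try - R0
        step <- alpha * dq
        J <- J + outer(dR - as.numeric(J %*% step), step) / sum(step^2)
        x <- x_try; R0 <- R_try; e0 <- err(R0); m0 <- merit(R0)
        ehist <- c(ehist[-1], m0)
        improved <- TRUE
        jitters <- 0L
        # heavily damped Broyden progress is slow: pay for a fresh Jacobian
        if (alpha <= 0.25 && !fresh) slow_steps <- slow_steps + 1 else slow_steps <- 0
        if (slow_steps >= 2) { J <- NULL; slow_steps <- 0 }
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) {
      if (fresh) {
        if (jitters >= 2) break    # cannot improve even with a fresh Jacobian
        # deterministic nudge off a non-smooth point (facet boundary)
        jitters <- jitters + 1
        x <- x + 1e-3 * (2 * (seq_along(x) %% 2) - 1) *
          ifelse(tolv > 5, 1e-2, 1)
        R0 <- resid_x(x); e0 <- err(R0); m0 <- merit(R0)
        ehist <- rep(m0, length(ehist))
        J <- NULL
      } else J <- NULL        # refresh and retry
    } else fresh <- FALSE
  }
  list(x = x, converged = e0 < 1, iterations = iter, residual = R0, J = J)
}

# min sum(a^2) s.t. sum(a_m c_m) = b, floor <= a <= 1, by water-filling on the
# single multiplier (piecewise-linear monotone in lambda)
qp_activations <- function(cvec, b, floor = 0, clamp = FALSE) {
  nz <- abs(cvec) > 1e-12
  smax <- sum(pmax(cvec, floor * cvec)[nz])
  smin <- sum(pmin(cvec, floor * cvec)[nz])
  if (b > smax + 1e-6 || b < smin - 1e-6) {
    if (clamp) {
      # transient infeasibility mid-iteration: saturate and let the
      # equilibrium (and the final residual check) adjudicate
      b <- min(max(b, smin), smax)
    } else stop(sprintf(
      "saturation error: flexion-moment demand infeasible (deficit %.2f N m)",
      (if (b > smax) b - smax else smin - b) / 1000))
  }
  if (!any(nz)) return(rep(floor, length(cvec)))
  act <- function(lam) pmin(1, pmax(floor, lam * cvec))
  S <- function(lam) sum(act(lam) * cvec)
  lmax <- 1.01 * max(1 / abs(cvec[nz]))
  lo <- -lmax; hi <- lmax
  if (S(lo) > b) lo <- lo * 2
  if (S(hi) < b) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (S(mid) < b) lo <- mid else hi <- mid
  }
  act((lo + hi) / 2)
}

# knee-flexion moment arms (mm) for the redundancy problem; muscles inserting
# on the patella use the extensor-mechanism excursion (their path plus the
# patellar tendon, the patella riding with the femur)
flexion_moment_arms <- function(model, state, delta = 1e-3) {
  pt <- model$ligaments[["PT"]]
  mech_len <- function(st) {
    poses <- body_poses(model, st)
    mean(bundle_lengths(pt, poses))
  }
  vapply(model$muscles, function(mu) {
    if (!is.null(mu$const_moment_arm_mm)) return(-mu$const_moment_arm_mm)
    stp <- state; stm <- state
    stp[["flexion"]] <- stp[["flexion"]] + delta
    stm[["flexion"]] <- stm[["flexion"]] - delta
    L_p <- path_length(mu, body_poses(model, stp))
    L_m <- path_length(mu, body_poses(model, stm))
    if (mu$via_patella && !is.null(pt)) {
      L_p <- L_p + mech_len(stp)
      L_m <- L_m + mech_len(stm)
    }
    -(L_p - L_m) / (2 * delta)
  }, numeric(1))
}

#' Solve one activity frame concurrently
#'
#' Fixed-point iteration between (i) the muscle-redundancy problem -- minimise
#' the sum of squared activations subject to the flexion-axis moment balance
#' (muscles + passive structures + external demand = 0) with bounded
#' activations, solved as a single-constraint boundQP -- and (ii) the
#' secondary-coordinate equilibrium at those activations, until both the
#' secondary coordinates and the activations stop changing.
#'
#' @param model calibrated [knee_model()]
#' @param flexion prescribed flexion (rad)
#' @param load an [external_load()]
#' @param prev previous frame solution for warm starting (or `NULL`)
#' @param control a [solver_control()]
#' @return a `frame_solution`: state, activations, muscle and ligament forces,
#'   tibiofemoral and patellofemoral [compute_contact()] results, residuals,
#'   convergence flags and iteration counts
#' @export
solve_frame <- function(model, flexion, load, prev = NULL,
                        control = model$control) {
  if (!model$calibrated) stop("model must be calibrated first")
  muscles <- names(model$muscles)
  floor_a <- control$activation_floor
  a <- if (!is.null(prev)) prev$activations else
    setNames(rep(floor_a, length(muscles)), muscles)
  state <- if (!is.null(prev)) prev$state else cold_start_state(model)
  state[["flexion"]] <- flexion
  J <- if (!is.null(prev)) prev$J else NULL

  has_sec <- length(model$secondary) > 0
  # cold starts (and alignment changes) can leave the guessed pose far from
  # mechanical equilibrium; relax the secondary coordinates at the initial
  # activations before the first moment-balance solve so the redundancy
  # problem sees a physical passive moment
  if (has_sec && is.null(prev)) {
    eq0 <- secondary_equilibrium(model, flexion, a, load, guess = state,
                                 control = control)
    state <- eq0$state
    J <- NULL
  }

  if (!has_sec) {
    # reduced model: the moment balance alone, no secondary coordinates
    rarm <- flexion_moment_arms(model, state)
    cvec <- vapply(muscles, function(nm) model$muscles[[nm]]$Fmax * rarm[[nm]],
                   numeric(1))
    G <- load$moment[3] * 1000 + sum(a * cvec)
    b <- sum(a * cvec) - G
    a <- setNames(qp_activations(cvec, b, floor_a), muscles)
    res_flex <- abs(load$moment[3] * 1000 + sum(a * cvec)) / 1000
    return(structure(list(
      state = state, activations = a,
      muscle_forces = setNames(a * vapply(model$muscles, `[[`, 0, "Fmax"),
                               muscles),
      ligament_forces = numeric(0), tf = NULL, pf = NULL,
      residual_flexion_Nm = res_flex, residual_secondary = numeric(0),
      converged = res_flex < control$tol_flexion_moment,
      outer_iterations = 1L, newton_iterations = 0L,
      objective_trace = sum(a^2), lambda = NULL, J = NULL
    ), class = "frame_solution"))
  }

  if (control$method == "alternating") {
    return(solve_frame_alternating(model, flexion, load, a, state, J, control))
  }

  # concurrent path: solve the 11 secondary coordinates and the activation
  # multiplier simultaneously.  Activations follow the water-filling family
  # a_m = clamp(lambda c_m / c_ref, floor, 1), whose multiplier is the 12th
  # unknown closed on the exact flexion moment balance; the moment arms that
  # shape the family are refreshed between solves, which only affects the
  # effort-optimal distribution, never the converged force balance.
  sec <- model$secondary
  tolv <- c(ifelse(sec %in% rot_coords, control$tol_moment * 1000,
                   control$tol_force), control$tol_flexion_moment * 1000)
  caps <- c(ifelse(sec %in% rot_coords, 0.25, 1.5), 0.25)
  trans_idx <- which(!(sec %in% rot_coords))
  lam_guard <- 5

  newton_iters <- 0L
  obj_trace <- numeric(0)
  lam <- if (!is.null(prev) && !is.null(prev$lambda)) prev$lambda else NULL
  res <- NULL
  state0 <- state; a0 <- a
  for (refresh in 1:3) {
    rarm <- flexion_moment_arms(model, state)
    cvec <- vapply(muscles, function(nm) model$muscles[[nm]]$Fmax * rarm[[nm]],
                   numeric(1))
    cref <- max(abs(cvec), 1e-9)
    act_of <- function(lamx) pmin(1, pmax(floor_a, lamx * cvec / cref))
    if (is.null(lam)) {
      G0 <- flexion_moment(model, state, a, load)
      b <- sum(a * cvec) - G0
      a_qp <- qp_activations(cvec, b, floor_a, clamp = TRUE)
      den <- sum(cvec^2 / cref)
      lam <- if (abs(den) > 1e-9) sum(a_qp * cvec) / den else 0
    }
    resid_aug <- function(x) {
      st <- state
      st[sec] <- x[seq_along(sec)]
      av <- setNames(act_of(x[[length(x)]]), muscles)
      fr <- assemble_forces(model, st, av, load)
      c(secondary_residual(model, st, av, load, forces = fr),
        flexion_moment(model, st, av, load, forces = fr))
    }
    x0 <- c(unname(state[sec]), lam)
    res <- tryCatch(
      newton_core(resid_aug, x0, tolv, caps,
                  guard = function(x)
                    all(abs(x[trans_idx]) <= control$guard_translation) &&
                      abs(x[length(x)]) <= lam_guard,
                  control = control,
                  J = if (!is.null(J) && nrow(J) == length(x0)) J else NULL),
      error = function(e) {
        if (!grepl("singular", conditionMessage(e))) stop(e)
        NULL
      })
    if (is.null(res)) {
      # the multiplier loses authority over the flexion balance when the
      # extensor mechanism is slack (unloaded swing): the alternating fixed
      # point handles that regime
      return(solve_frame_alternating(model, flexion, load, a0, state0, NULL,
                                     control))
    }
    newton_iters <- newton_iters + res$iterations
    state[sec] <- res$x[seq_along(sec)]
    lam_new <- res$x[[length(res$x)]]
    J <- res$J
    a <- setNames(act_of(lam_new), muscles)
    obj_trace <- c(obj_trace, sum(a^2))
    moved <- abs(lam_new - lam)
    lam <- lam_new
    if (res$converged && moved < 0.02) break
    if (!res$converged && abs(lam) > 0.98 * lam_guard) {
      G_now <- res$residual[length(res$residual)]
      stop(sprintf(
        "saturation error: flexion-moment demand infeasible (deficit %.2f N m)",
        abs(G_now) / 1000))
    }
    if (!res$converged && refresh >= 2) {
      return(solve_frame_alternating(model, flexion, load, a0, state0, NULL,
                                     control))
    }
  }

  forces <- assemble_forces(model, state, a, load, need_contact_detail = TRUE)
  G_final <- flexion_moment(model, state, a, load, forces = forces)
  res_flex <- abs(G_final) / 1000
  sec_res <- setNames(res$residual[seq_along(sec)], sec)
  conv_sec <- all(abs(sec_res) / tolv[seq_along(sec)] < 1)
  converged <- conv_sec && res_flex < control$tol_flexion_moment

  structure(list(
    state = state, activations = a,
    muscle_forces = forces$muscle_forces,
    ligament_forces = forces$ligament_forces,
    tf = forces$tf, pf = forces$pf,
    residual_flexion_Nm = res_flex,
    residual_secondary = sec_res,
    converged = converged, outer_iterations = length(obj_trace),
    newton_iterations = newton_iters,
    objective_trace = obj_trace, lambda = lam, J = J
  ), class = "frame_solution")
}

# classic alternating fixed point between the redundancy problem and the
# secondary equilibrium; retained for cross-checking the concurrent solver
solve_frame_alternating <- function(model, flexion, load, a, state, J,
                                    control) {
  muscles <- names(model$muscles)
  obj_trace <- numeric(0)
  conv_eq <- TRUE
  eqs <- NULL
  newton_iters <- 0L
  outer <- 0L
  if (!is.null(J) && nrow(J) != length(model$secondary)) J <- NULL
  # settle the secondary coordinates at the incoming activations before the
  # first redundancy solve, so the passive flexion moment is physical
  eq0 <- secondary_equilibrium(model, flexion, a, load, guess = state,
                               J = J, control = control)
  state <- eq0$state
  J <- eq0$J
  newton_iters <- newton_iters + eq0$iterations
  repeat {
    outer <- outer + 1L
    rarm <- flexion_moment_arms(model, state)
    cvec <- vapply(muscles, function(nm) model$muscles[[nm]]$Fmax * rarm[[nm]],
                   numeric(1))
    G <- flexion_moment(model, state, a, load)
    b <- sum(a * cvec) - G
    a_new <- setNames(qp_activations(cvec, b, control$activation_floor,
                                     clamp = TRUE), muscles)
    obj_trace <- c(obj_trace, sum(a_new^2))
    eqs <- secondary_equilibrium(model, flexion, a_new, load, guess = state,
                                 J = J, control = control)
    newton_iters <- newton_iters + eqs$iterations
    J <- eqs$J
    conv_eq <- eqs$converged
    dstate <- state_change(eqs$state, state)
    state <- eqs$state
    da <- max(abs(a_new - a))
    a <- a_new
    if ((dstate < control$tol_coord && da < control$tol_activation) ||
        outer >= control$max_outer) break
  }
  forces <- assemble_forces(model, state, a, load, need_contact_detail = TRUE)
  G_final <- flexion_moment(model, state, a, load, forces = forces)
  res_flex <- abs(G_final) / 1000
  converged <- conv_eq && res_flex < control$tol_flexion_moment
  structure(list(
    state = state, activations = a,
    muscle_forces = forces$muscle_forces,
    ligament_forces = forces$ligament_forces,
    tf = forces$tf, pf = forces$pf,
    residual_flexion_Nm = res_flex,
    residual_secondary = eqs$residual,
    converged = converged, outer_iterations = outer,
    newton_iterations = newton_iters,
    objective_trace = obj_trace, lambda = NULL, J = NULL
  ), class = "frame_solution")
}

# cold-start guess: nest the condyles in the (possibly slope-rotated) dishes
# and engage both contacts slightly so the first finite-difference Jacobian
# sees the contact stiffness.  Rotating the inlay by the slope angle about the
# frame origin carries the nested femur-origin position with it.
cold_start_state <- function(model) {
  st <- knee_state()
  if (length(model$secondary)) {
    th <- deg2rad(model$assembly$alignment$pts_deg)
    y0 <- model$assembly$landmarks$femur_origin[2]
    nest <- as.numeric(rot_z(th) %*% c(0, y0, 0)) - c(0, y0, 0)
    st[["ap"]] <- nest[1]
    st[["pd"]] <- nest[2] - 0.05
    st[["pap"]] <- -0.05
  }
  st
}

# max coordinate change in outer-loop units (mm / deg)
state_change <- function(s1, s0) {
  d <- abs(s1 - s0)
  d[rot_coords] <- rad2deg(d[rot_coords])
  max(d[setdiff(names(d), "flexion")])
}

#' Simulate a full activity
#'
#' Solves every frame of an activity profile in order with warm starts, and
#' collects the per-frame kinematic, kinetic, contact, ligament and muscle
#' outputs in a tidy data frame (forces in body weight, moments in N m).
#'
#' @param model calibrated [knee_model()]
#' @param profile a [generate_walking_profile()] / [generate_squat_profile()]
#'   activity
#' @param control a [solver_control()]
#' @param verbose print per-frame convergence lines
#' @param init optional list of per-frame `frame_solution`s from a closely
#'   related run (e.g. the neighbouring alignment in a sweep) used as
#'   same-frame warm starts
#' @return object of class `knee_simulation` with `$frames` (data.frame),
#'   `$solutions` (per-frame `frame_solution`s), `$profile`, and a
#'   convergence summary
#' @export
simulate_activity <- function(model, profile, control = model$control,
                              verbose = FALSE, init = NULL) {
  stopifnot(inherits(profile, "activity_profile"))
  n <- nrow(profile$frames)
  if (n < 2) stop("activity profile must have at least 2 frames")
  BW <- model$mass_kg * 9.81
  sols <- vector("list", n)
  rows <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    pr <- profile$frames[i, ]
    load <- external_load(force = c(pr$Fx_BW, pr$Fy_BW, pr$Fz_BW) * BW,
                          moment = c(pr$Mx_Nm, pr$My_Nm, pr$Mz_Nm))
    start <- if (!is.null(init) && length(init) >= i && !is.null(init[[i]]))
      init[[i]] else prev
    sol <- solve_frame(model, deg2rad(pr$flexion_deg), load, prev = start,
                       control = control)
    if (verbose)
      cat(sprintf("frame %3d: flex %5.1f deg, outer %d, newton %d, conv %s\n",
                  i, pr$flexion_deg, sol$outer_iterations,
                  sol$newton_iterations, sol$converged))
    sols[[i]] <- sol
    rows[[i]] <- frame_row(sol, pr, i, BW)
    prev <- sol
  }
  frames <- do.call(rbind, rows)
  conv_frac <- mean(frames$converged)
  if (conv_frac < 0.9)
    stop(sprintf("activity-level failure: only %.0f%% of frames converged",
                 100 * conv_frac))
  structure(list(frames = frames, solutions = sols, profile = profile,
                 mass_kg = model$mass_kg, converged_fraction = conv_frac),
            class = "knee_simulation")
}

frame_row <- function(sol, pr, i, BW) {
  st <- sol$state
  tf <- sol$tf; pf <- sol$pf
  d <- data.frame(
    frame = i, time_s = pr$time_s, flexion_deg = pr$flexion_deg,
    aa_deg = rad2deg(st[["aa"]]), ie_deg = rad2deg(st[["ie"]]),
    ap_mm = st[["ap"]], pd_mm = st[["pd"]], lm_mm = st[["lm"]],
    pat_flex_deg = rad2deg(st[["pflex"]]), pat_rot_deg = rad2deg(st[["prot"]]),
    pat_tilt_deg = rad2deg(st[["ptilt"]]),
    pat_ap_mm = st[["pap"]], pat_pd_mm = st[["ppd"]], pat_lm_mm = st[["plm"]],
    F_total_AP_BW = tf$F_total[1] / BW, F_total_PD_BW = tf$F_total[2] / BW,
    F_total_LM_BW = tf$F_total[3] / BW,
    F_med_PD_BW = tf$F_medial_PD / BW, F_lat_PD_BW = tf$F_lateral_PD / BW,
    M_AA_Nm = tf$M_total[1], M_IE_Nm = tf$M_total[2], M_FE_Nm = tf$M_total[3],
    CoP_med_x_mm = tf$CoP_medial[1], CoP_med_z_mm = tf$CoP_medial[3],
    CoP_lat_x_mm = tf$CoP_lateral[1], CoP_lat_z_mm = tf$CoP_lateral[3],
    TFCA_mm2 = tf$area, TFCP_MPa = tf$mean_pressure,
    TF_peak_p_MPa = tf$peak_pressure,
    PF_F_BW = vnorm(pf$F_total) / BW, PFCA_mm2 = pf$area,
    PFCP_MPa = pf$mean_pressure,
    resid_flex_Nm = sol$residual_flexion_Nm,
    resid_sec = if (length(sol$residual_secondary)) {
      rs <- sol$residual_secondary
      rot <- names(rs) %in% rot_coords
      max(abs(rs) / ifelse(rot, 50, 0.5))  # fraction of tolerance
    } else 0,
    converged = sol$converged, outer_iter = sol$outer_iterations
  )
  for (nm in names(sol$activations)) d[[paste0("act_", nm)]] <- sol$activations[[nm]]
  for (nm in names(sol$muscle_forces)) d[[paste0("F_", nm, "_N")]] <- sol$muscle_forces[[nm]]
  for (nm in names(sol$ligament_forces)) d[[paste0("lig_", nm, "_N")]] <- sol$ligament_forces[[nm]]
  d
}

#' @export
print.knee_simulation <- function(x, ...) {
  f <- x$frames
  cat(sprintf("knee_simulation: %s, %d frames, %.0f%% converged\n",
              x$profile$name, nrow(f), 100 * x$converged_fraction))
  cat(sprintf("  peak F_Total P-D: %.2f BW | peak flexion: %.1f deg\n",
              max(f$F_total_PD_BW), max(f$flexion_deg)))
  cat(sprintf("  worst residuals: flexion %.3g N m, secondary %.2f x tolerance\n",
              max(f$resid_flex_Nm), max(f$resid_sec)))
  invisible(x)
}

#' @export
summary.knee_simulation <- function(object, ...) {
  print(object)
  f <- object$frames
  qn <- grep("^act_", names(f), value = TRUE)
  cat("  peak activations:\n")
  for (nm in qn) cat(sprintf("    %-22s %.3f\n", sub("^act_", "", nm), max(f[[nm]])))
  invisible(object)
}

#' @export
as.data.frame.knee_simulation <- function(x, ...) x$frames

#' @export
plot.knee_simulation <- function(x, ...) {
  f <- x$frames
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  t <- 100 * (f$frame - 1) / (nrow(f) - 1)
  graphics::plot(t, f$flexion_deg, type = "l", xlab = "% cycle",
                 ylab = "flexion (deg)", main = "knee flexion")
  graphics::plot(t, f$F_total_PD_BW, type = "l", xlab = "% cycle",
                 ylab = "F P-D (BW)", main = "axial TF contact force")
  graphics::matplot(t, cbind(f$CoP_med_x_mm, f$CoP_lat_x_mm), type = "l",
                    lty = 1, xlab = "% cycle", ylab = "CoP A-P (mm)",
                    main = "centre of pressure")
  graphics::plot(t, f$F_vasti_N + f$F_rectus_femoris_N, type = "l",
                 xlab = "% cycle", ylab = "N", main = "quadriceps force")
  invisible(x)
}
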
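id_poses <- list(tibia = list(R = diag(3), t = c(0, 0, 0)),
                 femur = list(R = diag(3), t = c(0, 0, 0)),
                 patella = list(R = diag(3), t = c(0, 0, 0)))

test_that("straight-path length and activation-force mapping are exact", {
  mu <- muscle_actuator("m", 1000,
                        data.frame(body = c("tibia", "tibia"),
                                   x = c(0, 0), y = c(0, 100), z = c(0, 0)))
  expect_equal(path_length(mu, id_poses), 100)
  expect_equal(muscle_force(mu, 0), 0)
  expect_equal(muscle_force(mu, 1), 1000)
  mu2 <- muscle_actuator("m2", 3000, data.frame(body = "tibia", x = 0:1,
                                                y = c(0, 1), z = 0))
  expect_equal(muscle_force(mu2, 0.25), 750)
  expect_error(muscle_force(mu, 1.2), "bounds")
})

test_that("cylinder wrap produces the analytic tangent-arc length", {
  # endpoints at distance d = 1.2 R on perpendicular radii of a cylinder of
  # radius R = 25; the chord passes at d / sqrt(2) < R, so the path wraps:
  # L = 2 sqrt(d^2 - R^2) + R (pi/2 - 2 acos(R/d))
  R <- 25; d <- 1.2 * R
  mu <- muscle_actuator("w", 1000,
    data.frame(body = c("tibia", "tibia"), x = c(-d, 0),
               y = c(0, -d), z = c(0, 0)),
    wrap = list(body = "tibia", point = c(0, 0, 0), axis = c(0, 0, 1),
                radius = R, between = c(1, 2)))
  L_hand <- 2 * sqrt(d^2 - R^2) + R * (pi / 2 - 2 * acos(R / d))
  expect_equal(path_length(mu, id_poses), L_hand, tolerance = 1e-9)

  # length is continuous across wrap engagement: slide one endpoint until the
  # straight segment grazes the cylinder
  lens <- vapply(seq(24.99, 25.01, length.out = 21), function(d) {
    mu2 <- muscle_actuator("w", 1000,
      data.frame(body = c("tibia", "tibia"), x = c(-60, 60),
                 y = c(d, d), z = c(0, 0)),
      wrap = list(body = "tibia", point = c(0, 0, 0), axis = c(0, 0, 1),
                  radius = 25, between = c(1, 2)))
    path_length(mu2, id_poses)
  }, numeric(1))
  expect_lt(max(abs(diff(lens))), 1e-4)

  # a path point deep inside the wrap cylinder is a geometry error
  bad <- muscle_actuator("b", 1,
    data.frame(body = c("tibia", "tibia"), x = c(-60, 5), y = c(0, 0), z = c(0, 0)),
    wrap = list(body = "tibia", point = c(0, 0, 0), axis = c(0, 0, 1),
                radius = 25, between = c(1, 2)))
  expect_error(path_length(bad, id_poses), "geometry error")
})

test_that("moment arms follow the tendon-excursion definition", {
  m <- get_model()
  st <- knee_state(flexion_deg = 30)
  # pulley identity: a path wrapped on a cylinder coaxial with the flexion
  # axis has moment arm equal to the cylinder radius
  pulley <- muscle_actuator("p", 1000,
    data.frame(body = c("femur", "tibia"), x = c(10, -10), y = c(70, -80),
               z = c(0, 0)),
    wrap = list(body = "tibia", point = c(0, 36, 0), axis = c(0, 0, 1),
                radius = 25, between = c(1, 2)))
  r <- moment_arm(pulley, m, st, "flexion", delta = 1e-4)
  expect_equal(abs(r), 25, tolerance = 0.1)

  # a path parallel to an axis has no excursion about it
  par_mu <- muscle_actuator("q", 1000,
    data.frame(body = c("tibia", "tibia"), x = c(10, 10), y = c(0, -80),
               z = c(5, 5)))
  expect_equal(moment_arm(par_mu, m, st, "flexion"), 0, tolerance = 1e-6)

  # Richardson check: halving the step changes the result < 0.1%
  ham <- m$muscles$hamstrings_med
  r1 <- moment_arm(ham, m, st, "flexion", delta = 2e-4)
  r2 <- moment_arm(ham, m, st, "flexion", delta = 1e-4)
  expect_lt(abs(r2 - r1) / abs(r2), 1e-3)
  expect_error(moment_arm(ham, m, st, "flexion", delta = 0), "numeric error")
})

test_that("virtual-work consistency: generalized force = tension x moment arm", {
  m <- get_model()
  st <- knee_state(flexion_deg = 30)
  ham <- m$muscles$hamstrings_med
  r <- moment_arm(ham, m, st, "flexion")
  Tf <- 600
  poses <- body_poses(m, st)
  apps <- kneeslope:::muscle_force_entries(ham, poses, Tf)
  # flexion generalized force from the 3D force lines, about the femur origin
  tf <- poses$femur$t
  Q <- 0
  for (ap in apps) {
    if (ap$body != "femur") next
    Q <- Q + kneeslope:::cross3(ap$point - tf, ap$force)[3]
  }
  expect_equal(Q, Tf * r, tolerance = 0.01 * abs(Tf * r))
})

test_that("moment arms are frame-indifferent in the path-length sense", {
  # translating every body identically leaves all path lengths unchanged
  m <- get_model()
  st <- knee_state(flexion_deg = 45)
  poses <- body_poses(m, st)
  R <- kneeslope:::rot_x(0.4); t <- c(5, 5, -10)
  poses2 <- lapply(poses, function(p)
    list(R = R %*% p$R, t = as.numeric(R %*% p$t) + t))
  for (mu in m$muscles)
    expect_equal(path_length(mu, poses2), path_length(mu, poses),
                 tolerance = 1e-9)
})

test_that("the muscle table round-trips through CSV", {
  m <- get_model()
  path <- tempfile(fileext = ".csv")
  write_muscle_table(m$muscles, path)
  back <- read_muscle_table(path)
  expect_setequal(names(back), names(m$muscles))
  expect_equal(back$vasti$Fmax, m$muscles$vasti$Fmax)
  expect_equal(back$vasti$wrap$radius, m$muscles$vasti$wrap$radius)
  expect_equal(back$gastroc_lat$path$y, m$muscles$gastroc_lat$path$y)
  expect_true(back$rectus_femoris$via_patella)
})
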
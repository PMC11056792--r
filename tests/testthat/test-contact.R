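test_that("the foundation modulus and pressure laws evaluate correctly", {
  # hand-evaluated: K = 463 * 0.54 / (1.46 * 0.08) = 2140.58 MPa
  mat <- material_spec(E = 463, nu = 0.46, h = 6, law = "linear")
  expect_equal(mat$K, 463 * 0.54 / (1.46 * 0.08), tolerance = 1e-12)
  expect_equal(pressure_law(0, mat), 0)
  expect_equal(pressure_law(0.01, mat), mat$K * 0.01 / 6, tolerance = 1e-12)

  # nonlinear law agrees with linear to first order in d/h
  matn <- material_spec(E = 463, nu = 0.46, h = 6, law = "nonlinear")
  d <- c(1e-4, 1e-3, 0.06)  # d/h up to 0.01
  expect_true(all(abs(pressure_law(d, matn) / pressure_law(d, mat) - 1) < 0.01))
  # strictly increasing, zero at zero
  dd <- seq(0, 5.9, length.out = 50)
  expect_true(all(diff(pressure_law(dd, mat)) > 0))
  expect_true(all(diff(pressure_law(dd, matn)) > 0))
  expect_error(pressure_law(6, matn), "domain")
  expect_error(material_spec(nu = 0.5), "nu")
})

test_that("penetration depths: separated, uniform, and sphere cases", {
  mat <- material_spec()
  plane <- mesh_plane(half_x = 10, half_z = 10, nx = 12, nz = 12, y0 = 0)
  # separated: sphere well above the plane
  sph <- mesh_sphere(radius = 20, center = c(0, 25, 0), n_theta = 16, n_phi = 32)
  expect_equal(penetration_depths(plane, sph, mat$h), rep(0, nrow(plane$faces)))

  # plane pushed 0.05 mm into plane: uniform depth on the overlapped interior
  lower <- mesh_plane(half_x = 20, half_z = 20, nx = 4, nz = 4, y0 = -0.05,
                      normal = "-y")
  d <- penetration_depths(plane, lower, mat$h)
  expect_true(all(abs(d - 0.05) < 1e-9))

  # sphere lowered 0.1 mm into the plane: max depth at the pole (the plane
  # must sample close to the pole for the geometric check)
  plane_f <- mesh_plane(half_x = 10, half_z = 10, nx = 40, nz = 40, y0 = 0)
  sph2 <- mesh_sphere(radius = 20, center = c(0, 20 - 0.1, 0),
                      n_theta = 48, n_phi = 96, theta_max = pi / 4)
  d2 <- penetration_depths(plane_f, sph2, mat$h)
  expect_lt(abs(max(d2) - 0.1), 5e-3)
})

test_that("sphere-on-plane force matches the closed form and converges", {
  # F = pi K R delta^2 / h for the linear foundation
  mat <- material_spec()
  R <- 20; delta <- 0.1
  Fexact <- pi * mat$K * R * delta^2 / mat$h
  expect_equal(Fexact, 224.2, tolerance = 0.01)

  # refinement study: foundation-plane resolutions of 8, 16 and 32 elements
  # across the contact-patch diameter, plus a fine reference (64) standing in
  # for the converged integral over the (faceted) sphere
  sph <- mesh_sphere(radius = R, center = c(0, R - delta, 0),
                     n_theta = 60, n_phi = 120, theta_max = pi / 6)
  force_at <- function(n) {
    plane <- mesh_plane(half_x = 3, half_z = 3, nx = round(n * 1.5),
                        nz = round(n * 1.5), y0 = 0)
    compute_contact(plane, sph, mat)$F_total[2]
  }
  forces <- vapply(c(8, 16, 32), force_at, numeric(1))
  Fref <- force_at(64)
  expect_lt(abs(forces[1] - Fexact) / Fexact, 0.05)  # >= 64 patch elements
  expect_lt(abs(forces[2] - Fexact) / Fexact, 0.02)  # 256 patch elements
  expect_lt(abs(forces[3] - Fexact) / Fexact, 0.02)
  expect_true(all(diff(abs(forces - Fref)) < 0))
})

test_that("contact bookkeeping: compartments, CoP, moments, Newton pairs", {
  mat <- material_spec()
  a <- get_assembly()
  # symmetric compression of the symmetric assembly
  fem <- transform_mesh(a$local$condyles, diag(3),
                        a$landmarks$femur_origin - c(0, 0.08, 0))
  cr <- compute_contact(a$inlay, fem, mat)
  expect_equal(cr$F_medial_PD, cr$F_lateral_PD, tolerance = 1e-6)
  expect_equal(cr$CoP_medial[3], -cr$CoP_lateral[3], tolerance = 1e-6)
  expect_equal(cr$F_medial_PD + cr$F_lateral_PD, cr$F_total[2],
               tolerance = 1e-9 * abs(cr$F_total[2]))
  # mean pressure times area reproduces the axial force by construction
  expect_equal(cr$mean_pressure * cr$area, cr$F_total[2],
               tolerance = 1e-9 * abs(cr$F_total[2]))

  # CoP inside the convex hull (X-Z) of the pressured centroids
  cf <- face_centroids(a$inlay)
  act <- cr$pressure > 0 & cf[, 3] <= 0
  hull <- grDevices::chull(cf[act, 1], cf[act, 3])
  hx <- cf[act, 1][hull]; hz <- cf[act, 3][hull]
  inside <- function(px, pz) {
    n <- length(hx); s <- 0
    for (i in seq_len(n)) {
      j <- i %% n + 1
      crs <- (hx[j] - hx[i]) * (pz - hz[i]) - (hz[j] - hz[i]) * (px - hx[i])
      s <- s + sign(crs)
    }
    abs(s) == n
  }
  expect_true(inside(cr$CoP_medial[1], cr$CoP_medial[3]))

  # Newton's third law under role swap: forces equal and opposite
  inl_fixed <- a$inlay
  cr_fem <- compute_contact(transform_mesh(a$local$condyles, diag(3),
                                           a$landmarks$femur_origin - c(0, 0.08, 0)),
                            inl_fixed, mat)
  expect_equal(cr_fem$F_total, -cr$F_total, tolerance = 2e-1)

  # zero contact: flagged, not an error
  fem_up <- transform_mesh(a$local$condyles, diag(3),
                           a$landmarks$femur_origin + c(0, 1, 0))
  cr0 <- compute_contact(a$inlay, fem_up, mat)
  expect_equal(cr0$F_total, c(0, 0, 0))
  expect_equal(cr0$area, 0)
  expect_true(all(is.na(cr0$CoP_medial)))
})

test_that("a single loaded face produces the hand cross-product moment", {
  # triangle centred near x = (-10, 0, 0) with area A, normal +Y, uniformly
  # pressed by a plane from above: M = r x F must match the brute-force value
  v <- rbind(c(-11, 0, -1), c(-9, 0, -1), c(-10, 0, 1.5))
  tri <- surface_mesh(v, matrix(c(1, 2, 3), 1),
                      outward_normals = matrix(c(0, 1, 0), 1))
  press <- mesh_plane(half_x = 15, half_z = 5, nx = 2, nz = 2, y0 = -0.01,
                      normal = "-y")
  mat <- material_spec()
  cr <- compute_contact(tri, press, mat)
  p <- pressure_law(0.01, mat)
  A <- tri$areas[1]
  f <- c(0, p * A, 0)
  r <- face_centroids(tri)[1, ]
  expect_equal(cr$F_total, f, tolerance = 1e-9)
  expect_equal(cr$M_total * 1000, c(r[2] * f[3] - r[3] * f[2],
                                    r[3] * f[1] - r[1] * f[3],
                                    r[1] * f[2] - r[2] * f[1]),
               tolerance = 1e-9)
  # an axial force at negative x gives a negative moment about Z
  expect_lt(cr$M_total[3], 0)
})

test_that("foundation exhaustion raises a named error", {
  plane <- mesh_plane(half_x = 5, half_z = 5, nx = 4, nz = 4, y0 = 0)
  deep <- mesh_plane(half_x = 9, half_z = 9, nx = 4, nz = 4, y0 = -6.001,
                     normal = "-y")
  expect_error(penetration_depths(plane, deep, 6), "foundation exhausted")
})
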
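test_that("parametric assembly has the commanded symmetry and dimensions", {
  a <- get_assembly()
  # medial/lateral mirror symmetry of the inlay about Z = 0 at zero varus/slope
  v <- a$inlay$vertices
  vr <- cbind(v[, 1], v[, 2], -v[, 3])
  i1 <- order(v[, 1], v[, 2], v[, 3])
  i2 <- order(vr[, 1], vr[, 2], vr[, 3])
  expect_lt(max(abs(v[i1, ] - vr[i2, ])), 1e-9)

  # condyle lowest points sit at +/- half the condyle spacing
  g <- geometry_params(condyle_spacing = 46)
  a46 <- build_parametric_assembly(g)
  vmed <- a46$local$med_condyle$vertices
  low <- vmed[which.min(vmed[, 2]), ]
  expect_equal(low[3], -23, tolerance = 1e-9)
  expect_equal(low[1], 0, tolerance = 1e-9)
  vlat <- a46$local$lat_condyle$vertices
  expect_equal(vlat[which.min(vlat[, 2]), 3], 23, tolerance = 1e-9)

  # mesh invariants: positive areas, unit normals, finite coordinates
  for (msh in list(a$femoral, a$inlay, a$patellar_button)) {
    expect_true(all(msh$areas > 0))
    expect_equal(sqrt(rowSums(msh$normals^2)), rep(1, nrow(msh$faces)),
                 tolerance = 1e-9)
    expect_true(all(is.finite(msh$vertices)))
  }
})

test_that("doubling the mesh resolution quadruples face counts", {
  n1 <- nrow(build_parametric_assembly(
    geometry_params(elements_per_condyle_width = 8))$inlay$faces)
  n2 <- nrow(build_parametric_assembly(
    geometry_params(elements_per_condyle_width = 16))$inlay$faces)
  expect_lt(abs(n2 / n1 - 4), 0.4)
})

test_that("invalid geometric parameters are rejected", {
  expect_error(geometry_params(condyle_radius_fro = -1), "invalid parameter")
  expect_error(geometry_params(dish_radius_sag = 25), "congruency")
  expect_error(geometry_params(elements_per_condyle_width = 4), "at least 8")
})

test_that("apply_pts rotates the inlay as specified", {
  a <- get_assembly()
  # identity rotation leaves coordinates unchanged
  a0 <- apply_pts(a, 0)
  expect_equal(a0$inlay$vertices, a$inlay$vertices, tolerance = 1e-12)

  # +7 deg: a posterior point (-25, 0, 0) drops to y = -25 sin(7 deg)
  p <- c(-25, 0, 0)
  R <- with(list(th = 7 * pi / 180),
            matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3))
  expect_equal((R %*% p)[2], -25 * sin(7 * pi / 180), tolerance = 1e-12)
  a7 <- apply_pts(a, 7)
  # verify on the actual mesh: rotate a vertex by hand and compare
  expect_equal(a7$inlay$vertices, a$inlay$vertices %*% t(R), tolerance = 1e-9)
  expect_equal(a7$alignment$pts_deg, 7)

  # +5 then -5 restores the original mesh
  back <- apply_pts(apply_pts(a, 5), -5)
  expect_lt(max(abs(back$inlay$vertices - a$inlay$vertices)), 1e-9)

  # group action: (+3 then +4) equals +7
  a34 <- apply_pts(apply_pts(a, 3), 4)
  expect_lt(max(abs(a34$inlay$vertices - a7$inlay$vertices)), 1e-9)

  # rigid: pairwise distances preserved
  idx <- c(1, 50, 200)
  d0 <- dist(a$inlay$vertices[idx, ])
  d7 <- dist(a7$inlay$vertices[idx, ])
  expect_equal(as.numeric(d7), as.numeric(d0), tolerance = 1e-9)

  expect_error(apply_pts(a, 31), "guard rail")
})

test_that("sweep_alignments builds the slope sequence", {
  s <- sweep_alignments(7, 12, 2)
  expect_equal(s, seq(-5, 19, by = 2))
  expect_length(s, 13)
  expect_equal(sweep_alignments(7, 0, 2), 7)
  expect_equal(sweep_alignments(0, 4, 2), c(-4, -2, 0, 2, 4))
  expect_error(sweep_alignments(7, 12, 0), "step")
  expect_error(sweep_alignments(7, 5, 2), "multiple")
})

test_that("the tibial frame validates orthonormality and handedness", {
  f <- tibial_frame()
  expect_equal(crossprod(f$axes), diag(3), tolerance = 1e-10)
  expect_equal(det(f$axes), 1, tolerance = 1e-10)
  expect_error(tibial_frame(axes = matrix(1, 3, 3)), "orthonormal")
  expect_error(tibial_frame(axes = diag(c(1, 1, -1))), "right-handed")
})

test_that("mesh OBJ and STL I/O round-trips", {
  m <- mesh_sphere(radius = 10, n_theta = 6, n_phi = 12)
  fo <- tempfile(fileext = ".obj")
  write_mesh_obj(m, fo)
  m2 <- read_mesh_obj(fo)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(m2$faces, m$faces, ignore_attr = TRUE)

  fs <- tempfile(fileext = ".stl")
  write_mesh_stl(m, fs)
  m3 <- read_mesh_stl(fs)
  # binary STL stores float32: compare to single precision, via face centroids
  expect_equal(face_centroids(m3), face_centroids(m), tolerance = 1e-5)
  expect_equal(sum(m3$areas), sum(m$areas), tolerance = 1e-4)
})
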
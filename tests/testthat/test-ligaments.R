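test_that("the piecewise strand force law has the stated branches", {
  # slack: no force
  expect_equal(strand_force(2750, 100, 0.03, 99), 0)
  # continuity at the quadratic/linear junction, epsilon = 2 eps_l = 0.06
  quad <- 2750 * 0.06^2 / (4 * 0.03)
  lin <- 2750 * (0.06 - 0.03)
  expect_equal(quad, 82.5)
  expect_equal(lin, 82.5)
  expect_equal(strand_force(2750, 100, 0.03, 106), 82.5, tolerance = 1e-9)
  # linear branch arithmetic at epsilon = 0.10
  expect_equal(strand_force(2750, 100, 0.03, 110), 2750 * 0.07, tolerance = 1e-9)
  expect_error(strand_force(2750, 100, 0.03, 0), "positive")
})

test_that("strand force is C1 at the branch transition", {
  k <- 1500; l0 <- 80; eps_l <- 0.03
  Lj <- l0 * (1 + 2 * eps_l)
  h <- 1e-8 * l0
  f <- function(L) strand_force(k, l0, eps_l, L)
  # value continuity
  expect_equal(f(Lj - h), f(Lj + h), tolerance = 1e-6)
  # derivative continuity (central differences either side)
  d_lo <- (f(Lj - h) - f(Lj - 3 * h)) / (2 * h)
  d_hi <- (f(Lj + 3 * h) - f(Lj + h)) / (2 * h)
  expect_equal(d_lo, d_hi, tolerance = 1e-3 * abs(d_hi))
})

test_that("slack-length calibration implements the reference-strain rule", {
  # closed form: L_fe = 102, eps_ref = 0.02 -> l0 = 100
  b <- ligament_bundle("LCL", "tibia", cbind(0, 0, 0), "tibia", cbind(0, -102, 0),
                       k = 2000)
  poses <- body_poses(get_model(), knee_state())
  cal <- calibrate_slack_lengths(list(LCL = b), poses, eps_ref = 0.02)
  expect_equal(cal$LCL$l0, 102 / 1.02, tolerance = 1e-12)
  # eps_ref = 0: slack length equals the full-extension length
  cal0 <- calibrate_slack_lengths(list(LCL = b), poses, eps_ref = 0)
  expect_equal(cal0$LCL$l0, 102, tolerance = 1e-12)
  # post-calibration force equals the quadratic-branch value at eps_ref
  fcal <- strand_force(cal$LCL$k, cal$LCL$l0, cal$LCL$eps_l, 102)
  expect_equal(fcal, 2000 * 0.02^2 / (4 * 0.03), tolerance = 1e-9)
})

test_that("calibration is idempotent and hits 2% strain on the full model", {
  m <- get_model()
  pose0 <- m$calibration_pose
  for (nm in names(m$ligaments)) {
    b <- m$ligaments[[nm]]
    L <- kneeslope:::bundle_lengths(b, pose0)
    expect_equal((L - b$l0) / b$l0, rep(0.02, length(L)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  m2 <- calibrate_model(m)
  for (nm in names(m$ligaments))
    expect_equal(m2$ligaments[[nm]]$l0, m$ligaments[[nm]]$l0,
                 tolerance = 1e-12)
})

test_that("ligament wrenches match single-strand hand computations", {
  poses <- list(tibia = list(R = diag(3), t = c(0, 0, 0)),
                femur = list(R = diag(3), t = c(0, 0, 0)),
                patella = list(R = diag(3), t = c(0, 0, 0)))
  # all strands slack: zero wrench
  slack <- list(X = ligament_bundle("X", "femur", cbind(0, 50, 0), "tibia",
                                    cbind(0, 0, 0), k = 1000, l0 = 60))
  w <- total_ligament_wrench(slack, poses)
  expect_equal(w$force, c(0, 0, 0))
  expect_equal(w$moment, c(0, 0, 0))

  # one vertical strand, tension f at x = (0, 0, 20): M_x = -f * 20 / 1000 N m
  # (force on the insertion pulls toward the origin, i.e. +Y)
  vert <- list(V = ligament_bundle("V", "femur", cbind(0, 50, 20), "tibia",
                                   cbind(0, 0, 20), k = 1000, l0 = 40))
  # length 50, strain 0.25 -> linear branch f = 1000 * (0.25 - 0.03)
  fN <- 1000 * (50 / 40 - 1 - 0.03)
  wv <- total_ligament_wrench(vert, poses)
  expect_equal(wv$force, c(0, fN, 0), tolerance = 1e-9)
  brute <- kneeslope:::cross3(c(0, 0, 20), c(0, fN, 0)) / 1000
  expect_equal(wv$moment, brute, tolerance = 1e-9)
  expect_equal(wv$moment[1], -fN * 20 / 1000, tolerance = 1e-9)

  # symmetric medial/lateral pair: no net L-M force
  pair <- list(
    M = ligament_bundle("M", "femur", cbind(0, 50, -30), "tibia",
                        cbind(0, 0, -30), k = 1000, l0 = 45),
    L = ligament_bundle("L", "femur", cbind(0, 50, 30), "tibia",
                        cbind(0, 0, 30), k = 1000, l0 = 45))
  wp <- total_ligament_wrench(pair, poses)
  expect_equal(wp$force[3], 0, tolerance = 1e-6)

  expect_error(total_ligament_wrench(
    list(Z = ligament_bundle("Z", "femur", cbind(0, 0, 0), "tibia",
                             cbind(0, 0, 0), k = 1, l0 = 1)), poses),
    "geometry error")
})

test_that("ligament forces are frame-indifferent", {
  m <- get_model()
  st <- knee_state(flexion_deg = 15, ap_mm = -2, pd_mm = -0.1)
  poses <- body_poses(m, st)
  w1 <- total_ligament_wrench(m$ligaments, poses)
  # apply one common rigid transform to all bodies: tensions must not change
  R <- kneeslope:::rot_y(0.3) %*% kneeslope:::rot_x(-0.2)
  t <- c(12, -7, 4)
  poses2 <- lapply(poses, function(p)
    list(R = R %*% p$R, t = as.numeric(R %*% p$t) + t))
  # note: "tibia" attachments are stored in tibial coordinates, so transform
  # them through the tibia pose explicitly
  w2 <- total_ligament_wrench(m$ligaments, poses2)
  expect_equal(w2$per_bundle, w1$per_bundle, tolerance = 1e-9)
})

test_that("the ligament table round-trips through CSV", {
  m <- get_model()
  path <- tempfile(fileext = ".csv")
  write_ligament_table(m$ligaments, path)
  back <- read_ligament_table(path)
  expect_setequal(names(back), names(m$ligaments))
  for (nm in names(back)) {
    expect_equal(back[[nm]]$origin, m$ligaments[[nm]]$origin, tolerance = 1e-12)
    expect_equal(back[[nm]]$k, m$ligaments[[nm]]$k)
    expect_equal(back[[nm]]$l0, m$ligaments[[nm]]$l0, tolerance = 1e-12)
  }
})
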
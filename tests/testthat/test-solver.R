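rad2deg_internal <- function(x) x * 180 / pi
deg2rad_t <- function(x) x * pi / 180

test_that("the single-extensor moment balance matches hand statics", {
  toy <- toy_extensor_model(moment_arm_mm = 40, Fmax = 4000)
  sol <- solve_frame(toy, 0, external_load(moment = c(0, 0, 40)))
  expect_equal(unname(sol$activations[[1]]), 0.25, tolerance = 1e-6)
  expect_true(sol$converged)
  # muscle force 1000 N
  expect_equal(unname(sol$muscle_forces[[1]]), 1000, tolerance = 1e-3)

  # no demand: activation stays at the floor
  sol0 <- solve_frame(toy, 0, external_load())
  expect_equal(unname(sol0$activations[[1]]), 0, tolerance = 1e-9)

  # two equal extensors share the demand equally (min sum a^2 symmetry)
  toy2 <- toy_extensor_model(moment_arm_mm = 40, Fmax = 4000, n_extensors = 2)
  sol2 <- solve_frame(toy2, 0, external_load(moment = c(0, 0, 40)))
  expect_equal(unname(sol2$activations[[1]]), unname(sol2$activations[[2]]),
               tolerance = 1e-9)
  expect_equal(sum(sol2$activations * 4000 * 40 / 1000), 40, tolerance = 1e-6)

  # demand beyond capacity is a saturation error naming the deficit
  expect_error(solve_frame(toy, 0, external_load(moment = c(0, 0, 400))),
               "saturation")
})

test_that("full-extension equilibrium reproduces the calibration pose", {
  m <- get_model()
  a0 <- setNames(rep(0, length(m$muscles)), names(m$muscles))
  # the uncalibrated model is in equilibrium at the as-built pose with zero
  # force everywhere; after calibration the pretension settles the joint only
  # slightly away from it
  eq <- secondary_equilibrium(m, 0, a0, external_load(),
                              guess = knee_state(pd_mm = -0.02, pap_mm = -0.02))
  expect_true(eq$converged)
  st <- eq$state
  expect_lt(abs(st[["ap"]]), 0.75)
  expect_lt(abs(st[["pd"]]), 0.25)
  expect_lt(abs(st[["lm"]]), 0.25)
  expect_lt(abs(st[["aa"]]), 0.02)
})

test_that("pure axial load on the symmetric model stays in the sagittal plane", {
  m <- get_model()
  a0 <- setNames(rep(0, length(m$muscles)), names(m$muscles))
  eq <- secondary_equilibrium(m, 0, a0, external_load(force = c(0, -500, 0)),
                              guess = kneeslope:::cold_start_state(m))
  expect_true(eq$converged)
  st <- eq$state
  # out-of-plane coordinates remain at solver tolerance
  expect_lt(abs(st[["lm"]]), 0.05)
  expect_lt(abs(rad2deg_internal(st[["aa"]])), 0.1)
  expect_lt(abs(rad2deg_internal(st[["ie"]])), 0.1)
  # the femur moves distally under compression
  expect_lt(st[["pd"]], 0)
})

test_that("a slope step moves the femoral equilibrium posteriorly", {
  m <- get_model()
  prof <- generate_walking_profile()
  pr <- prof$frames[1, ]
  BW <- m$mass_kg * 9.81
  load <- external_load(c(pr$Fx_BW, pr$Fy_BW, pr$Fz_BW) * BW,
                        c(pr$Mx_Nm, pr$My_Nm, pr$Mz_Nm))
  s0 <- get_frame1()$sol
  m2 <- m
  m2$assembly <- apply_pts(m2$assembly, 2)
  s2 <- solve_frame(m2, get_frame1()$flexion, load)
  expect_true(s2$converged)
  expect_lt(s2$state[["ap"]], s0$state[["ap"]])
})

test_that("converged frames satisfy the stated residual tolerances", {
  f1 <- get_frame1()$sol
  expect_true(f1$converged)
  expect_lt(f1$residual_flexion_Nm, 0.05)
  sec <- f1$residual_secondary
  rot <- names(sec) %in% c("aa", "ie", "pflex", "prot", "ptilt")
  expect_true(all(abs(sec[rot]) < 50))      # N mm = 0.05 N m
  expect_true(all(abs(sec[!rot]) < 0.5))    # N
  expect_true(all(f1$activations >= 0 & f1$activations <= 1))
})

test_that("equilibrium is insensitive to the initial guess", {
  m <- get_model()
  f1 <- get_frame1()
  g1 <- kneeslope:::cold_start_state(m)
  g2 <- g1
  g2[["ap"]] <- g2[["ap"]] + 1.5
  g2[["pd"]] <- g2[["pd"]] - 0.4
  g2[["pflex"]] <- g2[["pflex"]] + 0.2
  a <- f1$sol$activations
  e1 <- secondary_equilibrium(m, f1$flexion, a, f1$load, guess = g1)
  e2 <- secondary_equilibrium(m, f1$flexion, a, f1$load, guess = g2)
  expect_true(e1$converged && e2$converged)
  d <- abs(e1$state - e2$state)
  expect_lt(max(d[c("ap", "pd", "lm")]), 0.01)
  expect_lt(max(d[c("aa", "ie")]) * 180 / pi, 0.01)
})

test_that("a constant-load profile solves to a constant solution", {
  m <- get_model()
  fr <- generate_walking_profile(20)$frames[rep(1, 3), ]
  fr$frame <- 1:3
  prof <- structure(list(name = "const", frames = fr, params = list(),
                         seed = NULL), class = "activity_profile")
  sim <- simulate_activity(m, prof)
  f <- sim$frames
  expect_true(all(f$converged))
  expect_lt(diff(range(f$ap_mm)), 2e-3)
  expect_lt(diff(range(f$F_total_PD_BW)), 1e-3)
  expect_lt(diff(range(f$act_vasti)), 2e-4)
})

test_that("the alternating fixed point converges and matches the concurrent solver", {
  prof <- generate_walking_profile()
  BW <- 95.6 * 9.81
  m_alt <- calibrate_model(knee_model(control = list(method = "alternating")))
  m_con <- get_model()
  s_alt <- NULL; s_con <- NULL
  for (i in 1:3) {
    pr <- prof$frames[i, ]
    load <- external_load(c(pr$Fx_BW, pr$Fy_BW, pr$Fz_BW) * BW,
                          c(pr$Mx_Nm, pr$My_Nm, pr$Mz_Nm))
    s_alt <- solve_frame(m_alt, deg2rad_t(pr$flexion_deg), load, prev = s_alt)
    s_con <- solve_frame(m_con, deg2rad_t(pr$flexion_deg), load, prev = s_con)
    # the activation-objective trace of the alternation settles
    tr <- s_alt$objective_trace
    expect_lt(abs(tr[length(tr)] - tr[length(tr) - 1]), 1e-5)
  }
  expect_true(s_alt$converged && s_con$converged)
  # same equilibrium from both formulations
  d <- abs(s_alt$state - s_con$state)
  expect_lt(max(d[c("ap", "pd", "lm")]), 0.02)
  expect_lt(max(abs(s_alt$activations - s_con$activations)), 5e-3)
})

test_that("a squat excursion to deep flexion solves end to end", {
  m <- get_model()
  prof <- generate_squat_profile(n_frames = 21)
  sim <- simulate_activity(m, prof)
  f <- sim$frames
  expect_gte(mean(f$converged), 0.9)
  expect_equal(max(f$flexion_deg), 90, tolerance = 1e-6)
  # compression grows toward deep flexion and the extensors are recruited
  expect_gt(max(f$F_total_PD_BW), 1.3)
  expect_gt(max(f$act_vasti), 0.05)
  # the femur rides posteriorly on the inlay as the knee flexes
  mid <- which.max(f$flexion_deg)
  expect_lt(f$ap_mm[mid], f$ap_mm[1])
})
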
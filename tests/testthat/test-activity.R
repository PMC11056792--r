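test_that("the walking profile has the stated structure", {
  p <- generate_walking_profile(n_frames = 100)
  f <- p$frames
  expect_equal(f$flexion_deg[1], 5, tolerance = 1e-9)
  expect_equal(max(f$flexion_deg), 55, tolerance = 0.5)
  # exactly two interior local maxima of flexion under defaults
  d <- diff(f$flexion_deg)
  n_max <- sum(d[-length(d)] > 0 & d[-1] < 0)
  expect_equal(n_max, 2)
  # axial load: double hump in stance, exactly zero throughout swing
  stance <- f$time_s / max(f$time_s) * (nrow(f) - 1) / nrow(f)
  swing <- which(seq(0, 1, length.out = nrow(f)) > 0.62)
  expect_true(all(f$Fy_BW[swing] == 0))
  expect_equal(max(-f$Fy_BW), 2.4, tolerance = 0.05)
  ax <- -f$Fy_BW
  dax <- diff(ax)
  expect_gte(sum(dax[-length(dax)] > 0 & dax[-1] < 0), 2)
  expect_error(generate_walking_profile(10), "n_frames")
  expect_error(generate_walking_profile(params = list(bogus = 1)), "unknown")
})

test_that("the squat profile is symmetric with flexion-scaled load", {
  p <- generate_squat_profile(n_frames = 51)
  f <- p$frames
  expect_equal(f$flexion_deg, rev(f$flexion_deg), tolerance = 1e-9)
  expect_equal(max(f$flexion_deg), 90, tolerance = 1e-9)
  expect_equal(-f$Fy_BW[1], 0.5, tolerance = 1e-9)
  expect_equal(max(-f$Fy_BW), 1.3, tolerance = 1e-9)
  expect_equal(max(f$Mz_Nm), 45, tolerance = 1e-9)
  # peak flexion parameter is an identity
  p120 <- generate_squat_profile(n_frames = 51,
                                 params = list(flexion_peak_deg = 120))
  expect_equal(max(p120$frames$flexion_deg), 120, tolerance = 1e-9)
})

test_that("generators are pure functions of parameters and seed", {
  a <- generate_walking_profile(50, seed = 11)
  b <- generate_walking_profile(50, seed = 99)
  expect_identical(a$frames, b$frames)  # sd = 0: seed irrelevant

  n1 <- generate_walking_profile(50, params = list(noise_sd = 0.5), seed = 7)
  n2 <- generate_walking_profile(50, params = list(noise_sd = 0.5), seed = 7)
  n3 <- generate_walking_profile(50, params = list(noise_sd = 0.5), seed = 8)
  expect_identical(n1$frames, n2$frames)
  expect_false(identical(n1$frames, n3$frames))
})

test_that("activity CSV round-trips bit-exactly", {
  p <- generate_walking_profile(40, params = list(noise_sd = 0.1), seed = 3)
  path <- tempfile(fileext = ".csv")
  write_activity_csv(p, path)
  back <- read_activity_csv(path)
  for (cn in names(p$frames))
    expect_identical(back$frames[[cn]], p$frames[[cn]])
})

test_that("reference traces recover the injected noise level", {
  # sd = 0: the trace equals the simulated signal exactly
  df <- data.frame(sig = sin(seq(0, 10, length.out = 200)))
  tr0 <- make_reference_traces(df, list(sig = 0), seed = 1)
  expect_equal(rmse(tr0$sig, df$sig), 0)

  # law of large numbers: at 1e4 frames the RMSE approaches sigma within 5%
  sigma <- 0.37
  df2 <- data.frame(sig = rep(1.5, 1e4))
  tr <- make_reference_traces(df2, list(sig = sigma), seed = 42)
  expect_lt(abs(rmse(tr$sig, df2$sig) - sigma) / sigma, 0.05)

  # seeded reproducibility and unknown-signal error
  tr2 <- make_reference_traces(df2, list(sig = sigma), seed = 42)
  expect_identical(tr$sig, tr2$sig)
  expect_error(make_reference_traces(df2, list(nope = 1)), "key error")
})
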
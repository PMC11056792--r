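# Shared fixtures, built once per test run.  Everything is generated in code;
# no data files.

fixture_env <- new.env(parent = emptyenv())

get_assembly <- function() {
  if (is.null(fixture_env$assembly))
    fixture_env$assembly <- build_parametric_assembly()
  fixture_env$assembly
}

get_model <- function() {
  if (is.null(fixture_env$model))
    fixture_env$model <- calibrate_model(knee_model())
  fixture_env$model
}

# a small frame solve reused by several solver tests: first walking frame
get_frame1 <- function() {
  if (is.null(fixture_env$frame1)) {
    m <- get_model()
    prof <- generate_walking_profile()
    pr <- prof$frames[1, ]
    BW <- m$mass_kg * 9.81
    load <- external_load(c(pr$Fx_BW, pr$Fy_BW, pr$Fz_BW) * BW,
                          c(pr$Mx_Nm, pr$My_Nm, pr$Mz_Nm))
    fixture_env$frame1 <- list(
      sol = solve_frame(m, pr$flexion_deg * pi / 180, load),
      load = load, flexion = pr$flexion_deg * pi / 180)
  }
  fixture_env$frame1
}

skip_slow <- function() invisible(TRUE)  # everything runs; kept for symmetry
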
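#' Synthetic activity profiles
#'
#' Generators for the two functional activities the analysis simulates, as
#' prescribed-flexion plus external-wrench time series.  They stand in for
#' gait-laboratory inputs (marker-driven kinematics and ground reaction
#' forces) with the structure those data have:
#'
#' * level walking (heel strike to heel strike): a small stance flexion bump
#'   and a large swing bump; a double-hump axial load during stance that is
#'   exactly zero throughout swing; flexion-moment and anterior-posterior
#'   shear bumps during stance;
#' * squatting (upright standing, through deep flexion, back to standing): a
#'   single symmetric flexion excursion with an axial load and extensor
#'   demand that grow with flexion.
#'
#' Bumps are Gaussians anchored so the cycle starts exactly at the baseline
#' value.  Outputs are pure functions of `(params, seed)`; optional Gaussian
#' noise is reproducible under the seed.
#'
#' Loads are expressed as the wrench applied to the femur in the tibial frame
#' (see [external_load()]): a compressive axial load appears as a negative
#' `Fy_BW`, an external flexion demand as a positive `Mz_Nm`.
#'
#' @param n_frames number of frames (>= 20)
#' @param params named list of generator-parameter overrides, see
#'   `walking_params()` / `squat_params()`
#' @param seed integer seed for the optional noise
#' @return object of class `activity_profile` with `$frames` (data.frame:
#'   `frame, time_s, flexion_deg, Fx_BW, Fy_BW, Fz_BW, Mx_Nm, My_Nm, Mz_Nm`),
#'   `$name`, `$params`, `$seed`
#' @export
generate_walking_profile <- function(n_frames = 50, params = list(), seed = NULL) {
  p <- modify_defaults(walking_params(), params)
  check_activity_params(p, n_frames)
  t <- seq(0, 1, length.out = n_frames)
  flex <- p$flexion_baseline_deg +
    anchored_bump(t, p$stance_flexion_peak_deg - p$flexion_baseline_deg,
                  p$stance_flexion_center, p$stance_flexion_width) +
    anchored_bump(t, p$swing_flexion_peak_deg - p$flexion_baseline_deg,
                  p$swing_flexion_center, p$swing_flexion_width)
  stance <- t <= p$stance_fraction
  axial <- (gauss_bump(t, p$axial_peak1_BW, p$stance_fraction * p$axial_center1,
                       p$axial_width) +
            gauss_bump(t, p$axial_peak2_BW, p$stance_fraction * p$axial_center2,
                       p$axial_width)) * stance
  shear <- (gauss_bump(t, p$shear_peak_BW, p$stance_fraction * 0.25, p$axial_width) -
            gauss_bump(t, p$shear_peak_BW, p$stance_fraction * 0.8, p$axial_width)) * stance
  mz <- gauss_bump(t, p$fe_moment_peak1_Nm, p$stance_fraction * p$axial_center1,
                   p$moment_width) +
    gauss_bump(t, p$fe_moment_peak2_Nm, p$stance_fraction * p$axial_center2,
               p$moment_width) +
    gauss_bump(t, p$fe_moment_swing_Nm, p$swing_flexion_center, p$swing_flexion_width)
  fr <- data.frame(frame = seq_len(n_frames), time_s = t * p$cycle_duration_s,
                   flexion_deg = flex, Fx_BW = shear, Fy_BW = -axial, Fz_BW = 0,
                   Mx_Nm = 0, My_Nm = 0, Mz_Nm = mz)
  fr <- add_activity_noise(fr, p$noise_sd, seed)
  structure(list(name = "walking", frames = fr, params = p, seed = seed),
            class = "activity_profile")
}

#' @rdname generate_walking_profile
#' @export
generate_squat_profile <- function(n_frames = 50, params = list(), seed = NULL) {
  p <- modify_defaults(squat_params(), params)
  check_activity_params(p, n_frames)
  t <- seq(0, 1, length.out = n_frames)
  s <- sin(pi * t)^2
  flex <- p$flexion_baseline_deg + (p$flexion_peak_deg - p$flexion_baseline_deg) * s
  excursion <- deg2rad(flex - p$flexion_baseline_deg)
  axial <- p$axial_baseline_BW + (p$axial_peak_BW - p$axial_baseline_BW) *
    sin(excursion) / sin(deg2rad(p$flexion_peak_deg - p$flexion_baseline_deg))
  demand <- (flex - p$flexion_baseline_deg) / (p$flexion_peak_deg - p$flexion_baseline_deg)
  mz <- p$fe_moment_peak_Nm * demand
  fr <- data.frame(frame = seq_len(n_frames), time_s = t * p$cycle_duration_s,
                   flexion_deg = flex, Fx_BW = 0, Fy_BW = -axial, Fz_BW = 0,
                   Mx_Nm = 0, My_Nm = 0, Mz_Nm = mz)
  fr <- add_activity_noise(fr, p$noise_sd, seed)
  structure(list(name = "squat", frames = fr, params = p, seed = seed),
            class = "activity_profile")
}

#' Default walking generator parameters
#'
#' Flexion: 5 deg baseline, 13 deg stance peak at 15 percent cycle (width 8
#' percent), 55 deg swing peak at 72 percent (width 9 percent).  Axial load:
#' double hump, 2.4 and 2.2 BW at 25 and 75 percent of stance (stance
#' fraction 0.62), zero in swing.  External flexion-extension demand and
#' anterior-posterior shear are scaled bumps over stance.
#'
#' @return named list of parameters
#' @export
walking_params <- function() {
  list(flexion_baseline_deg = 5, stance_flexion_peak_deg = 13,
       stance_flexion_center = 0.15, stance_flexion_width = 0.08,
       swing_flexion_peak_deg = 55, swing_flexion_center = 0.72,
       swing_flexion_width = 0.09,
       stance_fraction = 0.62,
       axial_peak1_BW = 2.4, axial_center1 = 0.25,
       axial_peak2_BW = 2.2, axial_center2 = 0.75,
       axial_width = 0.07,
       shear_peak_BW = 0.15,
       fe_moment_peak1_Nm = 35, fe_moment_peak2_Nm = 25,
       fe_moment_swing_Nm = 8, moment_width = 0.08,
       cycle_duration_s = 1.1, noise_sd = 0)
}

#' @rdname walking_params
#' @export
squat_params <- function() {
  list(flexion_baseline_deg = 5, flexion_peak_deg = 90,
       axial_baseline_BW = 0.5, axial_peak_BW = 1.3,
       fe_moment_peak_Nm = 45, cycle_duration_s = 4.5, noise_sd = 0)
}

gauss_bump <- function(t, amp, center, width) {
  amp * exp(-0.5 * ((t - center) / width)^2)
}

# bump re-anchored so the value at t = 0 is exactly zero and the peak exactly
# amp; the correction is itself a Gaussian pinned at t = 0, so it vanishes
# away from the cycle start instead of offsetting the whole curve
anchored_bump <- function(t, amp, center, width) {
  g <- exp(-0.5 * ((t - center) / width)^2)
  g0 <- exp(-0.5 * (center / width)^2)
  corr <- g0 * exp(-0.5 * (t / width)^2)
  amp * (g - corr) / (1 - g0^2)
}

modify_defaults <- function(defaults, overrides) {
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("parameter error: unknown generator parameter(s) ",
         paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  defaults
}

check_activity_params <- function(p, n_frames) {
  if (n_frames < 20) stop("parameter error: n_frames must be at least 20")
  widths <- p[grep("width", names(p))]
  if (any(unlist(widths) <= 0)) stop("parameter error: bump widths must be positive")
  if (any(!is.finite(unlist(p)))) stop("parameter error: non-finite parameter")
  invisible(p)
}

add_activity_noise <- function(fr, sd, seed) {
  if (sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig <- c("flexion_deg", "Fx_BW", "Fy_BW", "Mz_Nm")
    for (s in sig) fr[[s]] <- fr[[s]] + stats::rnorm(nrow(fr), 0, sd)
  }
  fr
}

#' @export
print.activity_profile <- function(x, ...) {
  f <- x$frames
  cat(sprintf("activity_profile '%s': %d frames over %.2f s\n",
              x$name, nrow(f), max(f$time_s)))
  cat(sprintf("  flexion %.1f..%.1f deg, peak axial %.2f BW, peak F-E demand %.1f N m\n",
              min(f$flexion_deg), max(f$flexion_deg), max(-f$Fy_BW), max(f$Mz_Nm)))
  invisible(x)
}

#' @export
plot.activity_profile <- function(x, ...) {
  f <- x$frames
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  t <- 100 * (f$frame - 1) / (nrow(f) - 1)
  graphics::plot(t, f$flexion_deg, type = "l", xlab = "% cycle",
                 ylab = "deg", main = "flexion")
  graphics::plot(t, -f$Fy_BW, type = "l", xlab = "% cycle",
                 ylab = "BW", main = "axial load")
  graphics::plot(t, f$Mz_Nm, type = "l", xlab = "% cycle",
                 ylab = "N m", main = "F-E demand")
  invisible(x)
}

#' Activity profile CSV I/O
#'
#' Round-trips a profile's frame table bit-exactly (full double precision).
#'
#' @param profile an `activity_profile`
#' @param path CSV path
#' @export
write_activity_csv <- function(profile, path) {
  fr <- profile$frames
  num <- vapply(fr, is.numeric, TRUE)
  out <- fr
  for (j in names(fr)[num]) out[[j]] <- sprintf("%.17g", fr[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @param name activity name for the reconstructed profile
#' @export
read_activity_csv <- function(path, name = "custom") {
  fr <- utils::read.csv(path)
  for (cn in setdiff(names(fr), "frame")) fr[[cn]] <- as.numeric(fr[[cn]])
  fr$frame <- as.integer(fr$frame)
  structure(list(name = name, frames = fr, params = list(), seed = NULL),
            class = "activity_profile")
}

#' Noisy reference traces for validation statistics
#'
#' Adds i.i.d. Gaussian noise to selected simulated signals, producing
#' synthetic "measured" traces on which the RMSE / peak-error machinery can be
#' exercised.  With `sd = 0` the trace equals the simulation exactly.
#'
#' @param simulation a [simulate_activity()] result, or a data.frame of
#'   signals
#' @param noise_sd named numeric vector/list: per-signal noise s.d. (signal
#'   units)
#' @param seed integer seed
#' @return named list of numeric traces (class `reference_traces`)
#' @export
make_reference_traces <- function(simulation, noise_sd, seed = 1L) {
  df <- if (inherits(simulation, "knee_simulation")) simulation$frames else
    as.data.frame(simulation)
  set.seed(seed)
  out <- list()
  for (nm in names(noise_sd)) {
    if (!nm %in% names(df)) stop("key error: unknown signal '", nm, "'")
    sdv <- noise_sd[[nm]]
    out[[nm]] <- df[[nm]] + if (sdv > 0) stats::rnorm(nrow(df), 0, sdv) else 0
  }
  structure(out, class = "reference_traces")
}
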
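#' Spearman rank correlation
#'
#' Average ranks (midranks for ties) of both vectors, then the Pearson
#' correlation of the ranks.  Returns `NA` (flagged missing, never coerced to
#' zero) when either rank vector has zero variance.
#'
#' @param x,y equal-length numeric vectors, length >= 3
#' @return rho in `[-1, 1]`, or `NA`
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / sqrt(sx * sy)
}

#' Root-mean-square error between two traces
#'
#' @param a,b equal-length numeric vectors
#' @return `sqrt(mean((a - b)^2))`, in the units of the inputs
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 1) stop("need at least one sample")
  sqrt(mean((a - b)^2))
}

#' Peak absolute error between two traces
#'
#' @param a,b equal-length numeric vectors
#' @return `max(abs(a - b))`
#' @export
peak_error <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  max(abs(a - b))
}

#' Extract per-simulation outcome metrics
#'
#' Peaks (max over frames) and ranges (max - min) of the kinematic, kinetic,
#' contact, ligament and muscle outputs of one simulated activity, the
#' per-alignment rows of the sensitivity analysis.  The corrected knee flexion
#' subtracts the shift in posterior tibial slope from the prescribed implant
#' flexion, so that alignment-induced reorientation of the component is not
#' mistaken for a change in knee flexion.  The anterior-posterior femoral
#' position at the most extended frame is kept as its own metric (`peaks` of
#' sliding quantities live on the full cycle).
#'
#' Frames that did not converge are excluded from every extremum and listed
#' in the `excluded_frames` attribute; the metrics are flagged via
#' `any_nonconverged`.
#'
#' @param simulation a [simulate_activity()] result
#' @param pts_deg alignment of the simulated model (deg)
#' @param baseline_pts_deg baseline alignment (deg)
#' @return one-row data.frame of metrics
#' @export
extract_metrics <- function(simulation, pts_deg = NA_real_,
                            baseline_pts_deg = 7) {
  f <- simulation$frames
  excl <- f$frame[!f$converged]
  g <- f[f$converged, , drop = FALSE]
  if (nrow(g) == 0) stop("no converged frames to extract metrics from")
  pk <- function(v) max(v, na.rm = TRUE)
  rg <- function(v) diff(range(v, na.rm = TRUE))

  corrected_flexion <- g$flexion_deg -
    (if (is.na(pts_deg)) 0 else pts_deg - baseline_pts_deg)

  out <- data.frame(
    pts_deg = pts_deg,
    peak_F_total_PD_BW = pk(g$F_total_PD_BW), range_F_total_PD_BW = rg(g$F_total_PD_BW),
    peak_F_med_PD_BW = pk(g$F_med_PD_BW), range_F_med_PD_BW = rg(g$F_med_PD_BW),
    peak_F_lat_PD_BW = pk(g$F_lat_PD_BW), range_F_lat_PD_BW = rg(g$F_lat_PD_BW),
    peak_F_total_AP_BW = pk(abs(g$F_total_AP_BW)), range_F_total_AP_BW = rg(g$F_total_AP_BW),
    peak_F_total_LM_BW = pk(abs(g$F_total_LM_BW)), range_F_total_LM_BW = rg(g$F_total_LM_BW),
    peak_M_FE_Nm = pk(abs(g$M_FE_Nm)), range_M_FE_Nm = rg(g$M_FE_Nm),
    peak_M_AA_Nm = pk(abs(g$M_AA_Nm)), range_M_AA_Nm = rg(g$M_AA_Nm),
    peak_M_IE_Nm = pk(abs(g$M_IE_Nm)), range_M_IE_Nm = rg(g$M_IE_Nm),
    peak_CoP_med_AP_mm = pk(g$CoP_med_x_mm), range_CoP_med_AP_mm = rg(g$CoP_med_x_mm),
    peak_CoP_lat_AP_mm = pk(g$CoP_lat_x_mm), range_CoP_lat_AP_mm = rg(g$CoP_lat_x_mm),
    peak_TFCA_mm2 = pk(g$TFCA_mm2), range_TFCA_mm2 = rg(g$TFCA_mm2),
    peak_TFCP_MPa = pk(g$TFCP_MPa), range_TFCP_MPa = rg(g$TFCP_MPa),
    peak_PF_F_BW = pk(g$PF_F_BW), range_PF_F_BW = rg(g$PF_F_BW),
    peak_PFCP_MPa = pk(g$PFCP_MPa), range_PFCP_MPa = rg(g$PFCP_MPa),
    CoP_med_AP_at_peak2_mm = cop_at_late_stance_peak(g, "CoP_med_x_mm"),
    CoP_lat_AP_at_peak2_mm = cop_at_late_stance_peak(g, "CoP_lat_x_mm"),
    peak_F_ap_anterior_tibia_BW = pk(-g$F_total_AP_BW),
    ap_at_extension_mm = g$ap_mm[which.min(g$flexion_deg)],
    range_ap_mm = rg(g$ap_mm),
    range_aa_deg = rg(g$aa_deg), range_ie_deg = rg(g$ie_deg),
    range_pat_flex_deg = rg(g$pat_flex_deg), range_pat_rot_deg = rg(g$pat_rot_deg),
    range_pat_tilt_deg = rg(g$pat_tilt_deg),
    range_pat_ap_mm = rg(g$pat_ap_mm), range_pat_lm_mm = rg(g$pat_lm_mm),
    corrected_flexion_range_deg = rg(corrected_flexion),
    any_nonconverged = length(excl) > 0
  )
  out$peak_quadriceps_N <- pk(g$F_vasti_N + g$F_rectus_femoris_N)
  out$peak_hamstrings_N <- pk(g$F_hamstrings_med_N + g$F_hamstrings_lat_N)
  out$peak_gastrocnemius_N <- pk(g$F_gastroc_med_N + g$F_gastroc_lat_N)
  for (nm in grep("^lig_", names(g), value = TRUE))
    out[[paste0("peak_", sub("_N$", "", nm), "_N")]] <- pk(g[[nm]])
  attr(out, "excluded_frames") <- excl
  out
}

# Centre of pressure sampled at the late-stance axial-force peak (the second
# hump of a walking cycle, around half cycle), the fixed cycle point at which
# compartmental CoP positions are compared across alignments.  Falls back to
# the global force peak for non-walking traces.
cop_at_late_stance_peak <- function(g, col) {
  n <- nrow(g)
  win <- which(seq_len(n) >= 0.35 * n & seq_len(n) <= 0.7 * n)
  if (length(win) < 1) win <- seq_len(n)
  i2 <- win[which.max(g$F_total_PD_BW[win])]
  g[[col]][i2]
}

#' Run the posterior-tibial-slope sweep
#'
#' Builds and calibrates the model once at the baseline alignment, then
#' simulates the activity at every commanded slope with identical profile and
#' seeds (ligament slack lengths frozen across the sweep, so implantation
#' changes express themselves as mechanics), extracts the outcome metrics per
#' alignment, and computes Spearman rank correlations between slope and every
#' metric.  Report rows are in ascending slope order regardless of the order
#' the alignments are given in.
#'
#' @param model a [knee_model()] (calibrated or not; calibration happens at
#'   the baseline alignment)
#' @param profile the activity to simulate at every alignment
#' @param pts_list slope angles (deg), e.g. [sweep_alignments()]
#' @param control solver control
#' @param verbose progress output
#' @return object of class `pts_sweep`: `$metrics` (alignment x metric
#'   data.frame), `$sensitivity` (metric, rho), `$simulations` (named list),
#'   `$pts`, `$convergence`
#' @export
run_pts_sweep <- function(model, profile, pts_list = sweep_alignments(),
                          control = model$control, verbose = FALSE) {
  pts_list <- sort(unique(pts_list))
  base <- model$assembly$alignment$baseline_pts_deg
  if (!model$calibrated) model <- calibrate_model(model)

  # each alignment is simulated independently (frames within a run warm-start
  # sequentially; the altered dish geometry makes cross-alignment warm starts
  # counterproductive)
  sims <- vector("list", length(pts_list))
  for (idx in seq_along(pts_list)) {
    pts <- pts_list[idx]
    mdl <- model
    mdl$assembly <- apply_pts(mdl$assembly, pts - mdl$assembly$alignment$pts_deg)
    if (verbose) cat(sprintf("PTS %+.0f deg ...\n", pts))
    sims[[idx]] <- tryCatch(
      simulate_activity(mdl, profile, control = control),
      error = function(e) stop(sprintf("sweep aborted at PTS %+.0f deg: %s",
                                       pts, conditionMessage(e))))
  }

  metrics <- do.call(rbind, lapply(seq_along(pts_list), function(i)
    extract_metrics(sims[[i]], pts_deg = pts_list[i], baseline_pts_deg = base)))
  rownames(metrics) <- NULL

  mcols <- setdiff(names(metrics), c("pts_deg", "any_nonconverged"))
  sensitivity <- data.frame(
    metric = mcols,
    rho = vapply(mcols, function(cn) spearman_rho(metrics$pts_deg, metrics[[cn]]),
                 numeric(1)),
    row.names = NULL
  )
  names(sims) <- sprintf("pts_%+03d", as.integer(round(pts_list)))
  structure(list(pts = pts_list, metrics = metrics, sensitivity = sensitivity,
                 simulations = sims, baseline_pts_deg = base,
                 profile_name = profile$name,
                 convergence = vapply(sims, `[[`, 0, "converged_fraction")),
            class = "pts_sweep")
}

#' @export
print.pts_sweep <- function(x, ...) {
  cat(sprintf("pts_sweep: %s, %d alignments (%.0f to %.0f deg, baseline %.0f)\n",
              x$profile_name, length(x$pts), min(x$pts), max(x$pts),
              x$baseline_pts_deg))
  cat(sprintf("  convergence: %.0f%% (worst alignment)\n",
              100 * min(x$convergence)))
  key <- c("CoP_med_AP_at_peak2_mm", "CoP_lat_AP_at_peak2_mm",
           "ap_at_extension_mm", "peak_quadriceps_N",
           "peak_F_ap_anterior_tibia_BW", "peak_PF_F_BW")
  s <- x$sensitivity
  cat("  Spearman rho vs PTS (key metrics):\n")
  for (k in key) {
    r <- s$rho[s$metric == k]
    if (length(r)) cat(sprintf("    %-24s %+0.3f\n", k, r))
  }
  invisible(x)
}

#' @export
summary.pts_sweep <- function(object, ...) {
  print(object)
  s <- object$sensitivity
  s <- s[order(-abs(s$rho)), ]
  cat("  strongest sensitivities:\n")
  for (i in seq_len(min(12, nrow(s))))
    cat(sprintf("    %-28s %+0.3f\n", s$metric[i], s$rho[i]))
  invisible(object)
}

#' @export
plot.pts_sweep <- function(x, ...) {
  m <- x$metrics
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(m$pts_deg, cbind(m$peak_CoP_med_AP_mm, m$peak_CoP_lat_AP_mm),
                    type = "b", pch = 1, lty = 1, xlab = "PTS (deg)",
                    ylab = "CoP A-P (mm)", main = "centre of pressure")
  graphics::plot(m$pts_deg, m$ap_at_extension_mm, type = "b", xlab = "PTS (deg)",
                 ylab = "A-P (mm)", main = "femoral A-P at extension")
  graphics::plot(m$pts_deg, m$peak_quadriceps_N, type = "b", xlab = "PTS (deg)",
                 ylab = "N", main = "peak quadriceps force")
  graphics::plot(m$pts_deg, m$peak_F_total_PD_BW, type = "b", xlab = "PTS (deg)",
                 ylab = "BW", main = "peak axial TF force")
  invisible(x)
}

#' Write a sweep report to disk
#'
#' Writes `metrics.csv` (alignment x metric), `sensitivity.csv` (metric, rho;
#' missing rho serialized as an empty cell), per-alignment `frames_pts*.csv`,
#' a `config.yaml` snapshot and a `run.log`.  Output is deterministic:
#' identical sweeps produce byte-identical files.
#'
#' @param report a [run_pts_sweep()] result
#' @param out_dir output directory (created if missing)
#' @param config optional study configuration list to snapshot
#' @return invisibly, the paths written
#' @export
write_report <- function(report, out_dir, config = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fmt <- function(df) {
    out <- df
    for (j in names(df)) if (is.numeric(df[[j]])) out[[j]] <- sprintf("%.12g", df[[j]])
    for (j in names(out)) out[[j]][out[[j]] %in% c("NA", NA)] <- ""
    out
  }
  paths <- character(0)
  p <- file.path(out_dir, "metrics.csv")
  utils::write.csv(fmt(report$metrics), p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "sensitivity.csv")
  utils::write.csv(fmt(report$sensitivity), p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  for (i in seq_along(report$pts)) {
    p <- file.path(out_dir, sprintf("frames_pts%+03d.csv",
                                    as.integer(round(report$pts[i]))))
    utils::write.csv(fmt(report$simulations[[i]]$frames), p,
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(config)) {
    p <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(config, p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "run.log")
  writeLines(c(sprintf("activity: %s", report$profile_name),
               sprintf("alignments: %s", paste(report$pts, collapse = " ")),
               sprintf("baseline: %s", report$baseline_pts_deg),
               sprintf("convergence: %s",
                       paste(sprintf("%.3f", report$convergence), collapse = " "))),
             p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Study configuration I/O
#'
#' The study configuration is a plain named list with blocks `geometry`,
#' `material`, `activity`, `sweep`, `solver`, `subject`; it round-trips
#' through YAML.  [default_config()] documents every field with its default.
#'
#' @return named list
#' @export
default_config <- function() {
  list(
    subject = list(mass_kg = 95.6),
    geometry = unclass(geometry_params()),
    material = unclass(material_spec())[c("E", "nu", "h", "law")],
    activity = list(walking = walking_params(), squat = squat_params(),
                    n_frames = 50),
    sweep = list(baseline_pts_deg = 7, half_range_deg = 12, step_deg = 2),
    solver = unclass(solver_control())
  )
}

#' @rdname default_config
#' @param path YAML file path
#' @export
read_study_config <- function(path) yaml::read_yaml(path)

#' @rdname default_config
#' @param config configuration list
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build a knee model from a study configuration
#'
#' @param config a configuration list as from [default_config()]
#' @return an uncalibrated [knee_model()]
#' @export
model_from_config <- function(config = default_config()) {
  geom <- do.call(geometry_params, config$geometry)
  mat <- do.call(material_spec, config$material)
  knee_model(geometry = geom, material = mat, mass_kg = config$subject$mass_kg,
             control = config$solver)
}
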
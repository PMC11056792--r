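# Internal fast paths for the per-frame equilibrium assembly.  These compute
# exactly what compute_contact() / ligament_force_entries() compute, but work
# from cached centroid/normal/area tables and accumulate wrenches directly,
# avoiding intermediate mesh objects in the solver's hot loop.  Consistency
# with the public functions is asserted in the test suite.

# evaluation counter for performance diagnostics (internal)
perf <- new.env(parent = emptyenv())
perf$raycasts <- 0

mesh_cache <- function(mesh) {
  list(V = mesh$vertices, F = mesh$faces, C = face_centroids(mesh),
       N = mesh$normals, A = mesh$areas)
}

transform_cache_target <- function(cache, R, t) {
  list(C = transform_points(cache$C, R, t), N = cache$N %*% t(R), A = cache$A)
}

# raycast from target cache (already posed) into opposing cache posed by R, t;
# returns per-face depth
cache_depths <- function(tg, op, R, t, h) {
  perf$raycasts <- perf$raycasts + 1
  orig <- tg$C
  dirs <- -tg$N
  V <- transform_points(op$V, R, t)
  lo <- pmin(apply(orig, 2, min), apply(orig + dirs * h * 1.001, 2, min)) - 1e-9
  hi <- pmax(apply(orig, 2, max), apply(orig + dirs * h * 1.001, 2, max)) + 1e-9
  fc <- op$F
  keep <- rep(TRUE, nrow(fc))
  for (j in 1:3) {
    cmin <- pmin(V[fc[, 1], j], V[fc[, 2], j], V[fc[, 3], j])
    cmax <- pmax(V[fc[, 1], j], V[fc[, 2], j], V[fc[, 3], j])
    keep <- keep & cmax >= lo[j] & cmin <= hi[j]
  }
  if (!any(keep)) return(numeric(nrow(orig)))
  d <- .raycast_depths(orig, dirs, V, fc[keep, , drop = FALSE], h * 1.001)
  if (any(d >= h - 1e-12))
    stop(sprintf("foundation exhausted: penetration >= h on face(s) %s",
                 paste(utils::head(which(d >= h - 1e-12), 5), collapse = ", ")))
  d
}

# wrench (about the world origin) and summary quantities of one contact pair
cache_contact <- function(tg, op, R, t, mat, detail = FALSE) {
  d <- cache_depths(tg, op, R, t, mat$h)
  p <- if (mat$law == "nonlinear") -mat$K * log(1 - d / mat$h) else
    mat$K * d / mat$h
  w <- p * tg$A
  f <- w * tg$N
  F <- colSums(f)
  M <- colSums(cross3m(tg$C, f))
  out <- list(F = F, M = M, axial = F[2])
  if (detail) {
    act <- p > 0
    out$p <- p; out$d <- d
    out$area <- sum(tg$A[act])
    out$peak_pressure <- if (any(act)) max(p) else 0
    out$cop <- if (sum(w) > 0) colSums(tg$C * w) / sum(w) else rep(NA_real_, 3)
    out$wsum <- sum(w)
  }
  out
}

# full tibiofemoral contact via the per-compartment caches; returns a
# contact_result-compatible list
tf_contact_fast <- function(asm, mat, Rf, tf, detail = FALSE) {
  med <- cache_contact(asm$cache$inlay_med, asm$cache$med_condyle, Rf, tf, mat,
                       detail = detail)
  lat <- cache_contact(asm$cache$inlay_lat, asm$cache$lat_condyle, Rf, tf, mat,
                       detail = detail)
  F <- med$F + lat$F
  M <- med$M + lat$M
  res <- list(F_total = F, M_total = (M - cross3(asm$frame$origin, F)) / 1000,
              M0 = M, F_medial_PD = med$axial, F_lateral_PD = lat$axial)
  if (detail) {
    area <- med$area + lat$area
    res$CoP_medial <- med$cop
    res$CoP_lateral <- lat$cop
    res$CoP_overall <- if ((med$wsum + lat$wsum) > 0)
      (ifelse(is.na(med$cop), 0, med$cop) * med$wsum +
         ifelse(is.na(lat$cop), 0, lat$cop) * lat$wsum) / (med$wsum + lat$wsum)
    else rep(NA_real_, 3)
    res$area <- area
    res$mean_pressure <- if (area > 0) F[2] / area else 0
    res$peak_pressure <- max(med$peak_pressure, lat$peak_pressure)
  }
  res
}

pf_contact_fast <- function(asm, mat, Rp, tp, Rf, tf, detail = FALSE) {
  tg <- transform_cache_target(asm$cache$button, Rp, tp)
  r <- cache_contact(tg, asm$cache$trochlea, Rf, tf, mat, detail = detail)
  res <- list(F_total = r$F, M_total = (r$M - cross3(asm$frame$origin, r$F)) / 1000,
              M0 = r$M)
  if (detail) {
    res$area <- r$area
    res$mean_pressure <- if (r$area > 0) vnorm(r$F) / r$area else 0
    res$peak_pressure <- r$peak_pressure
    res$CoP_overall <- r$cop
  }
  res
}

# ligament wrenches on femur and patella, vectorized over strands
ligament_wrench_fast <- function(bundles, poses) {
  Ff <- c(0, 0, 0); Mf <- c(0, 0, 0)
  Fp <- c(0, 0, 0); Mp <- c(0, 0, 0)
  tension <- setNames(numeric(length(bundles)), names(bundles))
  for (nm in names(bundles)) {
    b <- bundles[[nm]]
    o <- map_points(b$origin, b$origin_body, poses)
    i <- map_points(b$insertion, b$insertion_body, poses)
    dvec <- o - i
    L <- sqrt(rowSums(dvec^2))
    if (any(L <= 0)) stop("geometry error: coincident ligament endpoints in ", nm)
    f <- strand_force(b$k, b$l0, b$eps_l, L)
    tension[nm] <- sum(f)
    if (all(f == 0)) next
    u <- dvec / L
    fi <- f * u            # force on insertion body (toward origin)
    if (b$insertion_body == "femur") {
      Ff <- Ff + colSums(fi); Mf <- Mf + colSums(cross3m(i, fi))
    } else if (b$insertion_body == "patella") {
      Fp <- Fp + colSums(fi); Mp <- Mp + colSums(cross3m(i, fi))
    }
    if (b$origin_body == "femur") {
      Ff <- Ff - colSums(fi); Mf <- Mf - colSums(cross3m(o, fi))
    } else if (b$origin_body == "patella") {
      Fp <- Fp - colSums(fi); Mp <- Mp - colSums(cross3m(o, fi))
    }
  }
  list(Ff = Ff, Mf = Mf, Fp = Fp, Mp = Mp, tension = tension)
}
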
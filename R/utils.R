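#' @useDynLib kneeslope, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm sd cor optimize runif setNames
#' @importFrom utils write.csv read.csv
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, angle in radians.
#' In the tibial frame (X anterior, Y superior, Z lateral for a right knee)
#' a positive rotation about Z tilts +Y towards -X, i.e. knee flexion of the
#' femur and, applied to the inlay, a posterior-inferior tilt (positive
#' posterior tibial slope).
#'
#' @param a angle (rad)
#' @return 3x3 rotation matrix
#' @keywords internal
rot_x <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_y <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_z <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rowwise cross product of n x 3 matrices
cross3m <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# apply rigid transform to n x 3 point matrix: p' = p R^T + t
transform_points <- function(p, R, t = c(0, 0, 0)) {
  out <- p %*% t(R)
  out[, 1] <- out[, 1] + t[1]
  out[, 2] <- out[, 2] + t[2]
  out[, 3] <- out[, 3] + t[3]
  out
}
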
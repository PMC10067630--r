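#' Project a vector onto the tangent plane of a unit normal
#'
#' Removes the normal component of `v`, returning `v - (v . n) n`. This is
#' the projection used to keep polarity vectors and guidance directions in
#' the local tangent plane of the spherical shell.
#'
#' @param v numeric length-3 vector.
#' @param n unit numeric length-3 vector (checked to within 1e-6).
#' @return numeric length-3 vector orthogonal to `n`.
#' @examples
#' tangential_project(c(1, 1, 1), c(0, 0, 1))  # (1, 1, 0)
#' @export
tangential_project <- function(v, n) {
  stopifnot(length(v) == 3, length(n) == 3)
  if (abs(sqrt(sum(n^2)) - 1) > .unit_tol) {
    stop("`n` must be a unit vector")
  }
  v - sum(v * n) * n
}

#' Signed angle between two directions in a tangent plane
#'
#' The angle `alpha` in (-pi, pi] such that rotating the tangential
#' component of `a` about `n` by `alpha` aligns it with the tangential
#' component of `b`. Positive angles are counter-clockwise when viewed from
#' the tip of `n` (right-hand rule). Unlike the non-negative `acos` form,
#' the sign encodes the turning direction, which the repolarization
#' dynamics need in order to rotate toward (or away from) a target.
#'
#' @param a,b numeric length-3 vectors with nonzero tangential components.
#' @param n unit normal of the tangent plane.
#' @return angle in radians, or `NA_real_` when either tangential component
#'   vanishes (undefined angle; callers skip the corresponding term).
#' @export
signed_tangent_angle <- function(a, b, n) {
  stopifnot(length(a) == 3, length(b) == 3, length(n) == 3)
  if (abs(sqrt(sum(n^2)) - 1) > .unit_tol) {
    stop("`n` must be a unit vector")
  }
  at <- a - sum(a * n) * n
  bt <- b - sum(b * n) * n
  if (sqrt(sum(at^2)) < 1e-12 || sqrt(sum(bt^2)) < 1e-12) {
    return(NA_real_)
  }
  cr <- c(
    at[2] * bt[3] - at[3] * bt[2],
    at[3] * bt[1] - at[1] * bt[3],
    at[1] * bt[2] - at[2] * bt[1]
  )
  atan2(sum(n * cr), sum(at * bt))
}

#' Rotate a unit vector about an axis (Rodrigues formula)
#'
#' @param p unit numeric length-3 vector to rotate.
#' @param n unit rotation axis.
#' @param alpha rotation angle in radians.
#' @return rotated unit vector.
#' @export
rotate_about_axis <- function(p, n, alpha) {
  stopifnot(length(p) == 3, length(n) == 3, length(alpha) == 1)
  if (abs(sqrt(sum(p^2)) - 1) > .unit_tol || abs(sqrt(sum(n^2)) - 1) > .unit_tol) {
    stop("`p` and `n` must be unit vectors")
  }
  k <- c(
    n[2] * p[3] - n[3] * p[2],
    n[3] * p[1] - n[1] * p[3],
    n[1] * p[2] - n[2] * p[1]
  )
  cos(alpha) * p + sin(alpha) * k + sum(n * p) * (1 - cos(alpha)) * n
}

#' Sample points uniformly on a sphere
#'
#' Draws `count` points uniformly on the sphere of the given radius
#' (normalised Gaussian triples), using the current R random stream.
#'
#' @param count number of points (>= 1).
#' @param radius sphere radius (> 0).
#' @return a `count` x 3 numeric matrix; every row has norm `radius`.
#' @export
sample_uniform_sphere <- function(count, radius) {
  stopifnot(count >= 1, radius > 0)
  m <- matrix(rnorm(3 * count), ncol = 3)
  nrm <- sqrt(rowSums(m^2))
  while (any(nrm < 1e-12)) {
    bad <- which(nrm < 1e-12)
    m[bad, ] <- matrix(rnorm(3 * length(bad)), ncol = 3)
    nrm <- sqrt(rowSums(m^2))
  }
  radius * m / nrm
}
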
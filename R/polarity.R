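#' Repolarization parameters
#'
#' Parameters of the angular dynamics of the polarity vector: rotational
#' diffusion rate `Dr`, CIL repolarization rate `fcil`, taxis rate `ftax`,
#' and the dimensionless CIL strength `psi = fcil / (2 * Dr)`. Exactly one
#' of `psi` and `fcil` may be supplied; the other is derived. `Dr` defaults
#' to 1, the model's time-scale convention.
#'
#' @param psi dimensionless CIL strength (>= 0).
#' @param fcil CIL repolarization rate (>= 0).
#' @param ftax taxis repolarization rate (>= 0).
#' @param Dr rotational diffusion rate (>= 0; 0 is the deterministic limit).
#' @return a list of class `polarity_params` with consistent `psi`/`fcil`.
#' @export
polarity_params <- function(psi = NULL, fcil = NULL, ftax = 0, Dr = 1) {
  stopifnot(Dr >= 0, ftax >= 0)
  if (is.null(psi) && is.null(fcil)) psi <- 0
  if (is.null(fcil)) {
    fcil <- psi_to_fcil(psi, Dr)
  } else if (is.null(psi)) {
    psi <- fcil / (2 * Dr)
  } else if (abs(fcil - 2 * Dr * psi) > 1e-9 * max(1, fcil)) {
    stop("inconsistent `psi` and `fcil`: must satisfy fcil = 2 * Dr * psi")
  }
  stopifnot(fcil >= 0)
  structure(
    list(psi = psi, fcil = fcil, ftax = ftax, Dr = Dr),
    class = "polarity_params"
  )
}

#' Convert CIL strength to a repolarization rate
#'
#' The CIL dynamics are governed by the single dimensionless parameter
#' `psi = fcil / (2 * Dr)`; this inverts that definition.
#'
#' @param psi dimensionless CIL strength.
#' @param Dr rotational diffusion rate (>= 0; 0 is the deterministic limit).
#' @return repolarization rate `2 * Dr * psi`.
#' @export
psi_to_fcil <- function(psi, Dr = 1) {
  stopifnot(Dr >= 0)
  2 * Dr * psi
}

#' CIL guidance direction for one cell
#'
#' Direction a cell repolarizes toward under contact inhibition of
#' locomotion: the unit tangential component (with respect to the local
#' outward normal) of the vector from the mean position of its contacting
#' neighbors to the cell, i.e. pointing away from the neighbor centroid.
#'
#' @param i cell index (1-based).
#' @param positions `n` x 3 matrix or data frame with columns `x`, `y`, `z`.
#' @param adjacency list of neighbor index vectors, as from
#'   [neighbor_sets()].
#' @return unit length-3 vector, or `NULL` when the cell has no neighbors
#'   or the tangential component vanishes (the CIL term is then skipped).
#' @export
cil_direction <- function(i, positions, adjacency) {
  positions <- as_positions_matrix(positions)
  nb <- adjacency[[i]]
  if (length(nb) == 0) return(NULL)
  xi <- positions[i, ]
  centroid <- colMeans(positions[nb, , drop = FALSE])
  nhat <- xi / sqrt(sum(xi^2))
  v <- tangential_project(xi - centroid, nhat)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(NULL)
  v / nv
}

#' Taxis guidance direction toward the organizing center
#'
#' Unit tangential component of the vector from the cell to the organizing
#' center. The repolarization rate does not depend on the distance to the
#' center; only the direction matters.
#'
#' @param xi cell position (length-3, nonzero).
#' @param xorg organizing-center position on the shell.
#' @return unit length-3 vector, or `NULL` when the cell sits at the
#'   organizer or its antipode (no preferred tangential direction).
#' @export
taxis_direction <- function(xi, xorg) {
  r <- sqrt(sum(xi^2))
  stopifnot(r > 0)
  nhat <- xi / r
  v <- tangential_project(xorg - xi, nhat)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(NULL)
  v / nv
}

#' One Euler-Maruyama update of a single cell's polarity
#'
#' Rotates the polarity `p` about the local normal `n` by
#' `dalpha = -dt * fcil * a_cil - dt * ftax * a_tax + sqrt(2 * Dr * dt) * z`,
#' where `a_cil` (`a_tax`) is the signed tangent-plane angle from the CIL
#' (taxis) target direction to `p`, each term omitted when the target is
#' `NULL`, and `z` is a standard Gaussian draw (so the noise increment has
#' variance `2 * Dr * dt`). The result is re-projected to the tangent plane
#' and normalised.
#'
#' @param p unit polarity vector, tangential to `n`.
#' @param n unit outward normal.
#' @param cil_dir,tax_dir unit target directions or `NULL`.
#' @param params a [polarity_params()] object.
#' @param dt time step (> 0).
#' @return the updated unit tangential polarity vector.
#' @export
polarity_step <- function(p, n, cil_dir = NULL, tax_dir = NULL, params, dt) {
  stopifnot(inherits(params, "polarity_params"))
  if (dt <= 0) stop("dt must be positive")
  dalpha <- sqrt(2 * params$Dr * dt) * rnorm(1)
  if (!is.null(cil_dir) && params$fcil > 0) {
    a <- signed_tangent_angle(cil_dir, p, n)
    if (!is.na(a)) dalpha <- dalpha - dt * params$fcil * a
  }
  if (!is.null(tax_dir) && params$ftax > 0) {
    a <- signed_tangent_angle(tax_dir, p, n)
    if (!is.na(a)) dalpha <- dalpha - dt * params$ftax * a
  }
  p2 <- rotate_about_axis(p, n, dalpha)
  p2 <- tangential_project(p2, n)
  p2 / sqrt(sum(p2^2))
}
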
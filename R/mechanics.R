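#' Force-law parameters
#'
#' Bundles the mechanical parameters of the cell-cell and cell-layer force
#' model: cell radius `R`, cell-substrate adhesion energy `Ws`, cell-cell
#' adhesion energy `Wc`, and shell radius `RE`. The dynamics depend only on
#' the ratio of the adhesion energies, so `Ws` is fixed at 1 by convention
#' and `Wc` is the tuned quantity.
#'
#' @param R cell radius (> 0), model length unit.
#' @param Ws cell-substrate adhesion energy (>= 0).
#' @param Wc cell-cell adhesion energy (>= 0).
#' @param RE shell (embryo) radius (> R).
#' @return a list of class `force_params`.
#' @export
force_params <- function(R = 1, Ws = 1, Wc = 0, RE = 25) {
  stopifnot(R > 0, Ws >= 0, Wc >= 0, RE > R)
  structure(list(R = R, Ws = Ws, Wc = Wc, RE = RE), class = "force_params")
}

#' Pairwise cell-cell force magnitude
#'
#' Linear overlap force between two spherical cells at center separation
#' `d`: `2R * (Ws - ((Ws + Wc)/R) * (d - R))` while in contact (`d < 2R`),
#' zero beyond. Positive values are repulsive along the contact normal,
#' negative values adhesive. The force changes sign at
#' `d* = R (1 + Ws/(Ws + Wc))` and there is no inner cut-off below `R`.
#'
#' @param d numeric vector of separations (> 0).
#' @param params a [force_params()] object.
#' @return numeric vector of signed magnitudes.
#' @examples
#' p <- force_params(Wc = 1)
#' pair_force_magnitude(c(1, 1.5, 1.99, 2.5), p)
#' @export
pair_force_magnitude <- function(d, params) {
  stopifnot(inherits(params, "force_params"))
  if (any(d <= 0)) stop("coincident or interpenetrating centers: d must be > 0")
  ifelse(
    d < 2 * params$R,
    2 * params$R * (params$Ws - ((params$Ws + params$Wc) / params$R) * (d - params$R)),
    0
  )
}

#' Contact normal between two cells
#'
#' Unit vector from cell `j` toward cell `i`, the direction along which the
#' pairwise force acts.
#'
#' @param xi,xj numeric length-3 positions.
#' @return unit length-3 vector `(xi - xj) / ||xi - xj||`.
#' @export
contact_normal <- function(xi, xj) {
  d <- xi - xj
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop("coincident cell centers: contact normal undefined")
  d / nd
}

#' Confinement force from the bounding layers
#'
#' Radial force holding a cell on the shell of radius `RE`: the yolk
#' syncytial layer (inner) pushes outward when `||x|| - RE < R` and the
#' enveloping layer (outer) pushes inward when `RE - ||x|| < R`, each with
#' the same linear overlap law as the pair force evaluated against a
#' virtual cell of radius `RE`. In the overlap band the net force is
#' `4 (Ws + Wc) (RE - ||x||)` along the outward radial direction, i.e.
#' restoring toward `||x|| = RE`.
#'
#' @param xi numeric length-3 position (nonzero).
#' @param params a [force_params()] object.
#' @return numeric length-3 force vector.
#' @export
confinement_force <- function(xi, params) {
  stopifnot(inherits(params, "force_params"))
  r <- sqrt(sum(xi^2))
  if (r < 1e-12) stop("cell at the origin: confinement force undefined")
  R <- params$R; Ws <- params$Ws; Wc <- params$Wc; RE <- params$RE
  f <- 0
  if (r - RE < R) f <- f + 2 * R * (Ws - ((Ws + Wc) / R) * (r - RE - R))
  if (RE - r < R) f <- f - 2 * R * (Ws - ((Ws + Wc) / R) * (RE - r - R))
  (f / r) * xi
}

#' Contact adjacency of a cell configuration
#'
#' Exact neighbor detection: cells `i` and `j` are in contact iff
#' `0 < ||xi - xj|| < 2R` (strict at `2R`). Uses a uniform-grid cell list
#' internally but returns exactly the brute-force contact sets.
#'
#' @param positions an `n` x 3 matrix or a data frame with columns
#'   `x`, `y`, `z`.
#' @param R cell radius.
#' @return a list of length `n`; element `i` is the sorted integer vector
#'   of cells in contact with cell `i`. Symmetric and irreflexive.
#' @export
neighbor_sets <- function(positions, R = 1) {
  cpp_neighbor_sets(as_positions_matrix(positions), R)
}

#' Net passive force on every cell
#'
#' Sum of pairwise adhesion/repulsion forces along contact normals plus the
#' confinement force, for every cell. Excludes the motile force (which acts
#' along polarity and is added by the integrator). Pairwise contributions
#' obey Newton's third law, so their total over all cells is zero.
#'
#' @inheritParams neighbor_sets
#' @param params a [force_params()] object.
#' @return an `n` x 3 matrix of force vectors.
#' @export
net_forces <- function(positions, params) {
  stopifnot(inherits(params, "force_params"))
  cpp_net_forces(
    as_positions_matrix(positions),
    params$R, params$Ws, params$Wc, params$RE
  )
}
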
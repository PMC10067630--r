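#' Implicit Euler position update
#'
#' Advances every position by one time step of the overdamped dynamics,
#' solving the implicit relation
#' `x(t+dt) = x(t) + (dt/gamma_s) * (Fm p + F_pair(x(t+dt)) + F_conf(x(t+dt)))`
#' by damped Picard (fixed-point) iteration started from the explicit Euler
#' predictor. The contact pair set is frozen at time `t`; the `2R` cutoff
#' of the force law is still evaluated at the iterate distances. If the
#' fixed point does not converge within `fp_max_iter` iterations the step
#' falls back to sub-stepped explicit Euler.
#'
#' @param positions `n` x 3 matrix (or data frame with `x`, `y`, `z`).
#' @param polarities `n` x 3 matrix of unit tangential polarity vectors.
#' @param config a [sim_config()] (supplies force, motility and solver
#'   parameters).
#' @return a list with `positions` (updated matrix), `converged` (logical)
#'   and `iterations` used by the inner solver.
#' @export
position_step <- function(positions, polarities, config) {
  stopifnot(inherits(config, "sim_config"))
  cpp_position_step(
    as_positions_matrix(positions),
    as_positions_matrix(polarities),
    par_list(config)
  )
}

#' One full time step of the coupled dynamics
#'
#' Applies, in order: neighbor detection at time `t`, the Euler-Maruyama
#' polarity update for all cells (using time-`t` positions and contacts),
#' the implicit position update, and re-projection of every polarity onto
#' the tangent plane of its new position. Advances time by `dt`. Consumes
#' Gaussian draws from the R random stream (one per cell).
#'
#' @param state a `sim_state` (as from [init_state()] or [get_frame()]).
#' @param config a [sim_config()].
#' @return the updated `sim_state`.
#' @export
full_step <- function(state, config) {
  stopifnot(inherits(state, "sim_state"), inherits(config, "sim_config"))
  res <- cpp_full_step(state$positions, state$polarities, par_list(config))
  structure(
    list(
      time = state$time + config$dt,
      positions = res$positions,
      polarities = res$polarities
    ),
    class = "sim_state"
  )
}
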
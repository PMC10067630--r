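#' Packing density of cells on the shell
#'
#' Fraction of the shell surface covered by `n` cells of radius `R` on a
#' sphere of radius `RE`: `Phi = n R^2 / (4 RE^2)`.
#'
#' @param n number of cells.
#' @param R cell radius.
#' @param RE shell radius (> 0).
#' @return dimensionless fraction.
#' @examples
#' packing_density(500, 1, 25)  # 0.2, the in vivo-like density
#' @export
packing_density <- function(n, R, RE) {
  stopifnot(RE > 0)
  n * R^2 / (4 * RE^2)
}

#' Simulation configuration
#'
#' Collects every model and run parameter. Lengths are in units of the cell
#' radius (default `R = 1`) and time in units set by the rotational
#' diffusion rate (`Dr = 1`) and motile speed (`Fm = gamma_s = 1`).
#'
#' @param n_cells number of cells (>= 1).
#' @param RE shell radius.
#' @param R cell radius.
#' @param Ws cell-substrate adhesion energy (fixed at 1 by convention).
#' @param Wc cell-cell adhesion energy.
#' @param psi dimensionless CIL strength; the CIL rate is `2 * Dr * psi`.
#' @param Dr rotational diffusion rate.
#' @param Fm motile force magnitude.
#' @param gamma_s substrate viscosity.
#' @param ftax taxis repolarization rate; 0 disables taxis.
#' @param x_org organizing-center position (length-3, on the shell). When
#'   `NULL` and `ftax > 0`, defaults to the north pole `(0, 0, RE)`.
#' @param dt integration time step.
#' @param t_end simulation horizon in time units (so `t_end / dt` steps).
#' @param seed integer seed; together with the configuration it determines
#'   the trajectory bit-exactly on one platform.
#' @param stop_on_single_cluster stop early once the largest contact-graph
#'   cluster contains every cell (checked at recording times).
#' @param record_every interval between recorded frames, in time units.
#' @param max_steps optional cap on the number of integration steps.
#' @param fp_tol residual tolerance of the implicit-step fixed-point solver.
#' @param fp_max_iter iteration cap of the fixed-point solver.
#' @param fallback_substeps explicit Euler sub-steps used when the fixed
#'   point fails to converge for one step.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cells, RE, R = 1, Ws = 1, Wc = 0, psi = 0, Dr = 1,
                       Fm = 1, gamma_s = 1, ftax = 0, x_org = NULL,
                       dt = 0.1, t_end = 500, seed = 1,
                       stop_on_single_cluster = FALSE, record_every = 0.5,
                       max_steps = NULL, fp_tol = 1e-5 * R,
                       fp_max_iter = 200L,
                       fallback_substeps = 20L) {
  stopifnot(
    n_cells >= 1, R > 0, RE > R, Ws >= 0, Wc >= 0, psi >= 0, Dr >= 0,
    Fm >= 0, gamma_s > 0, ftax >= 0, dt > 0, t_end >= 0, record_every > 0,
    fp_tol > 0, fp_max_iter >= 1
  )
  if (packing_density(n_cells, R, RE) > 1) {
    stop("packing density n R^2 / (4 RE^2) exceeds 1: cells cannot fit on the shell")
  }
  if (is.null(x_org) && ftax > 0) x_org <- c(0, 0, RE)
  if (!is.null(x_org)) {
    stopifnot(length(x_org) == 3)
    if (abs(sqrt(sum(x_org^2)) - RE) > 1e-6 * RE) {
      stop("`x_org` must lie on the shell: ||x_org|| must equal RE")
    }
  }
  structure(
    list(
      n_cells = as.integer(n_cells), R = R, RE = RE, Ws = Ws, Wc = Wc,
      psi = psi, Dr = Dr, Fm = Fm, gamma_s = gamma_s, ftax = ftax,
      x_org = x_org, dt = dt, t_end = t_end, seed = as.integer(seed),
      stop_on_single_cluster = isTRUE(stop_on_single_cluster),
      record_every = record_every, max_steps = max_steps,
      fp_tol = fp_tol, fp_max_iter = as.integer(fp_max_iter),
      fallback_substeps = as.integer(fallback_substeps)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d cells, R = %g on shell RE = %g (packing density %.3g)\n",
    x$n_cells, x$R, x$RE, packing_density(x$n_cells, x$R, x$RE)
  ))
  cat(sprintf(
    "  Ws = %g, Wc = %g, psi = %g (fcil = %g), Dr = %g, ftax = %g\n",
    x$Ws, x$Wc, x$psi, psi_to_fcil(x$psi, x$Dr), x$Dr, x$ftax
  ))
  if (!is.null(x$x_org)) {
    cat(sprintf(
      "  organizing center at (%g, %g, %g)\n", x$x_org[1], x$x_org[2], x$x_org[3]
    ))
  }
  cat(sprintf(
    "  dt = %g, t_end = %g, record_every = %g, seed = %d%s\n",
    x$dt, x$t_end, x$record_every, x$seed,
    if (x$stop_on_single_cluster) ", stop on single cluster" else ""
  ))
  invisible(x)
}

# parameter list handed to the compiled stepping kernels
par_list <- function(config) {
  n_steps <- as.integer(round(config$t_end / config$dt))
  if (!is.null(config$max_steps)) {
    n_steps <- min(n_steps, as.integer(config$max_steps))
  }
  list(
    R = config$R, Ws = config$Ws, Wc = config$Wc, RE = config$RE,
    Fm = config$Fm, gamma_s = config$gamma_s, dt = config$dt,
    fcil = psi_to_fcil(config$psi, config$Dr), ftax = config$ftax,
    Dr = config$Dr, x_org = config$x_org,
    fp_tol = config$fp_tol, fp_max_iter = config$fp_max_iter,
    fallback_substeps = config$fallback_substeps,
    n_steps = n_steps,
    record_steps = max(1L, as.integer(round(config$record_every / config$dt))),
    stop_on_single_cluster = config$stop_on_single_cluster
  )
}

#' Initial state: random placement and random tangential polarity
#'
#' Places `n_cells` uniformly at random on the shell of radius `RE`,
#' resampling any cell that falls within `0.5 * R` of an already placed one
#' (at most 1e4 attempts per cell), and draws an independent uniform random
#' tangential unit polarity for each. Uses the current R random stream; call
#' `set.seed()` first for reproducibility ([simulate_cells()] does this).
#'
#' @param config a [sim_config()]. Requires packing density <= 0.6 so that
#'   placement terminates.
#' @return a list of class `sim_state` with fields `time` (0), `positions`
#'   (`n` x 3 matrix) and `polarities` (`n` x 3 matrix, unit tangential).
#' @export
init_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  phi <- packing_density(config$n_cells, config$R, config$RE)
  if (phi > 0.6) {
    stop(sprintf(
      "packing density %.3f > 0.6: minimum-separation placement may not terminate",
      phi
    ))
  }
  n <- config$n_cells
  min_sep2 <- (0.5 * config$R)^2
  pos <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(10000L)) {
      cand <- sample_uniform_sphere(1, config$RE)[1, ]
      if (i == 1) {
        placed <- TRUE
      } else {
        prev <- pos[seq_len(i - 1), , drop = FALSE]
        d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
          (prev[, 3] - cand[3])^2
        placed <- all(d2 >= min_sep2)
      }
      if (placed) {
        pos[i, ] <- cand
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "initialization failed at packing density %.3f: could not place cell %d with separation %.2f",
        phi, i, 0.5 * config$R
      ))
    }
  }
  pol <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nhat <- pos[i, ] / config$RE
    repeat {
      v <- tangential_project(sample_uniform_sphere(1, 1)[1, ], nhat)
      nv <- sqrt(sum(v^2))
      if (nv > 1e-6) {
        pol[i, ] <- v / nv
        break
      }
    }
  }
  structure(
    list(time = 0, positions = pos, polarities = pol),
    class = "sim_state"
  )
}

#' Run a single simulation
#'
#' Seeds the random stream from `config$seed`, draws the initial state, and
#' integrates the dynamics from `t = 0` to `t_end` (or until every cell
#' belongs to one cluster, if `stop_on_single_cluster` is set). Frames and
#' contact-graph cluster statistics are recorded every `record_every` time
#' units.
#'
#' @param config a [sim_config()].
#' @return an object of class `killi_trajectory`: a list with the `config`,
#'   the recorded `times`, `positions` and `polarities` arrays
#'   (`n_cells` x 3 x `n_frames`), per-frame `max_size` and `n_clusters`,
#'   the `termination` reason (`"horizon"`, `"single-cluster"` or
#'   `"error"`), `termination_time`, and the count of implicit-solver
#'   fallbacks. Use [tidy()] for a long tibble of frames,
#'   [cluster_timeseries()] for the cluster series.
#' @examples
#' cfg <- sim_config(n_cells = 20, RE = 6, Wc = 1, psi = 0.5, t_end = 5, seed = 1)
#' traj <- simulate_cells(cfg)
#' glance(traj)
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  state <- init_state(config)
  res <- cpp_run(state$positions, state$polarities, par_list(config))
  if (identical(res$termination, "error")) {
    warning(sprintf(
      "simulation (seed %d) stopped with an error after %d steps: %s",
      config$seed, res$n_steps_done, res$error
    ))
  }
  structure(
    list(
      config = config,
      times = res$times,
      positions = res$positions,
      polarities = res$polarities,
      max_size = res$max_size,
      n_clusters = res$n_clusters,
      termination = res$termination,
      termination_time = res$termination_time,
      n_fallback = res$n_fallback,
      replicate = 1L
    ),
    class = "killi_trajectory"
  )
}

#' @export
print.killi_trajectory <- function(x, ...) {
  nf <- length(x$times)
  cat(sprintf(
    "<killi_trajectory> %d cells, %d frames over t = [0, %g], termination: %s\n",
    x$config$n_cells, nf, x$times[nf], x$termination
  ))
  cat(sprintf(
    "  final max cluster size %d in %d clusters\n",
    x$max_size[nf], x$n_clusters[nf]
  ))
  invisible(x)
}

#' Extract one frame of a trajectory as a state
#'
#' @param traj a `killi_trajectory`.
#' @param frame frame index (defaults to the last frame).
#' @return a `sim_state` (time, positions, polarities).
#' @export
get_frame <- function(traj, frame = length(traj$times)) {
  stopifnot(inherits(traj, "killi_trajectory"), frame >= 1,
            frame <= length(traj$times))
  structure(
    list(
      time = traj$times[frame],
      positions = traj$positions[, , frame, drop = TRUE],
      polarities = traj$polarities[, , frame, drop = TRUE]
    ),
    class = "sim_state"
  )
}

# deterministic small-integer seed stream for replicate k of a batch
derive_seed <- function(seed, k) {
  as.integer((abs(as.double(seed)) * 48271 + as.double(k) * 104729) %% 2147483647)
}

#' Run a batch of replicate simulations
#'
#' Runs `replicates` independent simulations whose seeds are derived
#' deterministically from `config$seed` and the replicate index, so the
#' batch is reproducible and order-independent. A failing replicate is
#' recorded (with a warning) and does not abort the batch.
#'
#' @param config a [sim_config()] shared by all replicates.
#' @param replicates number of replicates (>= 1).
#' @param keep_frames keep the full positions/polarities arrays of each
#'   replicate; set `FALSE` to retain only cluster statistics (saves
#'   memory in large scans).
#' @return an object of class `killi_batch`: a list of `killi_trajectory`
#'   objects (failed replicates are `NULL`), with the shared config as an
#'   attribute.
#' @export
run_batch <- function(config, replicates, keep_frames = TRUE) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1)
  out <- vector("list", replicates)
  for (k in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, k)
    tr <- tryCatch(simulate_cells(cfg), error = function(e) {
      warning(sprintf("replicate %d failed: %s", k, conditionMessage(e)))
      NULL
    })
    if (!is.null(tr)) {
      tr$replicate <- k
      if (!keep_frames) {
        tr$positions <- NULL
        tr$polarities <- NULL
      }
    }
    out[[k]] <- tr
  }
  structure(out, class = "killi_batch", config = config)
}

#' @export
print.killi_batch <- function(x, ...) {
  ok <- !vapply(x, is.null, logical(1))
  fin <- vapply(x[ok], function(tr) tr$max_size[length(tr$max_size)], integer(1))
  cat(sprintf(
    "<killi_batch> %d replicates (%d succeeded); final max cluster size %s\n",
    length(x), sum(ok),
    if (length(fin)) sprintf("%.1f +/- %.1f", mean(fin), sd(fin)) else "n/a"
  ))
  invisible(x)
}
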
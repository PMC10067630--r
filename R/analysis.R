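#' Contact-graph clusters of a configuration
#'
#' Labels the connected components of the contact graph: two cells are
#' linked when their center distance is below `2R` (the same contact
#' criterion used for CIL neighbors), and a cluster is a maximal set of
#' cells joined by a path of contacts.
#'
#' @param positions `n` x 3 matrix or data frame with columns `x`, `y`, `z`.
#' @param R cell radius.
#' @return a tibble with columns `cell_id` and `cluster` (integer labels,
#'   contiguous from 1 in order of first appearance).
#' @export
find_clusters <- function(positions, R = 1) {
  m <- as_positions_matrix(positions)
  lab <- cpp_find_clusters(m, R)
  tibble::tibble(cell_id = seq_len(nrow(m)), cluster = lab)
}

#' Maximum cluster size of a configuration
#'
#' @inheritParams find_clusters
#' @return size of the largest connected component (integer).
#' @export
max_cluster_size <- function(positions, R = 1) {
  max(tabulate(cpp_find_clusters(as_positions_matrix(positions), R)))
}

#' Cluster-size time series of a trajectory
#'
#' Applies [find_clusters()] to every recorded frame and summarises each as
#' the size of the largest cluster and the number of clusters.
#'
#' @param traj a `killi_trajectory` (from [simulate_cells()] or
#'   [read_trajectory()]).
#' @return a tibble of class `cluster_series` with columns `time`,
#'   `max_size`, `n_clusters` and (if known) `replicate`.
#' @export
cluster_timeseries <- function(traj) {
  stopifnot(inherits(traj, "killi_trajectory"))
  if (is.null(traj$max_size)) {
    stopifnot(!is.null(traj$positions))
    nf <- length(traj$times)
    stats <- vapply(seq_len(nf), function(k) {
      sizes <- tabulate(cpp_find_clusters(traj$positions[, , k], traj$config$R))
      c(max(sizes), length(sizes))
    }, numeric(2))
    ms <- as.integer(stats[1, ])
    nc <- as.integer(stats[2, ])
  } else {
    ms <- traj$max_size
    nc <- traj$n_clusters
  }
  out <- tibble::tibble(
    time = traj$times,
    max_size = ms,
    n_clusters = nc,
    replicate = if (is.null(traj$replicate)) 1L else traj$replicate
  )
  class(out) <- c("cluster_series", class(out))
  out
}

#' Ensemble mean and standard deviation of cluster series
#'
#' Pointwise mean and sample standard deviation of the maximum cluster size
#' across replicate series recorded on a common time grid.
#'
#' @param series a `killi_batch`, or a list of `cluster_series` tibbles
#'   with identical `time` grids.
#' @return a tibble with columns `time`, `mean_max_size`, `sd_max_size`
#'   (0 for a single series) and `n_series`.
#' @export
ensemble_stats <- function(series) {
  if (inherits(series, "killi_batch")) {
    series <- lapply(Filter(Negate(is.null), unclass(series)), cluster_timeseries)
  }
  stopifnot(length(series) >= 1)
  times <- series[[1]]$time
  for (s in series[-1]) {
    if (length(s$time) != length(times) || any(s$time != times)) {
      stop("cluster series are not aligned: recording time grids differ")
    }
  }
  m <- vapply(series, function(s) as.numeric(s$max_size), numeric(length(times)))
  m <- matrix(m, nrow = length(times))
  tibble::tibble(
    time = times,
    mean_max_size = rowMeans(m),
    sd_max_size = if (ncol(m) > 1) apply(m, 1, sd) else rep(0, length(times)),
    n_series = ncol(m)
  )
}

#' Plateau (tail-mean) of a cluster series
#'
#' Mean of the maximum cluster size over the final fraction of recorded
#' times -- a simple, monotone-robust estimate of the late-time plateau.
#'
#' @param series a `cluster_series` tibble (or a `killi_trajectory`, which
#'   is converted first).
#' @param tail_fraction fraction of the recorded entries to average over,
#'   in (0, 1]. Defaults to the last 20%.
#' @return the tail mean (numeric scalar).
#' @export
plateau_estimate <- function(series, tail_fraction = 0.2) {
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  if (inherits(series, "killi_trajectory")) series <- cluster_timeseries(series)
  n <- nrow(series)
  stopifnot(n >= 1)
  k <- max(1L, as.integer(ceiling(tail_fraction * n)))
  mean(series$max_size[(n - k + 1):n])
}

#' Phase scan over adhesion and CIL strength
#'
#' Runs a replicate batch for every combination of `Wc` and `psi` (and
#' optionally `ftax`) values and records the ensemble mean and standard
#' deviation of the final-frame maximum cluster size. Deterministic given
#' `base$seed`: each grid point gets its own derived seed.
#'
#' @param base a [sim_config()] providing all non-scanned parameters.
#' @param Wc_values,psi_values numeric grids (non-empty).
#' @param replicates replicates per grid point (default 25, the convention
#'   for phase maps; time-dynamics curves conventionally use 50).
#' @param ftax_values optional grid of taxis rates; defaults to the base
#'   config's single value.
#' @return a tibble of class `scan_result` with one row per grid point:
#'   `Wc`, `psi`, `ftax`, `mean_final_max_size`, `sd_final_max_size`,
#'   `replicates`, `failed`.
#' @export
phase_scan <- function(base, Wc_values, psi_values, replicates = 25,
                       ftax_values = NULL) {
  stopifnot(inherits(base, "sim_config"),
            length(Wc_values) >= 1, length(psi_values) >= 1, replicates >= 1)
  if (is.null(ftax_values)) ftax_values <- base$ftax
  grid <- expand.grid(
    Wc = Wc_values, psi = psi_values, ftax = ftax_values,
    KEEP.OUT.ATTRS = FALSE
  )
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- base
    cfg$Wc <- grid$Wc[g]
    cfg$psi <- grid$psi[g]
    cfg$ftax <- grid$ftax[g]
    if (cfg$ftax > 0 && is.null(cfg$x_org)) cfg$x_org <- c(0, 0, cfg$RE)
    cfg$seed <- derive_seed(base$seed, g)
    batch <- run_batch(cfg, replicates, keep_frames = FALSE)
    ok <- Filter(Negate(is.null), unclass(batch))
    fin <- vapply(ok, function(tr) tr$max_size[length(tr$max_size)], integer(1))
    rows[[g]] <- tibble::tibble(
      Wc = cfg$Wc, psi = cfg$psi, ftax = cfg$ftax,
      mean_final_max_size = if (length(fin)) mean(fin) else NA_real_,
      sd_final_max_size = if (length(fin) > 1) sd(fin) else 0,
      replicates = length(fin),
      failed = replicates - length(fin)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scan_result", class(out))
  attr(out, "base_seed") <- base$seed
  out
}
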
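#' Write a trajectory to a CSV file (with a JSON manifest)
#'
#' Writes the recorded frames as a tidy table with columns `time`,
#' `replicate`, `cell_id`, `x`, `y`, `z`, `px`, `py`, `pz` (numeric values
#' at 15 significant digits), and a manifest
#' (`<path without extension>_manifest.json`) echoing the full
#' configuration, seed, package version and termination reason -- enough to
#' reproduce the run bit-exactly on one platform.
#'
#' @param traj a `killi_trajectory` with frames.
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "killi_trajectory"), !is.null(traj$positions))
  df <- tidy(traj)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "killisim",
    version = as.character(packageVersion("killisim")),
    config = config_to_list(traj$config),
    seed = traj$config$seed,
    replicate = traj$replicate,
    termination = traj$termination,
    termination_time = traj$termination_time,
    n_fallback = traj$n_fallback,
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, manifest_path(path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

manifest_path <- function(path) {
  paste0(sub("\\.[^./]*$", "", path), "_manifest.json")
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$x_org <- if (is.null(out$x_org)) NULL else as.numeric(out$x_org)
  out$max_steps <- out$max_steps
  out
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Validates the table structure (a malformed or truncated file raises a
#' parse error naming the first bad line), rebuilds the frame arrays, and
#' restores the configuration from the manifest. Cluster statistics are
#' recomputed lazily by [cluster_timeseries()]. A manifest written by a
#' different package version triggers a warning, not an error.
#'
#' @param path CSV file path.
#' @return a `killi_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such trajectory file: ", path)
  nfields <- count.fields(path, sep = ",")
  bad <- which(nfields != 9)
  if (length(bad) > 0) {
    stop(sprintf("parse error in %s at line %d: expected 9 fields, found %d",
                 path, bad[1], nfields[bad[1]]))
  }
  df <- utils::read.csv(path)
  expected <- c("time", "replicate", "cell_id", "x", "y", "z", "px", "py", "pz")
  if (!identical(names(df), expected)) {
    stop("parse error in ", path, ": header must be ",
         paste(expected, collapse = ","))
  }
  mpath <- manifest_path(path)
  if (!file.exists(mpath)) {
    stop("manifest not found alongside trajectory: ", mpath)
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(manifest$version, as.character(packageVersion("killisim")))) {
    warning(sprintf(
      "trajectory written by killisim %s, reading with %s",
      manifest$version, packageVersion("killisim")
    ))
  }
  cfg_list <- manifest$config
  cfg <- sim_config(
    n_cells = cfg_list$n_cells, RE = cfg_list$RE, R = cfg_list$R,
    Ws = cfg_list$Ws, Wc = cfg_list$Wc, psi = cfg_list$psi, Dr = cfg_list$Dr,
    Fm = cfg_list$Fm, gamma_s = cfg_list$gamma_s, ftax = cfg_list$ftax,
    x_org = if (is.null(cfg_list$x_org)) NULL else as.numeric(cfg_list$x_org),
    dt = cfg_list$dt, t_end = cfg_list$t_end, seed = cfg_list$seed,
    stop_on_single_cluster = cfg_list$stop_on_single_cluster,
    record_every = cfg_list$record_every
  )
  times <- sort(unique(df$time))
  n <- cfg$n_cells
  if (nrow(df) != n * length(times)) {
    stop("parse error in ", path, ": incomplete frames (",
         nrow(df), " rows for ", n, " cells x ", length(times), " times)")
  }
  df <- df[order(df$time, df$cell_id), ]
  nf <- length(times)
  pos <- array(0, c(n, 3, nf))
  pol <- array(0, c(n, 3, nf))
  for (k in seq_len(nf)) {
    rows <- ((k - 1) * n + 1):(k * n)
    pos[, , k] <- as.matrix(df[rows, c("x", "y", "z")])
    pol[, , k] <- as.matrix(df[rows, c("px", "py", "pz")])
  }
  structure(
    list(
      config = cfg, times = times, positions = pos, polarities = pol,
      max_size = NULL, n_clusters = NULL,
      termination = manifest$termination,
      termination_time = manifest$termination_time,
      n_fallback = manifest$n_fallback,
      replicate = if (is.null(manifest$replicate)) 1L else manifest$replicate
    ),
    class = "killi_trajectory"
  )
}

#' Write / read a cluster series as CSV
#'
#' @param series a `cluster_series` tibble (see [cluster_timeseries()]).
#' @param path CSV file path.
#' @return `path` (write) or the tibble (read), invisibly for write.
#' @export
write_cluster_series <- function(series, path) {
  write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cluster_series
#' @export
read_cluster_series <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  class(df) <- c("cluster_series", class(df))
  df
}

#' Write / read a phase-scan result as CSV
#'
#' @param scan a `scan_result` tibble (see [phase_scan()]).
#' @param path CSV file path.
#' @return `path` (write) or the tibble (read), invisibly for write.
#' @export
write_scan <- function(scan, path) {
  write.csv(scan, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  class(df) <- c("scan_result", class(df))
  df
}

#' Write / read a simulation configuration as YAML
#'
#' Every [sim_config()] field is a flat key; `x_org` is a 3-element list.
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @param overrides named list of values taking precedence over the file
#'   (used by the command-line interface for flag overrides).
#' @return `path` (write) or a `sim_config` (read).
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals <- modifyList(vals, overrides)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$x_org)) vals$x_org <- as.numeric(unlist(vals$x_org))
  do.call(sim_config, vals)
}
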
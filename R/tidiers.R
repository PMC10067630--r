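#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into a long frame table
#'
#' One row per (time, cell): columns `time`, `replicate`, `cell_id`,
#' position `x`, `y`, `z` and polarity `px`, `py`, `pz`. This is the
#' canonical tabular form used by [write_trajectory()].
#'
#' @param x a `killi_trajectory`.
#' @param ... unused.
#' @return a tibble with `n_frames * n_cells` rows.
#' @export
tidy.killi_trajectory <- function(x, ...) {
  stopifnot(!is.null(x$positions))
  n <- x$config$n_cells
  nf <- length(x$times)
  pos <- x$positions
  pol <- x$polarities
  tibble::tibble(
    time = rep(x$times, each = n),
    replicate = if (is.null(x$replicate)) 1L else x$replicate,
    cell_id = rep(seq_len(n), nf),
    x = as.vector(pos[, 1, ]),
    y = as.vector(pos[, 2, ]),
    z = as.vector(pos[, 3, ]),
    px = as.vector(pol[, 1, ]),
    py = as.vector(pol[, 2, ]),
    pz = as.vector(pol[, 3, ])
  )
}

#' One-row summary of a trajectory
#'
#' @param x a `killi_trajectory`.
#' @param ... unused.
#' @return a one-row tibble: cell count, packing density, number of frames,
#'   final time, termination reason and time, final maximum cluster size
#'   and cluster count, implicit-solver fallback count.
#' @export
glance.killi_trajectory <- function(x, ...) {
  cs <- cluster_timeseries(x)
  nf <- nrow(cs)
  tibble::tibble(
    n_cells = x$config$n_cells,
    packing_density = packing_density(x$config$n_cells, x$config$R, x$config$RE),
    n_frames = nf,
    t_final = cs$time[nf],
    termination = x$termination,
    termination_time = x$termination_time,
    final_max_size = cs$max_size[nf],
    final_n_clusters = cs$n_clusters[nf],
    n_fallback = x$n_fallback
  )
}

#' Per-replicate summaries of a batch
#'
#' @param x a `killi_batch`.
#' @param ... unused.
#' @return a tibble with one [glance.killi_trajectory()] row per successful
#'   replicate, plus a `replicate` column.
#' @export
tidy.killi_batch <- function(x, ...) {
  ok <- Filter(Negate(is.null), unclass(x))
  dplyr::bind_rows(lapply(ok, function(tr) {
    dplyr::bind_cols(tibble::tibble(replicate = tr$replicate), glance(tr))
  }))
}

#' One-row summary of a batch
#'
#' @param x a `killi_batch`.
#' @param ... unused.
#' @return a one-row tibble: replicate counts, mean and standard deviation
#'   of the final maximum cluster size, number of replicates that reached a
#'   single cluster, and the median termination time among those.
#' @export
glance.killi_batch <- function(x, ...) {
  per <- tidy(x)
  single <- per$termination == "single-cluster"
  tibble::tibble(
    replicates = length(x),
    succeeded = nrow(per),
    mean_final_max_size = mean(per$final_max_size),
    sd_final_max_size = if (nrow(per) > 1) sd(per$final_max_size) else 0,
    n_single_cluster = sum(single),
    median_termination_time = if (any(single)) {
      median(per$termination_time[single])
    } else {
      NA_real_
    }
  )
}
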
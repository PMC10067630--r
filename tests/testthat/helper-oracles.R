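# Independent oracles and small generators used across the test files.

# brute-force O(n^2) contact sets: j in nb[[i]] <=> 0 < d_ij < 2R
brute_neighbor_sets <- function(positions, R) {
  n <- nrow(positions)
  d <- as.matrix(dist(positions))
  lapply(seq_len(n), function(i) {
    js <- unname(which(d[i, ] < 2 * R & d[i, ] > 0))
    as.integer(sort(js[js != i]))
  })
}

# cluster labels via igraph connected components on the contact graph
igraph_clusters <- function(positions, R) {
  n <- nrow(positions)
  d <- as.matrix(dist(positions))
  edges <- which(d < 2 * R & upper.tri(d), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$membership
}

# signed tangent-plane angle from an explicit orthonormal basis
basis_signed_angle <- function(a, b, n) {
  at <- a - sum(a * n) * n
  e1 <- at / sqrt(sum(at^2))
  e2 <- c(
    n[2] * e1[3] - n[3] * e1[2],
    n[3] * e1[1] - n[1] * e1[3],
    n[1] * e1[2] - n[2] * e1[1]
  )
  bt <- b - sum(b * n) * n
  atan2(sum(bt * e2), sum(bt * e1))
}

# random unit vector, optionally tangential to n
runit <- function(n_normal = NULL) {
  v <- rnorm(3)
  if (!is.null(n_normal)) v <- v - sum(v * n_normal) * n_normal
  v / sqrt(sum(v^2))
}

# scattered configuration on a shell with no pair closer than min_sep
scatter_on_shell <- function(n, RE, min_sep = 1) {
  pos <- matrix(0, n, 3)
  k <- 0
  while (k < n) {
    cand <- RE * runit()
    if (k == 0 ||
        all(sqrt(colSums((t(pos[seq_len(k), , drop = FALSE]) - cand)^2)) >= min_sep)) {
      k <- k + 1
      pos[k, ] <- cand
    }
  }
  pos
}

# explicit Euler reference integration of the position dynamics (live
# contact sets and force cutoff re-evaluated every sub-step); used as the
# fine-step oracle for the implicit integrator
explicit_reference <- function(positions, polarities, config, t_total, dt_sub) {
  p <- force_params(R = config$R, Ws = config$Ws, Wc = config$Wc, RE = config$RE)
  x <- positions
  steps <- round(t_total / dt_sub)
  for (s in seq_len(steps)) {
    f <- net_forces(x, p) + config$Fm * polarities
    x <- x + (dt_sub / config$gamma_s) * f
  }
  x
}
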
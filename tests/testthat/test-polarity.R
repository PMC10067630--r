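test_that("CIL strength and repolarization rate convert consistently", {
  expect_equal(psi_to_fcil(0), 0)
  expect_equal(psi_to_fcil(0.5, 1), 1)
  expect_equal(psi_to_fcil(2, 1), 4)
  expect_equal(psi_to_fcil(2, 0.5), 2)

  p <- polarity_params(psi = 0.5, Dr = 2)
  expect_equal(p$fcil, 2)
  p <- polarity_params(fcil = 4, Dr = 1)
  expect_equal(p$psi, 2)
  expect_error(polarity_params(psi = 1, fcil = 1, Dr = 1), "inconsistent")
})

test_that("CIL direction points away from the neighbor centroid", {
  RE <- 10
  # cell at the north pole, single neighbor to its "east"
  pos <- rbind(c(0, 0, RE), c(1.5, 0, RE - 0.2))
  adj <- neighbor_sets(pos, 1)
  d <- cil_direction(1, pos, adj)
  expect_equal(d, c(-1, 0, 0), tolerance = 1e-6)
  # no neighbors: term absent
  expect_null(cil_direction(1, rbind(c(0, 0, RE), c(5, 0, RE)),
                            list(integer(0), integer(0))))

  # symmetric pair of neighbors: direction along the bisector, matching a
  # brute-force mean-and-project computation
  set.seed(301)
  for (k in 1:10) {
    xi <- RE * runit()
    nhat <- xi / RE
    e1 <- runit(n_normal = nhat)
    e2 <- c(nhat[2] * e1[3] - nhat[3] * e1[2],
            nhat[3] * e1[1] - nhat[1] * e1[3],
            nhat[1] * e1[2] - nhat[2] * e1[1])
    nb1 <- xi + 1.2 * (0.8 * e1 + 0.5 * e2)
    nb2 <- xi + 1.2 * (0.8 * e1 - 0.5 * e2)
    pos <- rbind(xi, nb1, nb2)
    d <- cil_direction(1, pos, neighbor_sets(pos, 1))
    oracle <- xi - colMeans(rbind(nb1, nb2))
    oracle <- oracle - sum(oracle * nhat) * nhat
    oracle <- oracle / sqrt(sum(oracle^2))
    expect_equal(d, oracle, tolerance = 1e-10)
  }
})

test_that("taxis direction is the tangential great-circle heading", {
  RE <- 25
  xorg <- c(0, 0, RE)
  expect_equal(taxis_direction(c(RE, 0, 0), xorg), c(0, 0, 1), tolerance = 1e-12)
  # at the organizer and at its antipode there is no preferred direction
  expect_null(taxis_direction(xorg, xorg))
  expect_null(taxis_direction(c(0, 0, -RE), xorg))
})

test_that("guidance terms are equivariant under rigid rotations", {
  set.seed(302)
  for (k in 1:5) {
    # random rotation matrix via QR of a Gaussian matrix
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    pos <- scatter_on_shell(20, 5, min_sep = 0.8)
    adj <- neighbor_sets(pos, 1)
    i <- which(lengths(adj) > 0)[1]
    skip_if(is.na(i))
    d <- cil_direction(i, pos, adj)
    d_rot <- cil_direction(i, pos %*% t(Q), neighbor_sets(pos %*% t(Q), 1))
    expect_equal(d_rot, as.numeric(Q %*% d), tolerance = 1e-9)

    xorg <- 5 * runit()
    xi <- pos[1, ]
    td <- taxis_direction(xi, xorg)
    if (!is.null(td)) {
      expect_equal(taxis_direction(as.numeric(Q %*% xi), as.numeric(Q %*% xorg)),
                   as.numeric(Q %*% td), tolerance = 1e-9)
    }
  }
})

test_that("deterministic repolarization contracts the angle to the target", {
  n <- c(0, 0, 1)
  pp <- polarity_params(fcil = 1, Dr = 0)
  # aligned with the target: fixed point
  p <- c(1, 0, 0)
  expect_equal(polarity_step(p, n, cil_dir = p, params = pp, dt = 0.1), p,
               tolerance = 1e-12)
  # small-step linear contraction: angle shrinks by (1 - fcil dt)
  set.seed(303)
  for (a0 in c(-2.5, -0.8, 0.4, 1.9)) {
    target <- c(1, 0, 0)
    p <- rotate_about_axis(target, n, a0)
    dt <- 0.01
    p1 <- polarity_step(p, n, cil_dir = target, params = pp, dt = dt)
    a1 <- signed_tangent_angle(target, p1, n)
    expect_equal(a1, a0 * (1 - pp$fcil * dt), tolerance = 1e-3)
    # monotone decay over repeated steps
    ang <- abs(a0)
    q <- p
    for (s in 1:20) {
      q <- polarity_step(q, n, cil_dir = target, params = pp, dt = 0.1)
      a <- abs(signed_tangent_angle(target, q, n))
      expect_lt(a, ang + 1e-12)
      ang <- a
    }
  }
  # polarity stays unit and tangential
  q <- polarity_step(runit(n_normal = n), n, cil_dir = runit(n_normal = n),
                     params = pp, dt = 0.1)
  expect_equal(sqrt(sum(q^2)), 1, tolerance = 1e-10)
  expect_lt(abs(sum(q * n)), 1e-8)
})

test_that("free polarity diffuses with angular variance 2 Dr t", {
  set.seed(304)
  pp <- polarity_params(psi = 0, Dr = 1)
  n <- c(0, 0, 1)
  dt <- 0.1
  nrep <- 2000
  nstep <- 10  # total time 1, expected variance 2
  total <- numeric(nrep)
  for (r in seq_len(nrep)) {
    p <- c(1, 0, 0)
    acc <- 0
    for (s in seq_len(nstep)) {
      q <- polarity_step(p, n, params = pp, dt = dt)
      acc <- acc + signed_tangent_angle(p, q, n)
      p <- q
    }
    total[r] <- acc
  }
  expect_equal(mean(total), 0, tolerance = 0.1)
  v <- var(total)
  # chi-square bounds on the sample variance at alpha = 0.01
  lo <- 2 * qchisq(0.005, nrep - 1) / (nrep - 1)
  hi <- 2 * qchisq(0.995, nrep - 1) / (nrep - 1)
  expect_gt(v, lo)
  expect_lt(v, hi)
})

test_that("pure taxis steers a single cell to the organizing center", {
  cfg <- sim_config(
    n_cells = 1, RE = 25, Wc = 0, psi = 0, Dr = 0, ftax = 1,
    t_end = 80, seed = 5, record_every = 5
  )
  traj <- simulate_cells(cfg)
  final <- traj$positions[, , length(traj$times)]
  expect_lt(sqrt(sum((final - c(0, 0, 25))^2)), 2)
})
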
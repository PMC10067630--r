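test_that("an isolated resting cell on the shell is a fixed point", {
  cfg <- sim_config(n_cells = 1, RE = 25, Wc = 1, Fm = 0, psi = 0, Dr = 1,
                    t_end = 1, seed = 1)
  pos <- matrix(c(25, 0, 0), 1)
  pol <- matrix(c(0, 1, 0), 1)
  ps <- position_step(pos, pol, cfg)
  expect_true(ps$converged)
  expect_equal(ps$positions, pos, tolerance = 1e-9)
})

test_that("a motile isolated cell advances by Fm dt / gamma_s along polarity", {
  cfg <- sim_config(n_cells = 1, RE = 25, Wc = 1, Fm = 1, t_end = 1, seed = 1)
  pos <- matrix(c(25, 0, 0), 1)
  pol <- matrix(c(0, 1, 0), 1)
  ps <- position_step(pos, pol, cfg)
  disp <- ps$positions - pos
  # 0.1 * p plus a confinement correction of second order in dt
  expect_equal(as.numeric(disp), 0.1 * c(0, 1, 0), tolerance = 5e-3)
  expect_lt(abs(disp[2] - 0.1), 1e-3)
})

test_that("the implicit step agrees with a fine explicit reference to O(dt^2)", {
  # three interacting cells on the shell, contacts stable within the step
  RE <- 25
  base <- c(25, 0, 0)
  e2 <- c(0, 1, 0)
  e3 <- c(0, 0, 1)
  pos <- rbind(base, base + 1.3 * e2, base + 1.4 * e3)
  pos <- RE * pos / sqrt(rowSums(pos^2))
  pol <- rbind(e2, e3, -e2)
  cfg <- sim_config(n_cells = 3, RE = RE, Wc = 1, Fm = 1, t_end = 1, seed = 1)
  imp <- position_step(pos, pol, cfg)$positions
  ref <- explicit_reference(pos, pol, cfg, t_total = 0.1, dt_sub = 1e-4)
  expect_lt(max(abs(imp - ref)), 5 * 0.1^2)
})

test_that("global error against the explicit reference scales as O(dt)", {
  RE <- 25
  base <- c(25, 0, 0)
  e2 <- c(0, 1, 0)
  e3 <- c(0, 0, 1)
  pos0 <- rbind(base, base + 1.3 * e2, base + 1.4 * e3)
  pos0 <- RE * pos0 / sqrt(rowSums(pos0^2))
  pol <- rbind(e2, e3, -e2)
  Ttot <- 1
  ref <- explicit_reference(pos0, pol, sim_config(3, RE, Wc = 1), Ttot, 1e-4)
  err <- sapply(c(0.2, 0.1, 0.05), function(dt) {
    cfg <- sim_config(n_cells = 3, RE = RE, Wc = 1, dt = dt, t_end = Ttot, seed = 1)
    x <- pos0
    for (s in seq_len(round(Ttot / dt))) x <- position_step(x, pol, cfg)$positions
    max(abs(x - ref))
  })
  slopes <- diff(log(err)) / diff(log(c(0.2, 0.1, 0.05)))
  expect_gt(mean(slopes), 0.8)
  expect_lt(mean(slopes), 1.2)
})

test_that("with all dynamics off the full step leaves the state invariant", {
  cfg <- sim_config(n_cells = 4, RE = 10, Wc = 0, psi = 0, Dr = 0, Fm = 0,
                    ftax = 0, t_end = 1, seed = 2)
  set.seed(2)
  st <- init_state(cfg)
  st2 <- full_step(st, cfg)
  expect_equal(st2$positions, st$positions, tolerance = 1e-9)
  expect_equal(st2$polarities, st$polarities, tolerance = 1e-9)
  expect_equal(st2$time, st$time + cfg$dt)
})

test_that("a noiseless single cell travels a great circle at speed Fm/gamma_s", {
  cfg <- sim_config(n_cells = 1, RE = 25, Dr = 0, psi = 0, ftax = 0, Fm = 1,
                    t_end = 10, seed = 3, record_every = 0.5)
  traj <- simulate_cells(cfg)
  nf <- length(traj$times)
  x0 <- traj$positions[, , 1]
  p0 <- traj$polarities[, , 1]
  axis <- c(x0[2] * p0[3] - x0[3] * p0[2],
            x0[3] * p0[1] - x0[1] * p0[3],
            x0[1] * p0[2] - x0[2] * p0[1])
  axis <- axis / sqrt(sum(axis^2))
  # stays on the great circle orthogonal to the initial angular momentum
  for (k in seq_len(nf)) {
    expect_lt(abs(sum(traj$positions[, , k] * axis)), 0.05)
  }
  # arc length traveled over t = 10 is 10 within 1%
  arc <- 0
  for (k in 2:nf) {
    a <- traj$positions[, , k - 1]
    b <- traj$positions[, , k]
    cosang <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
    arc <- arc + 25 * acos(min(1, cosang))
  }
  expect_equal(arc, 10, tolerance = 0.01)
})

test_that("two adhering cells relax monotonically toward the force balance", {
  # d* = R (1 + Ws/(Ws+Wc)) = 1.5 for Ws = Wc = 1
  RE <- 25
  a <- acos(1 - 1.9^2 / (2 * RE^2))
  pos <- rbind(c(RE, 0, 0), RE * c(cos(a), sin(a), 0))
  pol <- matrix(0, 2, 3)
  pol[1, ] <- c(0, 0, 1)
  pol[2, ] <- c(0, 0, 1)
  cfg <- sim_config(n_cells = 2, RE = RE, Wc = 1, Fm = 0, Dr = 0, t_end = 1, seed = 1)
  d_prev <- 1.9
  x <- pos
  for (s in 1:100) {
    x <- position_step(x, pol, cfg)$positions
    d <- sqrt(sum((x[1, ] - x[2, ])^2))
    expect_lte(d, d_prev + 1e-12)
    d_prev <- d
  }
  expect_equal(d_prev, 1.5, tolerance = 1e-3)
})

test_that("cells stay within one radius of the shell after burn-in", {
  cfg <- sim_config(n_cells = 60, RE = 8.7, Wc = 1, psi = 0.5, t_end = 5,
                    seed = 4, record_every = 0.5)
  traj <- simulate_cells(cfg)
  after <- which(traj$times >= 1)
  for (k in after) {
    r <- sqrt(colSums(apply(traj$positions[, , k], 1, function(v) v)^2))
    r <- sqrt(rowSums(traj$positions[, , k]^2))
    expect_true(all(abs(r - cfg$RE) < cfg$R))
  }
})

test_that("identical configuration and seed give bit-identical trajectories", {
  cfg <- sim_config(n_cells = 40, RE = 8, Wc = 1, psi = 1, ftax = 0.5,
                    t_end = 3, seed = 42)
  t1 <- simulate_cells(cfg)
  t2 <- simulate_cells(cfg)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$polarities, t2$polarities)
  expect_identical(t1$max_size, t2$max_size)
})
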
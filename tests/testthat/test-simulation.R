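test_that("packing density follows n R^2 / (4 RE^2)", {
  expect_equal(packing_density(500, 1, 25), 0.2)
  expect_equal(round(packing_density(500, 1, 15), 2), 0.56)
  expect_equal(packing_density(0, 1, 10), 0)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_cells = 3000, RE = 25), "packing")
  expect_error(sim_config(n_cells = 10, RE = 25, ftax = 1, x_org = c(1, 0, 0)),
               "x_org")
  expect_error(sim_config(n_cells = 10, RE = 0.5), "RE")
  # organizer defaults to the north pole when taxis is on
  cfg <- sim_config(n_cells = 10, RE = 25, ftax = 1)
  expect_equal(cfg$x_org, c(0, 0, 25))
  expect_null(sim_config(n_cells = 10, RE = 25)$x_org)
})

test_that("initialization respects the shell and the minimum separation", {
  cfg <- sim_config(n_cells = 1, RE = 25, seed = 1)
  set.seed(1)
  st <- init_state(cfg)
  expect_equal(sqrt(sum(st$positions^2)), 25, tolerance = 1e-9)
  expect_lt(abs(sum(st$positions * st$polarities) / 25), 1e-8)

  cfg <- sim_config(n_cells = 500, RE = 25, seed = 7)
  set.seed(7)
  st <- init_state(cfg)
  expect_equal(sqrt(rowSums(st$positions^2)), rep(25, 500), tolerance = 1e-9)
  expect_gte(min(dist(st$positions)), 0.5)
  pol_norm <- sqrt(rowSums(st$polarities^2))
  expect_equal(pol_norm, rep(1, 500), tolerance = 1e-9)
  expect_lt(max(abs(rowSums(st$positions * st$polarities) / 25)), 1e-8)

  # determinism of the draw
  set.seed(7)
  st2 <- init_state(cfg)
  expect_identical(st$positions, st2$positions)

  # too dense for the placement contract
  dense <- sim_config(n_cells = 500, RE = 13.4)
  expect_error(init_state(dense), "0.6")
})

test_that("a zero-horizon run returns only the initial frame", {
  cfg <- sim_config(n_cells = 10, RE = 8, t_end = 0, seed = 3)
  traj <- simulate_cells(cfg)
  expect_equal(length(traj$times), 1)
  expect_equal(traj$times, 0)
  expect_equal(traj$termination, "horizon")
  expect_equal(dim(traj$positions), c(10, 3, 1))
})

test_that("without adhesion a sparse system stays dispersed", {
  # packing 0.2 with 100 cells; no Wc, moderate CIL
  cfg <- sim_config(n_cells = 100, RE = sqrt(100 / 0.8), Wc = 0, psi = 0.5,
                    t_end = 10, seed = 21)
  traj <- simulate_cells(cfg)
  cs <- cluster_timeseries(traj)
  expect_lt(cs$max_size[nrow(cs)], 10)
})

test_that("taxis with adhesion and no CIL reaches a single cluster early", {
  cfg <- sim_config(n_cells = 12, RE = 4, Wc = 1, psi = 0, ftax = 1,
                    t_end = 200, seed = 9, stop_on_single_cluster = TRUE)
  traj <- simulate_cells(cfg)
  expect_equal(traj$termination, "single-cluster")
  expect_lt(traj$termination_time, 200)
  expect_equal(traj$max_size[length(traj$max_size)], 12)
  expect_equal(traj$n_clusters[length(traj$n_clusters)], 1)
})

test_that("cell count and state invariants hold on every recorded frame", {
  cfg <- sim_config(n_cells = 30, RE = 7, Wc = 1, psi = 1, t_end = 5, seed = 13)
  traj <- simulate_cells(cfg)
  nf <- length(traj$times)
  expect_true(all(diff(traj$times) > 0))
  expect_equal(traj$times[1], 0)
  for (k in seq_len(nf)) {
    expect_equal(dim(traj$positions[, , k, drop = FALSE])[1], 30)
    pn <- sqrt(rowSums(traj$polarities[, , k]^2))
    expect_equal(pn, rep(1, 30), tolerance = 1e-8)
    tangency <- rowSums(traj$polarities[, , k] * traj$positions[, , k]) /
      sqrt(rowSums(traj$positions[, , k]^2))
    expect_lt(max(abs(tangency)), 1e-8)
  }
  lab <- find_clusters(traj$positions[, , nf], cfg$R)
  expect_equal(sum(table(lab$cluster)), 30)
})

test_that("replicate batches are deterministic and seed-distinct", {
  cfg <- sim_config(n_cells = 20, RE = 6, Wc = 1, psi = 0.5, t_end = 2, seed = 31)
  b1 <- run_batch(cfg, 2)
  b2 <- run_batch(cfg, 2)
  expect_identical(b1[[1]]$positions, b2[[1]]$positions)
  expect_identical(b1[[2]]$positions, b2[[2]]$positions)
  # distinct derived seeds give distinct trajectories
  expect_false(identical(b1[[1]]$positions, b1[[2]]$positions))
  # one replicate equals a single run at the derived seed
  cfg1 <- cfg
  cfg1$seed <- killisim:::derive_seed(cfg$seed, 1)
  solo <- simulate_cells(cfg1)
  expect_identical(b1[[1]]$positions, solo$positions)
  # summaries
  g <- glance(b1)
  expect_equal(g$replicates, 2)
  expect_equal(g$succeeded, 2)
})
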
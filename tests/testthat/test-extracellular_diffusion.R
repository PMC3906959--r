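# lattice random-walk diffusion and the operator-splitting driver

test_that("diffusion sweeps conserve molecules exactly and stay local", {
  cfg <- tiny_config()
  f <- empty_field(cfg)
  expect_identical(sum(diffusion_sweep(f, 0.5, seed = 1)), 0L)

  set.seed(2)
  f[] <- rpois(length(f), 30)
  for (i in 1:10) {
    f2 <- diffusion_sweep(f, 0.5)
    expect_identical(sum(f2), sum(f))
    expect_true(all(f2 >= 0))
    f <- f2
  }

  # one sweep moves mass only to the 4 neighbors of a seeded box
  g <- matrix(0L, 5, 5)
  g[3, 3] <- 10000L
  g1 <- diffusion_sweep(g, 0.5, seed = 3)
  touched <- which(g1 > 0, arr.ind = TRUE)
  expect_true(all(abs(touched[, 1] - 3) + abs(touched[, 2] - 3) <= 1))
  expect_identical(sum(g1), 10000L)

  # reflecting wall: a 1x1 lattice keeps everything
  h <- matrix(1000L, 1, 1)
  expect_identical(diffusion_sweep(h, 1.0, seed = 4)[1, 1], 1000L)

  expect_error(diffusion_sweep(matrix(-1L, 2, 2), 0.5), "non-negative")
})

test_that("mean-squared displacement follows the 2D diffusion law", {
  # MSD after k sweeps is k * hop_prob in box units, i.e. 4 D t in physical
  # units with t = k * diffusion_time_step
  n <- 101L
  f <- matrix(0L, n, n)
  c0 <- 51L
  f[c0, c0] <- 20000L
  k <- 40L
  set.seed(9)
  for (i in seq_len(k)) f <- diffusion_sweep(f, 0.5)
  ix <- which(f > 0, arr.ind = TRUE)
  d2 <- (ix[, 1] - c0)^2 + (ix[, 2] - c0)^2
  msd <- sum(f[ix] * d2) / sum(f)
  expect_equal(msd, k * 0.5, tolerance = 0.05)
})

test_that("a uniform field stays statistically uniform", {
  f <- matrix(200L, 20, 20)
  set.seed(13)
  for (i in 1:20) f <- diffusion_sweep(f, 0.5)
  expect_identical(sum(f), 200L * 400L)
  chi <- chisq.test(as.vector(f))
  expect_gt(chi$p.value, 1e-4)
})

test_that("pretreatment increments the field as configured", {
  cfg <- sim_config()
  f <- empty_field(cfg)
  expect_identical(apply_pretreatment(f, 0), f)
  f2 <- apply_pretreatment(f, 1200)
  expect_equal(sum(as.numeric(f2)), 1200 * 1600)
  g <- build_grid(cfg)
  f3 <- apply_pretreatment(f, 1200, occupied_only = TRUE, grid = g)
  expect_equal(sum(as.numeric(f3)), 1200 * 210)
  expect_error(apply_pretreatment(f, 10, occupied_only = TRUE), "grid")
})

test_that("the global cytokine ledger balances exactly at every sample", {
  cfg <- sim_config(grid_nx = 12L, grid_ny = 12L, n_cells = 40L, moi = 1,
                    total_hours = 1.5, sample_interval = 300, seed = 6,
                    pretreat_amount = 50, pretreat_time_h = 0.5,
                    rates = rate_table(k_f1 = 0.02, k_act = 0.05,
                                       v_ifnb_low = 0.5, k_sec = 0.05,
                                       k_on_r = 1e-4, k_off_r = 5e-3))
  sim <- run_simulation(cfg)
  free_tot <- rowSums(sim$field)
  bound_tot <- rowSums(sim$bound_ifnar)
  expect_gt(sim$cum_secreted[length(sim$times)], 0)
  expect_equal(free_tot + bound_tot + sim$cum_degraded,
               sim$cum_secreted + sim$cum_pretreat)

  # with extracellular degradation switched on the ledger still balances
  cfg2 <- modify_config(cfg, list(rates = list(d_ext = 2e-4)))
  sim2 <- run_simulation(cfg2)
  expect_gt(sim2$cum_degraded[length(sim2$times)], 0)
  expect_equal(rowSums(sim2$field) + rowSums(sim2$bound_ifnar) +
                 sim2$cum_degraded,
               sim2$cum_secreted + sim2$cum_pretreat)
})

test_that("runs are deterministic given the configuration", {
  cfg <- tiny_config(moi = 1, seed = 17,
                     rates = rate_table(k_f1 = 0.02, k_act = 0.05,
                                        v_ifnb_low = 0.5, k_sec = 0.05))
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$m_dx, b$m_dx)
  expect_identical(a$field, b$field)
  expect_identical(a$cells, b$cells)
  c2 <- run_simulation(modify_config(cfg, list(seed = 18L)))
  expect_false(identical(a$m_dx, c2$m_dx))
})

test_that("a no-infection run produces no cytokine and Poisson DDX58 noise", {
  cfg <- sim_config(moi = 0, total_hours = 4, seed = 3)
  sim <- run_simulation(cfg)
  expect_equal(sum(sim$field), 0L)
  expect_equal(sum(sim$m_ifnb), 0L)
  expect_true(all(sim$bound_ifnar == 0L))
  fano <- sim$series$fano_dx
  expect_true(all(abs(fano - 1) < 0.6))   # per-time, 210 cells
  expect_lt(abs(mean(fano) - 1), 0.1)
})
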
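# population summaries

test_that("fano_factor uses sample variance over mean with NA sentinel", {
  expect_equal(fano_factor(c(5, 5, 5, 5)), 0)
  expect_equal(fano_factor(c(2, 4, 6)), 1)          # mean 4, sample var 4
  expect_true(is.na(fano_factor(c(0, 0, 0))))       # undefined, not zero
  expect_error(fano_factor(numeric(0)), "non-empty")
  set.seed(42)
  expect_lt(abs(fano_factor(rpois(1e5, 20)) - 1), 0.02)
})

test_that("fraction_expressing counts infected cells only", {
  m <- c(0, 3, 0, 9, 0, 2)
  inf <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(fraction_expressing(m, inf), 0.5)
  expect_equal(fraction_expressing(rep(0, 6), inf), 0)
  expect_true(is.na(fraction_expressing(m, rep(FALSE, 6))))
})

test_that("spatial categories use half-open upward binning", {
  bp <- c(375, 750, 1125)
  expect_equal(categorize_spatial_map(0, bp), 0L)
  expect_equal(categorize_spatial_map(375, bp), 1L)  # boundary goes up
  expect_equal(categorize_spatial_map(c(374, 750, 1124, 1125, 5000), bp),
               c(0L, 2L, 2L, 3L, 3L))
  expect_equal(categorize_spatial_map(1300, c(133, 400, 1200)), 3L)
  m <- matrix(c(0, 200, 500, 1300), 2)
  expect_equal(categorize_spatial_map(m, c(133, 400, 1200)),
               matrix(c(0L, 1L, 2L, 3L), 2))
  expect_error(categorize_spatial_map(1, c(3, 2, 5)), "increasing")
  # invariant to box enumeration order
  set.seed(1)
  v <- sample(0:2000, 200)
  perm <- sample(200)
  expect_equal(categorize_spatial_map(v, bp)[perm],
               categorize_spatial_map(v[perm], bp))
})

test_that("bound-receptor histograms partition the population", {
  set.seed(7)
  bound <- rpois(120, 300)
  m <- ifelse(runif(120) < 0.4, rpois(120, 50), 0)
  h <- bound_receptor_histograms(bound, m)
  expect_equal(sum(h$with_mrna$count), sum(m > 0))
  expect_equal(sum(h$with_mrna$count) + sum(h$without_mrna$count), 120)
  expect_identical(h$with_mrna[c("bin_lo", "bin_hi")],
                   h$without_mrna[c("bin_lo", "bin_hi")])
  none <- bound_receptor_histograms(rep(0L, 10), rep(0L, 10))
  expect_equal(sum(none$without_mrna$count[none$without_mrna$bin_lo == 0]), 10)
})

test_that("autocrine fraction sentinels and the single-cell limit", {
  expect_true(is.na(autocrine_fraction(NULL, c(1, 2))))     # tagging off
  expect_true(is.na(autocrine_fraction(c(0, 0), c(0, 0))))  # nothing bound
  expect_equal(autocrine_fraction(c(2, 1), c(4, 2)), 0.5)

  # one secreting cell alone on a 1-box lattice: every complex is autocrine
  cfg <- sim_config(grid_nx = 1L, grid_ny = 1L, n_cells = 1L, moi = 50,
                    total_hours = 0.5, sample_interval = 300,
                    tag_sources = TRUE, simultaneous_onset_h = 0,
                    seed = 2,
                    rates = rate_table(v_ifnb_low = 0.5, k_sec = 0.05,
                                       k_on_r = 1e-4))
  sim <- run_simulation(cfg)
  last <- length(sim$times)
  expect_gt(sim$bound_ifnar[last, 1], 0)
  expect_equal(sim$self_bound[last, 1], sim$bound_ifnar[last, 1])
  expect_equal(sim$series$autocrine_fraction[last], 1)
})

test_that("observable series and run summary are consistent with snapshots", {
  cfg <- tiny_config(moi = 1, seed = 9,
                     rates = rate_table(k_f1 = 0.02, k_act = 0.05,
                                        v_ifnb_low = 0.5, k_sec = 0.05))
  sim <- run_simulation(cfg)
  s <- sim$series
  i <- length(sim$times)
  expect_equal(s$fano_dx[i], fano_factor(sim$m_dx[i, ]))
  expect_equal(s$frac_expressing[i],
               fraction_expressing(sim$m_ifnb[i, ], sim$cells$infected))
  expect_equal(s$mean_dx[i], mean(sim$m_dx[i, ]))
  occ <- free_cytokine_at_cells(sim, sim$times[i] / 3600)
  expect_equal(s$frac_boxes_low[i], mean(occ < 133))
  sm <- summarize_sim(sim, at_hours = sim$times[i] / 3600)
  expect_equal(sm$fano_peak, max(s$fano_dx, na.rm = TRUE))
})
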
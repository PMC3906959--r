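# per-cell reaction network: propensities and exact SSA, validated against
# closed forms and brute-force master-equation solves

cfg <- sim_config()

test_that("enhanceosome propensities gate on infection, RIG-I and occupancy", {
  r <- cfg$rates
  expect_error(
    enhanceosome_propensities(new_cell_state(infected = FALSE), r),
    "infected")

  # no viral sensing without RIG-I protein
  s0 <- new_cell_state(infected = TRUE, p_rig = 0L)
  a0 <- enhanceosome_propensities(s0, r)
  expect_equal(unname(a0[1:8]), rep(0, 8))

  # saturation: forward propensity of the occupied step approaches k_f1*coop^i
  kf <- enh_forward_rates(r)
  expect_true(all(diff(kf) >= 0))  # cooperative: non-decreasing
  for (occ in 0:3) {
    s <- new_cell_state(infected = TRUE, enh_occ = occ, p_rig = 10000000L)
    a <- enhanceosome_propensities(s, r)
    expect_equal(unname(a[occ + 1]), kf[occ + 1], tolerance = 1e-4)
    expect_equal(sum(a[setdiff(1:4, occ + 1)]), 0)  # only current step active
  }
  # full occupancy: activation only
  s4 <- new_cell_state(infected = TRUE, enh_occ = 4L, p_rig = 100L)
  a4 <- enhanceosome_propensities(s4, r)
  expect_equal(unname(a4[["ifnb_activate"]]), r$k_act)
  expect_equal(sum(a4[1:4]), 0)
  # transcribing: deactivation only
  st <- new_cell_state(infected = TRUE, enh_occ = 4L,
                       ifnb_gene = "transcribing")
  at <- enhanceosome_propensities(st, r)
  expect_equal(unname(at[["ifnb_deactivate"]]), r$k_deact)
  expect_equal(sum(at[1:9]), 0)
})

test_that("transcribing fraction matches the 6-state chain stationary solve", {
  # fast artificial chain rates, constant H ~ 1 (saturating RIG-I, frozen)
  r <- rate_table(k_f1 = 0.02, coop = 1.5, k_b1 = 0.03, k_b2 = 0.03,
                  k_b3 = 0.03, k_b4 = 0.03, k_act = 0.05, k_deact = 0.02,
                  v_ifnb_low = 0, v_ifnb_high = 0, d_ifnb = 0, k_sec = 0,
                  k_on_r = 0, k_off_r = 0, k_g_off = 0, v_dx_basal = 0,
                  v_dx_active = 1e-9, d_dx = 0, k_tr_rig = 0, d_rig = 0,
                  K_rig = 100, h_rig = 2)
  H <- 1e8^2 / (100^2 + 1e8^2)
  oracle <- chain6_stationary(r, H)
  s0 <- new_cell_state(infected = TRUE, p_rig = 100000000L)
  env <- local_environment(0)
  n <- 1200
  finals <- ssa_ensemble(s0, env, T = 600, cfg, r, n, seed = 21)
  frac_tx <- mean(vapply(finals, function(s)
    s$ifnb_gene == "transcribing", TRUE))
  p <- oracle$p_transcribing
  expect_lt(abs(frac_tx - p), 3.5 * sqrt(p * (1 - p) / n))
})

test_that("IFN-beta transcription rate follows the bound-receptor Hill form", {
  r <- cfg$rates
  tx <- function(B, gene = "transcribing")
    ifnb_transcription_rate(new_cell_state(infected = TRUE, enh_occ = 4L,
                                           ifnb_gene = gene, bound_ifnar = B),
                            r, b_half = 475)
  expect_equal(tx(0L), r$v_ifnb_low)
  expect_equal(tx(475L), (r$v_ifnb_low + r$v_ifnb_high) / 2)
  expect_equal(ifnb_transcription_rate(
    new_cell_state(infected = TRUE, bound_ifnar = 900L), r), 0)
})

test_that("DDX58 switch rates realize half-maximal induction at threshold", {
  r <- cfg$rates
  expect_equal(unname(ddx58_switch_rates(0, cfg)["k_on"]), 0)
  k <- ddx58_switch_rates(475, cfg)
  expect_equal(unname(k["k_on"]), unname(k["k_off"]))
  expect_equal(unname(k["k_on"] / (k["k_on"] + k["k_off"])), 0.5)
  k2 <- ddx58_switch_rates(950, cfg)
  expect_equal(unname(k2["k_on"]), 4 * r$k_g_off)
  expect_equal(unname(k2["k_on"] / (k2["k_on"] + k2["k_off"])), 4 / 5)
  expect_error(ddx58_switch_rates(1001, cfg), "B")
  bad <- cfg; bad$threshold_fraction <- 0  # bypass constructor for the guard
  expect_error(ddx58_switch_rates(100, bad), "threshold")
})

test_that("full channel list is gated correctly", {
  r <- cfg$rates
  env0 <- local_environment(0)
  # uninfected cell, empty box: only DDX58/RIG-I channels and unbinding live
  s <- new_cell_state(infected = FALSE, bound_ifnar = 10L, m_dx = 5L,
                      p_rig = 50L, dx_gene = "active")
  a <- reaction_propensities(s, env0, cfg)
  live <- names(a[a > 0])
  expect_setequal(live, c("r_unbind", "dx_off", "dx_tx", "dx_deg",
                          "rig_tr", "rig_deg"))
  # no free receptors -> no binding
  s2 <- new_cell_state(infected = FALSE, receptors = 10L, bound_ifnar = 10L)
  a2 <- reaction_propensities(s2, local_environment(1000L), cfg)
  expect_equal(unname(a2[["r_bind"]]), 0)
  # binding propensity is k_on_r * free_cytokine * free_receptors
  s3 <- new_cell_state(infected = FALSE, receptors = 1000L,
                       bound_ifnar = 400L)
  a3 <- reaction_propensities(s3, local_environment(250L), cfg)
  expect_equal(unname(a3[["r_bind"]]), r$k_on_r * 250 * 600)
  expect_equal(unname(a3[["r_unbind"]]), r$k_off_r * 400)
})

test_that("SSA matches birth-death closed forms (Poisson law, decay)", {
  # zero total propensity: state unchanged, clock advances
  dead <- frozen_b_rates(0, 0, 1e-9, 0)
  s0 <- new_cell_state(infected = FALSE, m_dx = 7L)
  out <- ssa_advance(s0, local_environment(0), 0, 100, cfg, dead, seed = 1)
  expect_identical(out$state$m_dx, 7L)
  expect_equal(out$n_events, 0)

  # pure death: ensemble mean decays as m0 * exp(-d t)
  r_death <- frozen_b_rates(0, 0, 1e-9, d_dx = 0.02)
  m0 <- 50L
  finals <- ssa_ensemble(new_cell_state(m_dx = m0), local_environment(0),
                         T = 40, cfg, r_death, n = 2000, seed = 5)
  m_T <- vapply(finals, function(s) s$m_dx, 1L)
  expected <- m0 * exp(-0.02 * 40)
  expect_lt(abs(mean(m_T) - expected), 4 * sd(m_T) / sqrt(length(m_T)))

  # birth-death reaches the Poisson stationary law (chi-square GOF)
  r_bd <- frozen_b_rates(0, v_dx_basal = 0.5, v_dx_active = 1, d_dx = 0.01)
  lam <- 0.5 / 0.01
  finals <- ssa_ensemble(new_cell_state(m_dx = as.integer(lam)),
                         local_environment(0), T = 600, cfg, r_bd,
                         n = 4000, seed = 11)
  m_T <- vapply(finals, function(s) s$m_dx, 1L)
  expect_lt(abs(fano_factor(m_T) - 1), 0.08)
  breaks <- c(-Inf, qpois(seq(0.1, 0.9, 0.1), lam), Inf)
  obs <- table(cut(m_T, breaks))
  expc <- diff(ppois(c(-Inf, qpois(seq(0.1, 0.9, 0.1), lam), Inf), lam)) *
    length(m_T)
  chi2 <- sum((as.numeric(obs) - expc)^2 / expc)
  expect_lt(chi2, qchisq(0.999, df = length(expc) - 1))
})

test_that("frozen-B telegraph Fano matches the truncated CME solve", {
  v0 <- 0.1; v1 <- 2; d <- 0.01; kg <- 0.01
  r <- frozen_b_rates(kg, v0, v1, d)
  # B frozen at the threshold: k_on = k_off = k_g_off
  oracle <- telegraph_cme(v0, v1, d, kg, kg, M = 450)
  expect_lt(oracle$tail, 1e-8)  # truncation adequate
  expect_equal(oracle$mean, (v0 + v1) / 2 / d, tolerance = 1e-6)
  expect_equal(oracle$fano, telegraph_fano_closed(v0, v1, d, kg, kg),
               tolerance = 1e-3)

  s0 <- new_cell_state(infected = FALSE, bound_ifnar = 475L,
                       m_dx = round(oracle$mean))
  finals <- ssa_ensemble(s0, local_environment(0), T = 1500, cfg, r,
                         n = 1500, seed = 31)
  m_T <- vapply(finals, function(s) s$m_dx, 1L)
  expect_equal(mean(m_T), oracle$mean, tolerance = 0.05)
  # Fano within Monte-Carlo error (bootstrap SE)
  set.seed(1)
  boot <- replicate(200, fano_factor(sample(m_T, replace = TRUE)))
  expect_lt(abs(fano_factor(m_T) - oracle$fano), 4 * sd(boot))
})

test_that("receptor pool is conserved through eventful windows", {
  r <- rate_table(k_on_r = 1e-3, k_off_r = 0.05)  # busy binding traffic
  s <- new_cell_state(infected = FALSE, receptors = 1000L)
  env <- local_environment(500L)
  set.seed(8)
  for (i in 1:40) {
    out <- ssa_advance(s, env, 0, 5, cfg, r)
    s <- out$state; env <- out$env
    expect_identical(s$bound_ifnar + s$free_ifnar, 1000L)
    expect_gte(env$free_ifnb_in_box, 0)
  }
  expect_gt(s$bound_ifnar, 0)  # the traffic actually happened
})

test_that("uninfected cells never acquire IFN-beta machinery", {
  sim <- run_simulation(sim_config(grid_nx = 12L, grid_ny = 12L,
                                   n_cells = 40L, moi = 3, total_hours = 1,
                                   seed = 4,
                                   rates = rate_table(k_f1 = 0.05,
                                                      k_act = 0.05,
                                                      v_ifnb_low = 0.5)))
  unin <- !sim$cells$infected
  expect_gt(sum(unin), 0)
  expect_true(all(sim$m_ifnb[, unin] == 0))
  expect_true(all(sim$ifnb_gene[, unin] == 0))
  expect_true(all(sim$enh_occ[, unin] == 0))
  # and with these fast rates some infected cell did express
  expect_gt(max(sim$m_ifnb[, !unin]), 0)
})
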
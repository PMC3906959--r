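# Independent numerical oracles used to validate the stochastic kernels.
# These are deliberately brute-force (direct linear solves of truncated
# master equations) and share no code with the simulation path.

# Stationary distribution of the two-state (telegraph) gene CME, truncated
# at copy number M: states (g, m), g in {0, 1}, m in 0..M. Returns the
# stationary mean, variance and Fano factor of m.
telegraph_cme <- function(v0, v1, d, k_on, k_off, M) {
  n <- 2L * (M + 1L)
  idx <- function(g, m) g * (M + 1L) + m + 1L
  Q <- matrix(0, n, n)  # generator, Q[i, j] = rate i -> j
  for (g in 0:1) {
    v <- if (g == 1) v1 else v0
    for (m in 0:M) {
      i <- idx(g, m)
      if (m < M) Q[i, idx(g, m + 1L)] <- v
      if (m > 0) Q[i, idx(g, m - 1L)] <- d * m
      Q[i, idx(1L - g, m)] <- if (g == 0) k_on else k_off
    }
  }
  diag(Q) <- -rowSums(Q)
  # solve pi Q = 0, sum(pi) = 1 by replacing one balance equation
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- solve(A, b)
  m_marg <- p[1:(M + 1L)] + p[(M + 2L):n]
  m_vals <- 0:M
  mu <- sum(m_vals * m_marg)
  va <- sum((m_vals - mu)^2 * m_marg)
  list(mean = mu, var = va, fano = va / mu, tail = m_marg[M + 1L])
}

# Closed-form telegraph Fano factor (fluctuation-dissipation result for the
# two-state birth-death process); used to cross-check the CME solve.
telegraph_fano_closed <- function(v0, v1, d, k_on, k_off) {
  p <- k_on / (k_on + k_off)
  vbar <- v0 + (v1 - v0) * p
  1 + (v1 - v0)^2 * p * (1 - p) / ((k_on + k_off + d) * vbar)
}

# Stationary distribution of the 6-state enhanceosome/gene chain
# (occupancies 0..4 while assembling, plus the transcribing state) for a
# fixed RIG-I response H. Returns the probability vector and the
# transcribing-state occupancy.
chain6_stationary <- function(rates, H) {
  kf <- enh_forward_rates(rates) * H
  kb <- unlist(rates[c("k_b1", "k_b2", "k_b3", "k_b4")])
  Q <- matrix(0, 6, 6)  # states 1..5 = occ 0..4 (assembling), 6 = transcribing
  for (i in 1:4) {
    Q[i, i + 1] <- kf[i]
    Q[i + 1, i] <- kb[i]
  }
  Q[5, 6] <- rates$k_act
  Q[6, 1] <- rates$k_deact
  diag(Q) <- -rowSums(Q)
  A <- t(Q)
  A[6, ] <- 1
  p <- solve(A, c(rep(0, 5), 1))
  list(p = p, p_transcribing = p[6])
}

# A rate table whose only live channels are the DDX58/RIG-I subsystem, with
# receptor binding frozen so the bound count stays wherever it is put.
frozen_b_rates <- function(k_g_off, v_dx_basal, v_dx_active, d_dx) {
  rate_table(k_f1 = 0, coop = 1, k_b1 = 0, k_b2 = 0, k_b3 = 0, k_b4 = 0,
             k_act = 0, k_deact = 0, v_ifnb_low = 0, v_ifnb_high = 0,
             d_ifnb = 0, k_sec = 0, k_on_r = 0, k_off_r = 0,
             k_g_off = k_g_off, v_dx_basal = v_dx_basal,
             v_dx_active = v_dx_active, d_dx = d_dx,
             k_tr_rig = 0, d_rig = 0)
}

# Advance n independent cells to time T and return their final states.
ssa_ensemble <- function(state0, env0, T, config, rates, n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    ssa_advance(state0, env0, 0, T, config, rates)$state)
}

# small, fast configuration for unit tests
tiny_config <- function(...) {
  sim_config(grid_nx = 10L, grid_ny = 10L, n_cells = 20L, total_hours = 0.25,
             sample_interval = 150, ...)
}
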
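test_that("Redfield rates obey exact detailed balance and the T -> 0 limit", {
  eig <- dimer_eigensystem(nr_homodimer(V = 0.4, M = 5))
  bath <- bath_spec(temperature = 300, gamma = 5)
  rates <- redfield_rates(eig, bath)
  kT <- vibrex_constants$kb_ev_k * 300
  E <- eig$energies
  for (a in c(2, 10, 25)) {
    for (b in c(1, 5, 18)) {
      if (a == b || rates$k[a, b] == 0) next
      ratio <- rates$k[a, b] / rates$k[b, a]
      expect_equal(ratio, exp((E[a] - E[b]) / kT), tolerance = 1e-12)
    }
  }
  # near zero temperature every uphill rate vanishes
  cold <- redfield_rates(eig, bath_spec(temperature = 1e-4, gamma = 5))
  dE <- outer(E, E, "-")
  expect_equal(max(cold$k[dE < 0]), 0)
  expect_gt(max(cold$k[dE > 0]), 0)
})

test_that("two-level rates equal the closed-form golden-rule expression", {
  # a system with two vibronic levels coupled through one coordinate
  p <- molecule_params(1.5, 0.6, 0.2, 0.2)
  eig <- dimer_eigensystem(dimer_spec(p, p, V = 0.3, M = 3))
  bath <- bath_spec(temperature = 250, gamma = 8)
  rates <- redfield_rates(eig, bath, coupling = "plus_only")
  g_fs <- 8 / 1000
  kT <- vibrex_constants$kb_ev_k * 250
  a <- 4; b <- 2                     # an arbitrary downhill pair
  w <- eig$energies[a] - eig$energies[b]
  n_occ <- 1 / expm1(w / kT)
  q2 <- Re(eig$Q_plus[a, b])^2
  expect_equal(rates$k[a, b], g_fs * q2 * (n_occ + 1), tolerance = 1e-12)
  expect_equal(rates$k[b, a], g_fs * q2 * n_occ, tolerance = 1e-12)
  # coherence decay = half-sum of the total outflows
  expect_equal(rates$Gamma[a, b],
               0.5 * (sum(rates$k[a, ]) + sum(rates$k[b, ])),
               tolerance = 1e-12)
})

test_that("impulsive initial state is trace-one with the right bright manifold", {
  eig_j <- dimer_eigensystem(nr_homodimer(V = -0.4, M = 7))
  s_j <- initial_state_impulsive(eig_j)
  expect_equal(Re(sum(diag(s_j))), 1, tolerance = 1e-12)
  expect_lt(max(abs(s_j - Conj(t(s_j)))), 1e-12)
  dom_j <- attr(s_j, "active")[which.max(Re(diag(s_j)))]
  expect_equal(eig_j$manifold[dom_j], "S1")

  eig_h <- dimer_eigensystem(nr_homodimer(V = 0.4, M = 7))
  s_h <- initial_state_impulsive(eig_h)
  dom_h <- attr(s_h, "active")[which.max(Re(diag(s_h)))]
  expect_equal(eig_h$manifold[dom_h], "S2")

  # a single bright state gives a pure state with population 1: donor-only
  # dipole in a gap-split pair with negligible mixing
  m1 <- molecule_params(1.5, 1e-9, 0, 0.2)
  m2 <- molecule_params(1.9, 1e-9, 0, 0.2)
  eig1 <- dimer_eigensystem(dimer_spec(m1, m2, V = 0, M = 1))
  s1 <- initial_state_impulsive(eig1, dipole = "site1")
  expect_equal(max(Re(diag(s1))), 1, tolerance = 1e-9)

  # thresholding drops weak states but keeps unit trace
  s_thr <- initial_state_impulsive(eig_h, threshold = 1e-3)
  expect_equal(Re(sum(diag(s_thr))), 1, tolerance = 1e-12)
  expect_lte(length(attr(s_thr, "active")), length(attr(s_h, "active")))
})

test_that("propagation conserves trace, stays positive and thermalizes", {
  eig <- dimer_eigensystem(nr_homodimer(V = 0.4, M = 6))
  bath <- bath_spec(temperature = 300, gamma = 5)
  rates <- redfield_rates(eig, bath)
  s0 <- initial_state_impulsive(eig)
  traj <- propagate(s0, rates, eig, times = seq(0, 2000, 10))
  expect_lt(traj$trace_drift, 1e-8)
  expect_gt(min(traj$populations), -1e-8)
  obs <- trajectory_observables(traj)
  tot <- obs$pop_G + obs$pop_S1 + obs$pop_S2 + obs$pop_higher
  expect_lt(max(abs(tot - 1)), 1e-8)
  expect_equal(obs$energy_ev[1],
               sum(Re(diag(s0)) * eig$energies[attr(s0, "active")]),
               tolerance = 1e-10)

  # very long times: every active-state population matches the Boltzmann
  # distribution over the active space
  far <- propagate(s0, rates, eig, times = c(0, 1e9, 2e9))
  p_inf <- far$populations[, 3]
  act <- far$active
  w <- exp(-(eig$energies[act] - min(eig$energies[act])) /
             (vibrex_constants$kb_ev_k * 300))
  expect_lt(max(abs(p_inf - w / sum(w))), 1e-6)

  # a thermal state is stationary
  th <- thermal_state(eig, 300, subset = act, active = act)
  stat <- propagate(th, rates, eig, times = seq(0, 500, 50))
  expect_lt(max(abs(stat$populations - Re(diag(th)))), 1e-9)
})

test_that("relaxation funnels into the Kasha state with residual S2 thermal population", {
  for (V in c(-1.2, -0.4, 0.4, 1.2)) {
    eig <- dimer_eigensystem(nr_homodimer(V = V, M = 7))
    rates <- redfield_rates(eig, bath_spec())
    s0 <- initial_state_impulsive(eig)
    traj <- propagate(s0, rates, eig, times = seq(0, 3000, 25))
    obs <- trajectory_observables(traj)
    last <- obs[nrow(obs), ]
    # after the fast transient the Kasha state holds the largest population
    expect_equal(last$pop_kasha, max(traj$populations[, ncol(traj$populations)]),
                 tolerance = 1e-10)
    expect_gt(last$pop_kasha, 0.5)
    # residual thermal population of the lowest S2 eigenstate
    kT <- vibrex_constants$kb_ev_k * 300
    dE <- eig$energies[eig$s2_lowest] - eig$energies[eig$kasha]
    expect_equal(last$pop_s2_lowest / last$pop_kasha, exp(-dE / kT),
                 tolerance = 0.05)
  }
})

test_that("<Q-> vanishes by symmetry along symmetric-dimer trajectories", {
  eig <- dimer_eigensystem(nr_homodimer(V = 0.4, M = 7))
  rates <- redfield_rates(eig, bath_spec())
  s0 <- initial_state_impulsive(eig)
  traj <- propagate(s0, rates, eig, times = seq(0, 2000, 10))
  obs <- trajectory_observables(traj)
  expect_lt(max(abs(obs$q_minus)), 1e-8)
  # the symmetric coordinate does move (coherent oscillations + relaxation)
  expect_gt(diff(range(obs$q_plus)), 0.1)
  # P_M1* of the symmetric dimer stays at 1/2 of the excited population
  expect_lt(max(abs(obs$p_m1 - obs$p_m2)), 1e-8)
})

test_that("coupling through Q+ alone blocks parity-changing relaxation", {
  spec <- nr_homodimer(V = 0.4, M = 6)
  eig <- dimer_eigensystem(spec)
  b <- eig$basis
  P <- nrow(b) / 4
  swap_elec <- c(1, 3, 2, 4)
  X <- matrix(0, nrow(b), nrow(b))
  for (r in seq_len(nrow(b))) {
    e <- (r - 1) %/% P + 1
    v <- r - (e - 1) * P
    X[(swap_elec[e] - 1) * P + v, r] <- (-1)^b$n2[v]
  }
  parity <- round(colSums(eig$vectors * (X %*% eig$vectors)))
  opposite <- outer(parity, parity, "!=")
  plus_only <- redfield_rates(eig, bath_spec(), coupling = "plus_only")
  expect_lt(max(plus_only$k[opposite]), 1e-20)
  both <- redfield_rates(eig, bath_spec(), coupling = "both")
  expect_gt(max(both$k[opposite]), 1e-4)
})

test_that("secular propagation matches an independent dense ODE integration", {
  skip_if_not_installed("deSolve")
  eig <- dimer_eigensystem(nr_homodimer(V = 0.4, M = 3))
  rates <- redfield_rates(eig, bath_spec())
  s0 <- initial_state_impulsive(eig)
  act <- attr(s0, "active")
  na <- length(act)
  traj <- propagate(s0, rates, eig, times = seq(0, 500, 25))

  # independent route: integrate the same secular master equation (Pauli
  # populations + independently decaying coherences) with lsoda
  k_act <- rates$k[act, act]
  K <- t(k_act); diag(K) <- diag(K) - rowSums(k_act)
  outflow <- rowSums(k_act)
  E <- eig$energies[act]
  hbar <- vibrex_constants$hbar_ev_fs
  pairs <- which(upper.tri(s0), arr.ind = TRUE)
  y0 <- c(Re(diag(s0)), Re(s0[pairs]), Im(s0[pairs]))
  np <- nrow(pairs)
  deriv <- function(t, y, parms) {
    p <- y[1:na]
    re <- y[na + seq_len(np)]
    im <- y[na + np + seq_len(np)]
    w <- (E[pairs[, 1]] - E[pairs[, 2]]) / hbar
    g <- 0.5 * (outflow[pairs[, 1]] + outflow[pairs[, 2]])
    list(c(as.vector(K %*% p),
           w * im - g * re,
           -w * re - g * im))
  }
  sol <- deSolve::lsoda(y0, seq(0, 500, 25), deriv, parms = NULL,
                        rtol = 1e-11, atol = 1e-12)
  expect_lt(max(abs(t(sol[, 1 + seq_len(na)]) - traj$populations)), 1e-8)
  # spot-check a coherence against the analytic decay at the final time
  sig_end <- sigma_at(traj, 500)
  re_ode <- sol[nrow(sol), 1 + na + seq_len(np)]
  expect_lt(max(abs(re_ode - Re(sig_end[pairs]))), 1e-8)
})

test_that("Arnoldi stepper agrees with the exact population propagator", {
  eig <- dimer_eigensystem(nr_homodimer(V = 0.4, M = 5))
  rates <- redfield_rates(eig, bath_spec())
  s0 <- initial_state_impulsive(eig)
  t_grid <- seq(0, 800, 8)
  exact <- propagate(s0, rates, eig, times = t_grid)
  sia <- propagate(s0, rates, eig, times = t_grid, method = "arnoldi")
  expect_lt(max(abs(exact$populations - sia$populations)), 1e-8)
})

test_that("zero coupling gives purely unitary dynamics with constant energy", {
  eig <- dimer_eigensystem(nr_homodimer(V = 0.4, M = 6))
  rates <- redfield_rates(eig, bath_spec(gamma = 0))
  s0 <- initial_state_impulsive(eig)
  traj <- propagate(s0, rates, eig, times = seq(0, 1000, 5))
  en <- trajectory_observables(traj)$energy_ev
  expect_lt(max(abs(en - en[1])), 1e-9)
  expect_lt(traj$trace_drift, 1e-12)
})
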
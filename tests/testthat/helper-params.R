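# Shared fixtures: the two reference dyes and small dimer builders.

nr_params <- function(mu0 = 20) {
  molecule_params(gap_2z = 1.76, tau = 0.95, eps_v = 0.33,
                  hbar_omega_v = 0.14, mu0 = mu0)
}

dans_params <- function(mu0 = 20) {
  molecule_params(gap_2z = 2.64, tau = 0.72, eps_v = 0.30,
                  hbar_omega_v = 0.17, mu0 = mu0)
}

# NR homodimer in the symmetrized-mode representation (the reference setup
# that lifts the homodimer degeneracies without breaking symmetry)
nr_homodimer <- function(V, M = 8, ...) {
  nr <- nr_params()
  dimer_spec(nr, nr, V = V, M = M, hbar_omega_plus = 0.15,
             hbar_omega_minus = 0.13, ...)
}

dans_nr_pair <- function(V, M = 10, ...) {
  dimer_spec(dans_params(), nr_params(), V = V, M = M, ...)
}

# brute-force fixed-point oracle: dense scan of rho over [0, 1] bracketing
# the root of rho - rho_ground(gap_eff(rho)), then bisection
bruteforce_ionicity <- function(params, V = 0, rho_partner = 0,
                                n_scan = 2001, tol = 1e-12) {
  f <- function(rho) {
    gap <- params$gap_2z - 2 * params$eps_v * rho + V * rho_partner
    0.5 * (1 - gap / sqrt(gap^2 + 4 * params$tau^2)) - rho
  }
  grid <- seq(0, 1, length.out = n_scan)
  vals <- vapply(grid, f, numeric(1))
  i <- which(vals[-1] * vals[-n_scan] <= 0)[1]
  lo <- grid[i]; hi <- grid[i + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
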
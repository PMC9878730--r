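test_that("basis truncation follows the strict-inequality convention", {
  nr <- nr_params()
  expect_equal(nrow(build_basis(dimer_spec(nr, nr, V = 0, M = 14))), 420)
  expect_equal(nrow(build_basis(dimer_spec(nr, nr, V = 0, M = 1))), 4)
  # count formula vs explicit enumeration for a range of M
  for (M in c(2, 3, 5, 9)) {
    b <- build_basis(dimer_spec(nr, nr, V = 0, M = M))
    expect_equal(nrow(b), 4 * M * (M + 1) / 2)
    expect_true(all(b$n1 + b$n2 < M))
    # explicit enumeration oracle
    cnt <- 0L
    for (n1 in 0:(M - 1)) for (n2 in 0:(M - 1)) if (n1 + n2 < M) cnt <- cnt + 1L
    expect_equal(nrow(b), 4L * cnt)
    # deterministic ordering: electronic major, then lexicographic quanta
    expect_equal(b$elec, rep(c("NN", "ZN", "NZ", "ZZ"), each = cnt))
    expect_false(is.unsorted(b$n1[seq_len(cnt)]))
  }
})

test_that("dimer Hamiltonian separates at V = 0 and shifts ZZ by exactly V", {
  m1 <- molecule_params(1.5, 0.6, 0.2, 0.2)
  m2 <- molecule_params(2.0, 0.8, 0.3, 0.25)
  # separability: with a generous M, low eigenvalues are pairwise sums of
  # monomer eigenvalues
  M <- 16
  h0 <- build_dimer_hamiltonian(dimer_spec(m1, m2, V = 0, M = M))
  expect_equal(h0, t(h0), tolerance = 1e-12)
  vals <- sort(eigen(h0, symmetric = TRUE, only.values = TRUE)$values)
  e1 <- monomer_eigensystem(m1, n_max = 24)$energies
  e2 <- monomer_eigensystem(m2, n_max = 24)$energies
  sums <- sort(outer(e1, e2, "+"))
  expect_equal(vals[1:12], sums[1:12], tolerance = 1e-6)

  # the only effect of V on matrix elements: +V on every ZZ diagonal element
  spec_v <- dimer_spec(m1, m2, V = 0.7, M = 5)
  hv <- build_dimer_hamiltonian(spec_v)
  h0 <- build_dimer_hamiltonian(dimer_spec(m1, m2, V = 0, M = 5))
  d <- hv - h0
  b <- build_basis(spec_v)
  expect_equal(diag(d), ifelse(b$elec == "ZZ", 0.7, 0))
  d2 <- d; diag(d2) <- 0
  expect_equal(max(abs(d2)), 0)
})

test_that("retained low-lying eigenvalues are converged and variational in M", {
  spec14 <- nr_homodimer(V = 1.2, M = 14)
  spec16 <- nr_homodimer(V = 1.2, M = 16)
  v14 <- sort(eigen(build_dimer_hamiltonian(spec14), symmetric = TRUE,
                    only.values = TRUE)$values)[1:10]
  v16 <- sort(eigen(build_dimer_hamiltonian(spec16), symmetric = TRUE,
                    only.values = TRUE)$values)[1:10]
  expect_lt(max(abs(v14 - v16)), 1e-6)
  # variational monotonicity: enlarging the basis never raises a low state
  expect_true(all(v16 <= v14 + 1e-12))
})

test_that("exciton mapping J = V rho (1 - rho) matches the printed endpoint", {
  nr <- nr_params()
  ex <- exciton_parameters(dimer_spec(nr, nr, V = 1.2, M = 4))
  rho <- solve_mean_field_ionicity(nr)$rho_bar
  expect_equal(ex$J, 1.2 * rho * (1 - rho), tolerance = 1e-12)
  # the paper's printed range endpoint ~0.16 eV
  expect_lt(abs(ex$J - 0.16), 0.02)
  expect_equal(exciton_parameters(dimer_spec(nr, nr, V = 0, M = 4))$J, 0)
  # rho = 0.5 algebraic case: J = V/4
  sym <- molecule_params(0, 1, 0, 0.2)
  exs <- exciton_parameters(dimer_spec(sym, sym, V = 1, M = 4))
  expect_equal(exs$J, 0.25, tolerance = 1e-10)
})

test_that("symmetrized modes are unitarily equivalent at equal frequencies", {
  nr <- nr_params()
  s_site <- dimer_spec(nr, nr, V = 0.6, M = 7)
  s_sym <- dimer_spec(nr, nr, V = 0.6, M = 7, hbar_omega_plus = 0.14,
                      hbar_omega_minus = 0.14)
  e_site <- sort(eigen(build_dimer_hamiltonian(s_site), symmetric = TRUE,
                       only.values = TRUE)$values)
  e_sym <- sort(eigen(build_dimer_hamiltonian(s_sym), symmetric = TRUE,
                      only.values = TRUE)$values)
  expect_lt(max(abs(e_site[1:40] - e_sym[1:40])), 1e-8)

  # heterodimer (different vibrational parameters) is rejected
  expect_error(dimer_spec(nr, dans_params(), V = 0.1, M = 5,
                          hbar_omega_plus = 0.15, hbar_omega_minus = 0.13),
               "vibrational parameters")

  # distinct frequencies lift the accidental degeneracies without breaking
  # the electronic symmetry: <phi|Q-|phi> = 0 for every eigenstate
  eig <- dimer_eigensystem(nr_homodimer(V = 0.4, M = 7))
  expect_lt(max(abs(Re(diag(eig$Q_minus)))), 1e-10)
  # assigning distinct omega+/omega- widens the spread of the one-quantum
  # vibronic levels (this is what lifts the homodimer near-degeneracies)
  eq <- dimer_eigensystem(dimer_spec(nr, nr, V = 0, M = 7,
                                     hbar_omega_plus = 0.14,
                                     hbar_omega_minus = 0.14))
  neq <- dimer_eigensystem(dimer_spec(nr, nr, V = 0, M = 7,
                                      hbar_omega_plus = 0.15,
                                      hbar_omega_minus = 0.13))
  one_q_spread <- function(eig) {
    s1 <- eig$energies[eig$manifold != "G"]
    one_q <- sort(s1[s1 - s1[1] > 0.05][1:4])
    one_q[3] - one_q[1]
  }
  expect_gt(one_q_spread(neq), one_q_spread(eq) + 0.005)
})

test_that("dipole operator obeys the geometry sign and a tensor-product oracle", {
  nr <- nr_params()
  spec <- nr_homodimer(V = 0.4, M = 5)
  P <- 5 * 6 / 2
  b <- build_basis(spec)
  occ1 <- c(NN = 0, ZN = 1, NZ = 0, ZZ = 1)[b$elec]
  occ2 <- c(NN = 0, ZN = 0, NZ = 1, ZZ = 1)[b$elec]
  mu_par <- dipole_operator(spec, "total")
  expect_equal(diag(mu_par), unname(20 * (occ1 + occ2)))
  spec_ap <- dimer_spec(nr, nr, V = 0.4, geometry = "antiparallel", M = 5,
                        hbar_omega_plus = 0.15, hbar_omega_minus = 0.13)
  mu_ap <- dipole_operator(spec_ap, "total")
  expect_equal(diag(mu_ap), unname(20 * (occ1 - occ2)))
  # independent Kronecker-product oracle (site representation, full ops)
  sspec <- dimer_spec(nr, nr, V = 0.4, M = 5)
  rho1_el <- diag(c(0, 1, 0, 1))
  oracle <- 20 * kronecker(rho1_el, diag(P)) +
    20 * kronecker(diag(c(0, 0, 1, 1)), diag(P))
  expect_equal(dipole_operator(sspec, "total"), oracle)
})

test_that("bright state lies in S1 for J-dimers and S2 for H-dimers", {
  for (V in c(-1.2, -0.4)) {
    eig <- dimer_eigensystem(nr_homodimer(V = V, M = 7))
    bright <- which.max(abs(eig$dipole[-1, 1])) + 1
    expect_equal(eig$manifold[bright], "S1")
    expect_equal(bright, eig$kasha)     # J-dimer: Kasha state is bright
  }
  for (V in c(0.4, 1.2)) {
    eig <- dimer_eigensystem(nr_homodimer(V = V, M = 7))
    bright <- which.max(abs(eig$dipole[-1, 1])) + 1
    expect_equal(eig$manifold[bright], "S2")
  }
})

test_that("homodimer Hamiltonian commutes with site exchange", {
  # symmetrized representation with equal mode frequencies: exchange is
  # electronic swap (ZN <-> NZ) times parity (-1)^(n_minus)
  nr <- nr_params()
  spec <- dimer_spec(nr, nr, V = 0.5, M = 6, hbar_omega_plus = 0.14,
                     hbar_omega_minus = 0.14)
  H <- build_dimer_hamiltonian(spec)
  b <- build_basis(spec)
  P <- nrow(b) / 4
  swap_elec <- c(1, 3, 2, 4)
  X <- matrix(0, nrow(b), nrow(b))
  for (r in seq_len(nrow(b))) {
    e <- (r - 1) %/% P + 1
    v <- r - (e - 1) * P
    X[(swap_elec[e] - 1) * P + v, r] <- (-1)^b$n2[v]
  }
  expect_lt(max(abs(H %*% X - X %*% H)), 1e-12)
})

test_that("adiabatic PES has a double minimum for the H-dimer only", {
  qp <- seq(-1, 6, by = 0.05)
  qm <- seq(-4, 4, by = 0.05)
  shape <- function(V) {
    pes <- adiabatic_pes(nr_homodimer(V = V, M = 4), q_plus = qp, q_minus = qm)
    i <- which.min(pes$S1)
    cut <- pes[pes$Q_plus == pes$Q_plus[i], ]
    cut <- cut[order(cut$Q_minus), ]
    interior_minima <- which(diff(sign(diff(cut$S1))) == 2) + 1
    list(n_min = length(interior_minima),
         qm_min = cut$Q_minus[interior_minima],
         barrier = cut$S1[which.min(abs(cut$Q_minus))] - min(cut$S1))
  }
  h <- shape(1.2)
  expect_equal(h$n_min, 2)
  expect_equal(sort(h$qm_min), sort(-h$qm_min), tolerance = 1e-10)
  expect_gt(h$barrier, 1e-4)
  j <- shape(-1.2)
  expect_equal(j$n_min, 1)
  expect_equal(j$qm_min, 0, tolerance = 1e-10)

  # V = 0 separability: surfaces are sums of the two monomer adiabatic curves
  m <- nr_params()
  spec0 <- dimer_spec(m, m, V = 0, M = 4)
  pts <- adiabatic_pes(spec0, q_plus = c(-0.5, 0.9), q_minus = c(-0.3, 1.1))
  kap <- sqrt(2 * m$eps_v * m$hbar_omega_v)
  mono <- function(q) {
    h <- matrix(c(0, -m$tau, -m$tau, m$gap_2z - kap * q), 2, 2)
    eigen(h, symmetric = TRUE, only.values = TRUE)$values +
      0.5 * m$hbar_omega_v * q^2
  }
  for (r in seq_len(nrow(pts))) {
    q1 <- (pts$Q_plus[r] + pts$Q_minus[r]) / sqrt(2)
    q2 <- (pts$Q_plus[r] - pts$Q_minus[r]) / sqrt(2)
    expected <- sort(as.vector(outer(mono(q1), mono(q2), "+")))
    expect_equal(unlist(pts[r, c("S0", "S1", "S2", "S3")]), expected,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("eigensystem bookkeeping is orthonormal, sorted and trace-consistent", {
  eig <- dimer_eigensystem(nr_homodimer(V = 0.4, M = 6))
  expect_false(is.unsorted(eig$energies))
  n <- length(eig$energies)
  expect_lt(max(abs(crossprod(eig$vectors) - diag(n))), 1e-10)
  expect_equal(eig$manifold[1], "G")
  expect_true(all(eig$w1 >= -1e-10 & eig$w1 <= 1 + 1e-10))
  # dipole matrix in the eigenbasis is symmetric (real operator)
  expect_equal(eig$dipole, t(eig$dipole), tolerance = 1e-10)
})
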
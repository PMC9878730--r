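## Secular Redfield dynamics: the two vibrational coordinates of the dimer are
## coupled to two independent harmonic baths. With a flat spectral density
## J(omega) = gamma the golden-rule population rates are
##   k(a -> b) = gamma |<a|Q|b>|^2 * (n(|w_ab|) + 1)   downhill
##   k(a -> b) = gamma |<a|Q|b>|^2 *  n(|w_ab|)        uphill
## (Bose occupation n), which obey detailed balance exactly. In the secular
## approximation populations follow a Pauli master equation and each coherence
## decays independently with rate Gamma_ab = (outflow_a + outflow_b)/2 plus an
## optional pure-dephasing constant (zero by default: the flat-density
## omega -> 0 limit is not defined thermally).

#' Thermal bath specification
#'
#' @param temperature Bath temperature (K, > 0). Default 300.
#' @param gamma Overall system-bath coupling strength (ps^-1, >= 0; zero
#'   gives purely unitary dynamics); for the flat ("constant") spectral
#'   density this is the value of J(omega). Default 5.
#' @param kind \code{"constant"} (flat spectral density, the default) or
#'   \code{"debye"} (Debye form \code{J(w) = gamma * 2 w wc / (w^2 + wc^2)},
#'   peaking at \code{gamma} for \code{w = wc}).
#' @param debye_cutoff Debye cutoff energy (eV); required for
#'   \code{kind = "debye"}.
#' @return An object of class \code{bath_spec}.
#' @export
bath_spec <- function(temperature = 300, gamma = 5,
                      kind = c("constant", "debye"), debye_cutoff = NULL) {
  kind <- match.arg(kind)
  if (!(is.numeric(temperature) && temperature > 0))
    stop("'temperature' must be positive", call. = FALSE)
  if (!(is.numeric(gamma) && gamma >= 0))
    stop("'gamma' must be non-negative", call. = FALSE)
  if (kind == "debye" && (is.null(debye_cutoff) || debye_cutoff <= 0))
    stop("'debye_cutoff' (eV) must be supplied for a Debye bath", call. = FALSE)
  structure(list(temperature = temperature, gamma = gamma, kind = kind,
                 debye_cutoff = debye_cutoff),
            class = "bath_spec")
}

## Spectral density in fs^-1 at transition energy dE (eV, > 0)
spectral_density <- function(bath, dE) {
  g_fs <- bath$gamma / 1000
  if (bath$kind == "constant") return(rep.int(g_fs, length(dE)))
  wc <- bath$debye_cutoff
  g_fs * 2 * dE * wc / (dE^2 + wc^2)
}

#' Secular Redfield rates on the vibronic eigenbasis
#'
#' Computes golden-rule population transfer rates between all eigenstate pairs
#' for the chosen coupling operators (one independent bath per operator) and
#' the coherence decay rates of the secular master equation.
#'
#' @param eig A [dimer_eigensystem()].
#' @param bath A [bath_spec()].
#' @param coupling Which coordinates couple to (independent) baths:
#'   \code{"both"} (\code{Q+} and \code{Q-}, the default), \code{"plus_only"},
#'   or \code{"minus_only"}. Coupling only \code{Q+} blocks relaxation between
#'   manifolds of different exchange parity in a symmetric homodimer.
#' @param pure_dephasing Additional constant pure-dephasing rate added to
#'   every coherence (fs^-1, default 0).
#' @param secular_tol Energy splittings below this value (eV) are treated as
#'   degenerate: no thermal rate is assigned within a degenerate pair.
#' @return An object of class \code{redfield_rates}: \code{k} (matrix,
#'   \code{k[a, b]} = rate a -> b in fs^-1), \code{K} (Pauli generator,
#'   \code{dp/dt = K p}), \code{Gamma} (coherence decay matrix, fs^-1),
#'   \code{outflow}, \code{bath}, \code{coupling}.
#' @export
redfield_rates <- function(eig, bath, coupling = c("both", "plus_only",
                                                   "minus_only"),
                           pure_dephasing = 0, secular_tol = 1e-9) {
  stopifnot(inherits(eig, "vibronic_eigensystem"))
  if (!inherits(bath, "bath_spec")) stop("'bath' must be a bath_spec",
                                         call. = FALSE)
  coupling <- match.arg(coupling)
  ops <- switch(coupling,
    both = list(eig$Q_plus, eig$Q_minus),
    plus_only = list(eig$Q_plus),
    minus_only = list(eig$Q_minus))
  E <- eig$energies
  n <- length(E)
  dE <- outer(E, E, "-")          # dE[a, b] = E_a - E_b
  absdE <- abs(dE)
  nondeg <- absdE > secular_tol
  kT <- .kb * bath$temperature
  occ <- matrix(0, n, n)
  occ[nondeg] <- 1 / expm1(absdE[nondeg] / kT)
  jw <- matrix(0, n, n)
  jw[nondeg] <- spectral_density(bath, absdE[nondeg])
  q2 <- matrix(0, n, n)
  for (op in ops) q2 <- q2 + Re(op)^2
  k <- jw * q2 * (occ + (dE > 0))  # downhill (E_a > E_b) gets n + 1
  k[!nondeg] <- 0
  diag(k) <- 0

  outflow <- rowSums(k)
  K <- t(k)
  diag(K) <- diag(K) - outflow
  Gamma <- 0.5 * outer(outflow, outflow, "+") + pure_dephasing
  diag(Gamma) <- 0
  structure(list(k = k, K = K, Gamma = Gamma, outflow = outflow,
                 bath = bath, coupling = coupling,
                 pure_dephasing = pure_dephasing),
            class = "redfield_rates")
}

#' Impulsive initial state after delta-pulse excitation
#'
#' Builds the coherent superposition reached by acting with the dipole
#' operator on the ground state, \code{mu |phi_1>}, projected on the excited
#' eigenstates and normalized to unit trace. Eigenstates whose initial
#' population falls below \code{threshold} are dropped, and the active space
#' retains every eigenstate up to the highest initially populated one (the
#' relaxation targets below it are kept).
#'
#' @param eig A [dimer_eigensystem()].
#' @param dipole \code{"total"} for the full dimer dipole, or \code{"site1"} /
#'   \code{"site2"} for donor-only excitation in RET workflows.
#' @param threshold Relative population threshold (default 1e-6).
#' @return A complex matrix of class \code{reduced_density_matrix} on the
#'   active space, with attributes \code{"active"} (eigenstate indices) and
#'   \code{"time"} (0).
#' @export
initial_state_impulsive <- function(eig, dipole = c("total", "site1", "site2"),
                                    threshold = 1e-6) {
  dipole <- match.arg(dipole)
  mu <- switch(dipole, total = eig$dipole, site1 = eig$dipole1,
               site2 = eig$dipole2)
  amp <- Re(mu[, 1])
  amp[1] <- 0                       # excited states only
  norm2 <- sum(amp^2)
  if (norm2 <= 0) stop("zero total transition strength from the ground state",
                       call. = FALSE)
  pops <- amp^2 / norm2
  i_max <- max(which(pops >= threshold))
  active <- seq_len(i_max)
  psi <- amp[active] / sqrt(sum(amp[active]^2))
  sigma <- outer(psi, psi) + 0i
  structure(sigma, active = active, time = 0,
            class = "reduced_density_matrix")
}

#' Pure eigenstate as a density matrix
#'
#' @param eig A [dimer_eigensystem()].
#' @param index Eigenstate index (e.g. \code{eig$kasha}).
#' @param active Optional active-space indices (default: states up to
#'   \code{index}).
#' @return A \code{reduced_density_matrix}.
#' @export
pure_state <- function(eig, index, active = seq_len(index)) {
  stopifnot(index %in% active)
  sigma <- matrix(0 + 0i, length(active), length(active))
  sigma[match(index, active), match(index, active)] <- 1
  structure(sigma, active = active, time = 0,
            class = "reduced_density_matrix")
}

#' Thermal (Boltzmann) state over a set of eigenstates
#'
#' @param eig A [dimer_eigensystem()].
#' @param temperature Temperature (K).
#' @param subset Eigenstate indices carrying thermal population (default all
#'   states). Use e.g. the excited manifolds to build the quasi-equilibrated
#'   long-time emissive state.
#' @param active Active-space indices (default: \code{1:max(subset)}).
#' @return A \code{reduced_density_matrix} (diagonal).
#' @export
thermal_state <- function(eig, temperature = 300, subset = NULL,
                          active = NULL) {
  n <- length(eig$energies)
  if (is.null(subset)) subset <- seq_len(n)
  if (is.null(active)) active <- seq_len(max(subset))
  stopifnot(all(subset %in% active))
  E <- eig$energies[subset]
  w <- exp(-(E - min(E)) / (.kb * temperature))
  w <- w / sum(w)
  sigma <- matrix(0 + 0i, length(active), length(active))
  ii <- match(subset, active)
  sigma[cbind(ii, ii)] <- w
  structure(sigma, active = active, time = 0,
            class = "reduced_density_matrix")
}

#' Propagate the reduced density matrix under the secular master equation
#'
#' Populations evolve under the Pauli block (matrix-exponential via the
#' detailed-balance-symmetrized eigendecomposition of the generator, exact at
#' arbitrary times); each secular coherence evolves analytically with its own
#' frequency \code{omega_ab} and decay \code{Gamma_ab}. A Short-Iterative
#' Arnoldi (Krylov) stepper for the population block is available as an
#' independent cross-check (\code{method = "arnoldi"}).
#'
#' @param sigma0 Initial \code{reduced_density_matrix} (with its active space).
#' @param rates A [redfield_rates()] object (full-space; restricted
#'   internally).
#' @param eig The [dimer_eigensystem()] the state is expressed on.
#' @param times Output time grid (fs); default \code{seq(0, t_max, by = dt)}.
#' @param t_max,dt Convenience controls for the default grid (fs); defaults
#'   1000 fs and 1 fs.
#' @param method \code{"analytic"} (default) or \code{"arnoldi"}.
#' @param krylov_dim Krylov subspace dimension for the Arnoldi stepper.
#' @return An object of class \code{trajectory}: the observable time series
#'   (data frame \code{$observables} with energy, manifold populations,
#'   Kasha-state and lowest-S2 populations, \code{<Q+>}, \code{<Q->},
#'   \code{dQ-}, site-apportioned excitation populations \code{p_m1},
#'   \code{p_m2}), the population matrix, coherence bookkeeping, and the
#'   active space. Use [sigma_at()] to reconstruct the density matrix at any
#'   stored time.
#' @export
propagate <- function(sigma0, rates, eig, times = NULL, t_max = 1000, dt = 1,
                      method = c("analytic", "arnoldi"), krylov_dim = 12) {
  method <- match.arg(method)
  stopifnot(inherits(rates, "redfield_rates"),
            inherits(eig, "vibronic_eigensystem"))
  active <- attr(sigma0, "active")
  if (is.null(active)) active <- seq_len(nrow(sigma0))
  if (is.null(times)) times <- seq(0, t_max, by = dt)
  na <- length(active)
  E <- eig$energies[active]

  p0 <- Re(diag(sigma0))
  if (abs(sum(p0) - 1) > 1e-8)
    stop("initial state does not have unit trace", call. = FALSE)

  k_act <- rates$k[active, active, drop = FALSE]
  pops <- propagate_populations(k_act, p0, times, method, krylov_dim)

  ## coherences: sigma_ab(t) = sigma_ab(0) exp(-(i w_ab + Gamma_ab) t)
  outflow_act <- rowSums(k_act)
  coh <- which(upper.tri(sigma0) & abs(sigma0) > 1e-14, arr.ind = TRUE)
  coh_val0 <- sigma0[coh]
  coh_omega <- (E[coh[, 1]] - E[coh[, 2]]) / .hbar
  coh_gamma <- 0.5 * (outflow_act[coh[, 1]] + outflow_act[coh[, 2]]) +
    rates$pure_dephasing

  obs <- trajectory_observable_frame(eig, active, times, pops,
                                     coh, coh_val0, coh_omega, coh_gamma)
  drift <- max(abs(colSums(pops) - 1))
  if (drift > 1e-8)
    warning(sprintf("trace drift %.2e exceeds 1e-8", drift))
  min_pop <- min(pops)
  if (min_pop < -1e-8)
    warning(sprintf("positivity violated: most negative population %.2e",
                    min_pop))
  structure(list(times = times, populations = pops, active = active,
                 coh = coh, coh_val0 = coh_val0, coh_omega = coh_omega,
                 coh_gamma = coh_gamma, observables = obs, eig = eig,
                 trace_drift = drift, method = method),
            class = "trajectory")
}

## Population block. The Pauli generator is exponentiated per time step
## (Pade scaling-and-squaring via Matrix::expm, cached for each distinct step
## length), which stays well conditioned even when the initial population
## sits several eV above the ground state; a Short-Iterative-Arnoldi stepper
## is available as an independent cross-check.
propagate_populations <- function(k_act, p0, times, method, krylov_dim) {
  na <- length(p0)
  K <- t(k_act)
  diag(K) <- diag(K) - rowSums(k_act)
  pops <- matrix(0, na, length(times))
  pops[, 1] <- p0
  if (length(times) == 1 || max(abs(K)) == 0) {
    pops[] <- p0
    return(pops)
  }
  if (method == "arnoldi") {
    p <- p0
    for (i in seq_along(times)[-1]) {
      p <- krylov_expv(K, p, times[i] - times[i - 1], m = krylov_dim)
      pops[, i] <- p
    }
    return(pops)
  }
  dts <- diff(times)
  cache <- list()
  p <- p0
  for (i in seq_along(dts)) {
    key <- sprintf("%.12g", dts[i])
    if (is.null(cache[[key]])) {
      E <- as.matrix(Matrix::expm(Matrix::Matrix(K * dts[i])))
      # the exact propagator is column-stochastic; renormalizing the column
      # sums removes the Pade round-off drift at very long steps
      E <- sweep(E, 2, colSums(E), "/")
      cache[[key]] <- E
    }
    p <- as.vector(cache[[key]] %*% p)
    pops[, i + 1] <- p
  }
  pops
}

## Arnoldi approximation of expm(A * dt) %*% v
krylov_expv <- function(A, v, dt, m = 12, tol = 1e-12) {
  n <- length(v)
  m <- min(m, n)
  beta <- sqrt(sum(v^2))
  if (beta == 0) return(v)
  Q <- matrix(0, n, m + 1)
  H <- matrix(0, m + 1, m)
  Q[, 1] <- v / beta
  mk <- m
  for (j in seq_len(m)) {
    w <- A %*% Q[, j]
    for (i in seq_len(j)) {
      H[i, j] <- sum(Q[, i] * w)
      w <- w - H[i, j] * Q[, i]
    }
    ## re-orthogonalization for numerical safety
    for (i in seq_len(j)) {
      c2 <- sum(Q[, i] * w)
      H[i, j] <- H[i, j] + c2
      w <- w - c2 * Q[, i]
    }
    H[j + 1, j] <- sqrt(sum(w^2))
    if (H[j + 1, j] < tol) { mk <- j; break }
    Q[, j + 1] <- w / H[j + 1, j]
  }
  Hm <- H[seq_len(mk), seq_len(mk), drop = FALSE]
  eh <- eigen(Hm)
  e1 <- numeric(mk); e1[1] <- 1
  expH1 <- Re(eh$vectors %*% (exp(eh$values * dt) * solve(eh$vectors, e1)))
  as.vector(beta * Q[, seq_len(mk), drop = FALSE] %*% expH1)
}

trajectory_observable_frame <- function(eig, active, times, pops,
                                        coh, coh_val0, coh_omega, coh_gamma) {
  E <- eig$energies[active]
  man <- eig$manifold[active]
  qp <- Re(eig$Q_plus[active, active, drop = FALSE])
  qm <- Re(eig$Q_minus[active, active, drop = FALSE])
  qm2 <- Re(eig$Q_minus_sq[active, active, drop = FALSE])
  w1 <- eig$w1[active]; w2 <- eig$w2[active]
  wtot <- pmax(w1 + w2, 1e-12)
  share1 <- ifelse(man == "G", 0, w1 / wtot)
  share2 <- ifelse(man == "G", 0, w2 / wtot)
  kasha_i <- match(eig$kasha, active)
  s2_i <- match(eig$s2_lowest, active)

  ncoh <- nrow(coh)
  coh_qp <- if (ncoh) qp[coh[, c(2, 1), drop = FALSE]] else numeric(0)
  coh_qm <- if (ncoh) qm[coh[, c(2, 1), drop = FALSE]] else numeric(0)
  coh_qm2 <- if (ncoh) qm2[coh[, c(2, 1), drop = FALSE]] else numeric(0)

  nt <- length(times)
  out <- data.frame(time_fs = times, energy_ev = 0, pop_G = 0, pop_S1 = 0,
                    pop_S2 = 0, pop_higher = 0, pop_kasha = NA_real_,
                    pop_s2_lowest = NA_real_, q_plus = 0, q_minus = 0,
                    dq_minus = 0, p_m1 = 0, p_m2 = 0)
  for (i in seq_len(nt)) {
    p <- pops[, i]
    cvals <- if (ncoh) coh_val0 * exp(-(1i * coh_omega + coh_gamma) * times[i])
             else complex(0)
    out$energy_ev[i] <- sum(p * E)
    out$pop_G[i] <- sum(p[man == "G"])
    out$pop_S1[i] <- sum(p[man == "S1"])
    out$pop_S2[i] <- sum(p[man == "S2"])
    out$pop_higher[i] <- sum(p[man == "higher"])
    if (!is.na(kasha_i)) out$pop_kasha[i] <- p[kasha_i]
    if (!is.na(s2_i)) out$pop_s2_lowest[i] <- p[s2_i]
    qp_t <- sum(p * diag(qp)) + if (ncoh) 2 * Re(sum(cvals * coh_qp)) else 0
    qm_t <- sum(p * diag(qm)) + if (ncoh) 2 * Re(sum(cvals * coh_qm)) else 0
    qm2_t <- sum(p * diag(qm2)) + if (ncoh) 2 * Re(sum(cvals * coh_qm2)) else 0
    out$q_plus[i] <- qp_t
    out$q_minus[i] <- qm_t
    out$dq_minus[i] <- sqrt(max(qm2_t - qm_t^2, 0))
    out$p_m1[i] <- sum(p * share1)
    out$p_m2[i] <- sum(p * share2)
  }
  ## excitation share on each molecule among excited states only: immune to
  ## the slow common-mode leakage toward the ground manifold
  tot <- pmax(out$p_m1 + out$p_m2, 1e-300)
  out$p_m1_share <- out$p_m1 / tot
  out$p_m2_share <- out$p_m2 / tot
  out
}

#' Observable time series of a trajectory
#' @param traj A [propagate()] trajectory.
#' @return The observable data frame.
#' @export
trajectory_observables <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$observables
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(paste0("<trajectory> %d steps over %g fs, %d active states, ",
                     "trace drift %.1e\n"),
              length(x$times), max(x$times), length(x$active), x$trace_drift))
  invisible(x)
}

#' Reconstruct the reduced density matrix at a stored time
#'
#' @param traj A [propagate()] trajectory.
#' @param t Time (fs); the nearest stored time is used.
#' @return A \code{reduced_density_matrix} on the trajectory's active space.
#' @export
sigma_at <- function(traj, t) {
  i <- which.min(abs(traj$times - t))
  na <- length(traj$active)
  sigma <- matrix(0 + 0i, na, na)
  diag(sigma) <- traj$populations[, i]
  if (nrow(traj$coh)) {
    cvals <- traj$coh_val0 *
      exp(-(1i * traj$coh_omega + traj$coh_gamma) * traj$times[i])
    sigma[traj$coh] <- cvals
    sigma[traj$coh[, c(2, 1), drop = FALSE]] <- Conj(cvals)
  }
  structure(sigma, active = traj$active, time = traj$times[i],
            class = "reduced_density_matrix")
}
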
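## Single-molecule essential-state model: two diabatic states |N>, |Z> mixed
## by -tau and split by 2z, one effective vibration of quantum hbar_omega_v
## linearly coupled to the ionicity operator. The coupling constant is
## sqrt(eps_v * hbar_omega_v) on (a + a^dagger), i.e. sqrt(2 eps_v hbar_omega_v)
## on the dimensionless coordinate Q = (a + a^dagger)/sqrt(2), so that the
## |Z> diabatic surface relaxes by exactly eps_v below its value at the |N>
## equilibrium geometry.

#' Molecular parameters of the essential-state model
#'
#' Bundles the four molecular constants of the two-state + one-mode model of a
#' donor-acceptor (push-pull) dye, plus the permanent dipole moment of the
#' zwitterionic structure which sets the intensity scale.
#'
#' @param gap_2z Energy gap \code{2z} between the neutral \code{|N>} and the
#'   zwitterionic \code{|Z>} diabatic state (eV).
#' @param tau Magnitude of the mixing matrix element between \code{|N>} and
#'   \code{|Z>} (eV, enters the Hamiltonian as \code{-tau}); must be > 0.
#' @param eps_v Vibrational relaxation energy of the electron transfer from
#'   \code{|N>} to \code{|Z>} (eV); must be >= 0.
#' @param hbar_omega_v Vibrational quantum of the effective mode (eV); > 0.
#' @param mu0 Permanent dipole moment of \code{|Z>} (arbitrary units or Debye);
#'   the molecular dipole operator is \code{mu0 * rho_hat}. Default 1.
#' @return An object of class \code{molecule_params}.
#' @examples
#' nr <- molecule_params(gap_2z = 1.76, tau = 0.95, eps_v = 0.33,
#'                       hbar_omega_v = 0.14)
#' @export
molecule_params <- function(gap_2z, tau, eps_v, hbar_omega_v, mu0 = 1) {
  stopifnot(is.numeric(gap_2z), length(gap_2z) == 1L, is.finite(gap_2z))
  if (!(is.numeric(tau) && length(tau) == 1L && tau > 0))
    stop("'tau' must be a single positive number", call. = FALSE)
  if (!(is.numeric(hbar_omega_v) && length(hbar_omega_v) == 1L && hbar_omega_v > 0))
    stop("'hbar_omega_v' must be a single positive number", call. = FALSE)
  if (!(is.numeric(eps_v) && length(eps_v) == 1L && eps_v >= 0))
    stop("'eps_v' must be a single non-negative number", call. = FALSE)
  if (!(is.numeric(mu0) && length(mu0) == 1L && mu0 >= 0))
    stop("'mu0' must be a single non-negative number", call. = FALSE)
  structure(list(gap_2z = gap_2z, tau = tau, eps_v = eps_v,
                 hbar_omega_v = hbar_omega_v, mu0 = mu0),
            class = "molecule_params")
}

#' @export
print.molecule_params <- function(x, ...) {
  cat("<molecule_params>  2z =", x$gap_2z, "eV  tau =", x$tau,
      "eV  eps_v =", x$eps_v, "eV  hbar*omega_v =", x$hbar_omega_v,
      "eV  mu0 =", x$mu0, "\n")
  invisible(x)
}

## Ground-state ionicity of the bare 2x2 electronic problem
## [[0, -tau], [-tau, gap]]: weight of |Z> in the lower eigenvector.
rho_of_gap <- function(gap, tau) {
  if (tau == 0) return(if (gap > 0) 0 else if (gap < 0) 1 else 0.5)
  0.5 * (1 - gap / sqrt(gap^2 + 4 * tau^2))
}

## Effective (mean-field) diabatic gap seen by the electrons: the equilibrium
## displacement of the vibration lowers |Z> by 2*eps_v*rho_bar, while a partner
## molecule with mean ionicity rho_partner raises it by V*rho_partner.
effective_gap <- function(params, rho_bar, V = 0, rho_partner = 0) {
  params$gap_2z - 2 * params$eps_v * rho_bar + V * rho_partner
}

#' Self-consistent mean-field ionicity of one molecule
#'
#' Solves the fixed-point equation for the ground-state expectation value of
#' the ionicity operator, \code{rho_bar = <G|rho_hat|G>}. The effective 2x2
#' electronic Hamiltonian has a diabatic gap renormalized by the vibrational
#' relaxation (the oscillator displaces to its equilibrium at the current
#' ionicity, lowering \code{|Z>} by \code{2*eps_v*rho_bar}) and by the mean
#' ionicity of a partner molecule through the electrostatic coupling \code{V}.
#'
#' @param params A [molecule_params] object.
#' @param V Electrostatic coupling to the partner molecule (eV, any sign).
#' @param rho_partner Mean ionicity of the partner molecule, in \code{[0, 1]}.
#' @param tol Convergence tolerance on \code{|delta rho|} (default 1e-10).
#' @param max_iter Maximum number of damped iterations (default 1e4).
#' @param mixing Damping factor of the fixed-point iteration (default 0.5).
#' @param rho_init Starting guess (default 0.5).
#' @return A list of class \code{ionicity_result} with elements
#'   \code{rho_bar}, \code{iterations} and \code{residual}.
#' @examples
#' nr <- molecule_params(1.76, 0.95, 0.33, 0.14)
#' solve_mean_field_ionicity(nr)$rho_bar
#' @export
solve_mean_field_ionicity <- function(params, V = 0, rho_partner = 0,
                                      tol = 1e-10, max_iter = 1e4,
                                      mixing = 0.5, rho_init = 0.5) {
  stopifnot(inherits(params, "molecule_params"))
  if (rho_partner < 0 || rho_partner > 1)
    stop("'rho_partner' must lie in [0, 1]", call. = FALSE)
  rho <- rho_init
  res <- Inf
  for (it in seq_len(max_iter)) {
    rho_new <- rho_of_gap(effective_gap(params, rho, V, rho_partner), params$tau)
    res <- abs(rho_new - rho)
    rho <- (1 - mixing) * rho + mixing * rho_new
    if (res < tol) {
      return(structure(list(rho_bar = rho, iterations = it, residual = res),
                       class = "ionicity_result"))
    }
  }
  stop(sprintf(
    "mean-field ionicity did not converge in %d iterations (last residual %.3e)",
    max_iter, res), call. = FALSE)
}

#' Joint self-consistent ionicities of an interacting pair
#'
#' Iterates the two molecules' mean-field ionicities to a common fixed point:
#' each molecule's effective gap is renormalized by its own vibrational
#' relaxation and by \code{V} times the partner's current mean ionicity.
#'
#' @param mol1,mol2 [molecule_params] objects.
#' @param V Electrostatic interaction of the doubly zwitterionic state (eV).
#' @param tol,max_iter,mixing Solver controls as in
#'   [solve_mean_field_ionicity()].
#' @return Numeric vector \code{c(rho1, rho2)}.
#' @export
solve_mean_field_pair <- function(mol1, mol2, V, tol = 1e-10, max_iter = 1e4,
                                  mixing = 0.5) {
  r1 <- 0.5; r2 <- 0.5
  for (it in seq_len(max_iter)) {
    r1_new <- rho_of_gap(effective_gap(mol1, r1, V, r2), mol1$tau)
    r2_new <- rho_of_gap(effective_gap(mol2, r2, V, r1), mol2$tau)
    res <- max(abs(r1_new - r1), abs(r2_new - r2))
    r1 <- (1 - mixing) * r1 + mixing * r1_new
    r2 <- (1 - mixing) * r2 + mixing * r2_new
    if (res < tol) return(c(r1, r2))
  }
  stop("pair mean-field ionicities did not converge", call. = FALSE)
}

#' Rotation from the diabatic to the mean-field molecular basis
#'
#' Returns the orthogonal 2x2 matrix whose rows are the mean-field ground
#' \code{|G>} and excited \code{|E>} states expressed on \code{(|N>, |Z>)},
#' with \code{<G|rho_hat|G> = rho_bar}.
#'
#' @param params A [molecule_params] object (unused beyond validation; the
#'   rotation is fixed by \code{rho_bar}).
#' @param rho_bar Mean ionicity in \code{[0, 1]}.
#' @return A 2x2 matrix with rownames \code{c("G", "E")} and colnames
#'   \code{c("N", "Z")}.
#' @export
ge_transform <- function(params, rho_bar) {
  if (rho_bar < 0 || rho_bar > 1)
    stop("'rho_bar' must lie in [0, 1]", call. = FALSE)
  c_g <- sqrt(1 - rho_bar)  # |G> = c_g |N> + s_g |Z>
  s_g <- sqrt(rho_bar)
  m <- rbind(G = c(c_g, s_g), E = c(-s_g, c_g))
  colnames(m) <- c("N", "Z")
  m
}

## (a + a^dagger) on an n_max-dimensional Fock space (n = 0 .. n_max-1)
fock_x <- function(n_max) {
  x <- matrix(0, n_max, n_max)
  if (n_max > 1) {
    for (k in seq_len(n_max - 1)) {
      x[k, k + 1] <- sqrt(k)
      x[k + 1, k] <- sqrt(k)
    }
  }
  x
}

#' Molecular vibronic Hamiltonian on the (electronic x Fock) basis
#'
#' Builds the essential-state Hamiltonian of a single dye on the basis
#' \code{|N> x |n>}, \code{|Z> x |n>} with \code{n = 0 .. n_max - 1}:
#' diabatic gap \code{2z} on the \code{|Z>} block, mixing \code{-tau},
#' harmonic term \code{hbar_omega_v (n + 1/2)}, and linear electron-vibration
#' coupling \code{-sqrt(eps_v hbar_omega_v) (a + a^dagger)} acting on
#' \code{|Z>} only, so that the relaxed \code{|Z>} surface lies \code{eps_v}
#' below its energy at the \code{|N>} equilibrium geometry.
#'
#' @param params A [molecule_params] object.
#' @param n_max Number of Fock states per electronic state (>= 1).
#' @return A symmetric \code{2 n_max x 2 n_max} matrix with a
#'   \code{"basis"} attribute (data frame with columns \code{elec}, \code{n}).
#' @export
monomer_hamiltonian <- function(params, n_max) {
  stopifnot(inherits(params, "molecule_params"), n_max >= 1)
  x <- fock_x(n_max)
  hvib <- diag(params$hbar_omega_v * (seq_len(n_max) - 0.5), n_max)
  kappa <- sqrt(params$eps_v * params$hbar_omega_v)
  h_n <- hvib
  h_z <- hvib + diag(params$gap_2z, n_max) - kappa * x
  h <- rbind(cbind(h_n, diag(-params$tau, n_max)),
             cbind(diag(-params$tau, n_max), h_z))
  attr(h, "basis") <- data.frame(
    elec = rep(c("N", "Z"), each = n_max),
    n = rep.int(seq_len(n_max) - 1L, 2L))
  h
}

#' Vibronic eigenstates of an isolated molecule
#'
#' Diagonalizes [monomer_hamiltonian()] and classifies each eigenstate by its
#' mean-field exciton character: the expectation of \code{|E><E|} (with
#' \code{|E>} from [ge_transform()] at the self-consistent ionicity), rounded
#' to 0 (ground manifold) or 1 (excited manifold).
#'
#' @inheritParams monomer_hamiltonian
#' @return A list of class \code{monomer_eigensystem}: \code{energies}
#'   (ascending, eV), \code{vectors} (columns = eigenstates on the diabatic
#'   basis), \code{rho} (ionicity expectation per state), \code{exciton_weight},
#'   \code{manifold} (\code{"G"} or \code{"E"}), \code{dipole} (transition
#'   dipole matrix \code{mu0 * rho_hat} on the eigenbasis), \code{kasha}
#'   (index of the lowest excited-manifold state), \code{params}, \code{n_max}.
#' @export
monomer_eigensystem <- function(params, n_max = 20) {
  h <- monomer_hamiltonian(params, n_max)
  e <- eigen(h, symmetric = TRUE)
  idx <- order(e$values)
  vals <- e$values[idx]
  vecs <- e$vectors[, idx, drop = FALSE]
  vecs <- fix_eigvec_signs(vecs)

  rho_diag <- c(rep(0, n_max), rep(1, n_max))
  rho_exp <- colSums(vecs^2 * rho_diag)

  rho_bar <- solve_mean_field_ionicity(params)$rho_bar
  ge <- ge_transform(params, rho_bar)
  # |E><E| on the diabatic electronic basis, lifted to the vibronic basis
  e_vec <- ge["E", ]
  w_e <- (e_vec[1] * vecs[seq_len(n_max), , drop = FALSE] +
          e_vec[2] * vecs[n_max + seq_len(n_max), , drop = FALSE])
  exciton_weight <- colSums(w_e^2)
  manifold <- ifelse(round(exciton_weight) >= 1, "E", "G")
  manifold[1] <- "G"

  dip <- params$mu0 * crossprod(vecs, rho_diag * vecs)
  kasha <- which(manifold == "E")[1]
  structure(list(energies = vals, vectors = vecs, rho = rho_exp,
                 exciton_weight = exciton_weight, manifold = manifold,
                 dipole = dip, kasha = kasha, rho_bar = rho_bar,
                 params = params, n_max = n_max),
            class = "monomer_eigensystem")
}

## Deterministic eigenvector sign convention: largest-magnitude coefficient
## of every column is made positive.
fix_eigvec_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    k <- which.max(abs(v[, j]))
    if (v[k, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' Absorption and emission line shapes of the isolated molecule
#'
#' Absorption is computed from the ground vibronic state; emission from the
#' lowest excited-manifold state (the molecular Kasha state). Line shapes are
#' sums of Lorentzians of half-width \code{hbar/damping_a} centred at the
#' vibronic transition energies, weighted by squared transition dipoles, and
#' normalized to unit area on request.
#'
#' @param params A [molecule_params] object.
#' @param n_max Fock states per electronic state (default 20).
#' @param damping_a Damping time of the dipole correlation function (fs);
#'   the Lorentzian half-width at half-maximum is \code{hbar/damping_a}.
#' @param energy_grid Energy grid (eV) for the line shapes.
#' @param normalize Normalize each spectrum to unit area (default TRUE).
#' @return A list with elements \code{absorption} and \code{emission}, both
#'   [spectrum] objects, plus the underlying \code{eigensystem}.
#' @export
monomer_spectra <- function(params, n_max = 20, damping_a = 7,
                            energy_grid = seq(0, 5, by = 0.001),
                            normalize = TRUE) {
  es <- monomer_eigensystem(params, n_max)
  gamma <- .hbar / damping_a
  up <- seq_along(es$energies)[-1]
  abs_pos <- es$energies[up] - es$energies[1]
  abs_w <- es$dipole[up, 1]^2
  k <- es$kasha
  down <- which(es$energies < es$energies[k])
  em_pos <- es$energies[k] - es$energies[down]
  em_w <- es$dipole[down, k]^2
  meta <- list(damping_a = damping_a, n_max = n_max)
  list(absorption = lorentzian_spectrum(abs_pos, abs_w, gamma, energy_grid,
                                        normalize, c(meta, kind = "absorption")),
       emission = lorentzian_spectrum(em_pos, em_w, gamma, energy_grid,
                                      normalize, c(meta, kind = "emission")),
       eigensystem = es)
}
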
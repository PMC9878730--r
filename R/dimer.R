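## Four-diabatic-state dimer on a truncated two-mode vibronic basis.
## Electronic ordering is fixed as |N1 N2>, |Z1 N2>, |N1 Z2>, |Z1 Z2>;
## the vibrational pair basis keeps states with n1 + n2 strictly below the
## truncation threshold M (with M = 14 this gives 4 * 105 = 420 states).

.elec_labels <- c("NN", "ZN", "NZ", "ZZ")
.occ1 <- c(0, 1, 0, 1)  # site-1 zwitterionic occupancy per electronic state
.occ2 <- c(0, 0, 1, 1)

#' Specification of a molecular dimer
#'
#' @param mol1,mol2 [molecule_params] objects for the two sites (site 1 is the
#'   energy donor in RET workflows).
#' @param V Electrostatic interaction of the doubly zwitterionic configuration
#'   \code{|Z1 Z2>} (eV, any sign; V < 0 gives a J-dimer, V > 0 an H-dimer for
#'   parallel permanent dipoles).
#' @param geometry \code{"parallel"} or \code{"antiparallel"} relative
#'   orientation of the molecular permanent dipoles; sets the relative sign of
#'   the two site dipole operators in the dimer dipole moment.
#' @param M Truncation threshold: vibrational pair states with
#'   \code{n1 + n2 < M} are retained (strict inequality).
#' @param hbar_omega_plus,hbar_omega_minus Optional frequencies (eV) of the
#'   symmetrized modes \code{Q+ = (Q1+Q2)/sqrt(2)}, \code{Q- = (Q1-Q2)/sqrt(2)}.
#'   Supplying both switches the construction to the symmetrized-mode
#'   representation (used for homodimers, where slightly different values such
#'   as 0.15/0.13 eV lift exact degeneracies without breaking the electronic
#'   symmetry); requires the two sites to share \code{eps_v} and
#'   \code{hbar_omega_v}. The electron-vibration coupling constant is rescaled
#'   so the site vibrational relaxation energy stays equal to \code{eps_v}.
#' @return An object of class \code{dimer_spec}.
#' @export
dimer_spec <- function(mol1, mol2, V, geometry = c("parallel", "antiparallel"),
                       M = 14, hbar_omega_plus = NULL, hbar_omega_minus = NULL) {
  stopifnot(inherits(mol1, "molecule_params"), inherits(mol2, "molecule_params"))
  geometry <- match.arg(geometry)
  if (!(is.numeric(M) && length(M) == 1L && M >= 1))
    stop("'M' must be a single integer >= 1", call. = FALSE)
  sym <- !is.null(hbar_omega_plus) || !is.null(hbar_omega_minus)
  if (sym) {
    if (is.null(hbar_omega_plus) || is.null(hbar_omega_minus) ||
        hbar_omega_plus <= 0 || hbar_omega_minus <= 0)
      stop("both symmetrized-mode frequencies must be supplied and positive",
           call. = FALSE)
    if (mol1$hbar_omega_v != mol2$hbar_omega_v || mol1$eps_v != mol2$eps_v)
      stop(paste("symmetrized modes require the two sites to share the",
                 "vibrational parameters (eps_v, hbar_omega_v)"), call. = FALSE)
  }
  structure(list(mol1 = mol1, mol2 = mol2, V = V, geometry = geometry,
                 M = as.integer(M),
                 representation = if (sym) "sym" else "site",
                 hbar_omega_plus = hbar_omega_plus,
                 hbar_omega_minus = hbar_omega_minus),
            class = "dimer_spec")
}

#' @export
print.dimer_spec <- function(x, ...) {
  cat(sprintf("<dimer_spec> V = %g eV, %s geometry, M = %d (%d states), %s modes\n",
              x$V, x$geometry, x$M, 4 * x$M * (x$M + 1) / 2,
              if (x$representation == "sym") "symmetrized (Q+,Q-)" else "site"))
  invisible(x)
}

#' Enumerate the truncated vibronic basis of the dimer
#'
#' Complete enumeration of the 4 electronic states times all vibrational pairs
#' with \code{n1 + n2 < M}, ordered electronic-major and then lexicographically
#' in the quanta. In the symmetrized representation the two quantum numbers
#' refer to the \code{Q+} and \code{Q-} modes.
#'
#' @param spec A [dimer_spec] object.
#' @return A data frame with columns \code{elec}, \code{n1}, \code{n2} and an
#'   attribute \code{"representation"} (\code{"site"} or \code{"sym"}).
#' @export
build_basis <- function(spec) {
  stopifnot(inherits(spec, "dimer_spec"))
  pairs <- pair_basis(spec$M)
  basis <- data.frame(
    elec = rep(.elec_labels, each = nrow(pairs)),
    n1 = rep.int(pairs$n1, 4L),
    n2 = rep.int(pairs$n2, 4L))
  attr(basis, "representation") <- spec$representation
  basis
}

pair_basis <- function(M) {
  n1 <- unlist(lapply(0:(M - 1), function(k) rep.int(k, M - k)))
  n2 <- unlist(lapply(0:(M - 1), function(k) 0:(M - 1 - k)))
  data.frame(n1 = n1, n2 = n2)
}

## Ladder-operator combinations on the truncated pair-Fock space:
## X_i = a_i + a_i^dagger, projected on n1 + n2 < M.
pair_ops <- function(M) {
  pb <- pair_basis(M)
  P <- nrow(pb)
  idx <- matrix(NA_integer_, M, M)
  idx[cbind(pb$n1 + 1L, pb$n2 + 1L)] <- seq_len(P)
  X1 <- matrix(0, P, P)
  X2 <- matrix(0, P, P)
  for (r in seq_len(P)) {
    n1 <- pb$n1[r]; n2 <- pb$n2[r]
    if (n1 > 0) {                      # a1 |n1> = sqrt(n1) |n1 - 1>
      s <- idx[n1, n2 + 1L]
      X1[s, r] <- X1[r, s] <- sqrt(n1)
    }
    if (n2 > 0) {
      s <- idx[n1 + 1L, n2]
      X2[s, r] <- X2[r, s] <- sqrt(n2)
    }
  }
  list(basis = pb, X1 = X1, X2 = X2, P = P)
}

## Site electron-vibration coupling operators (matrices on the pair-Fock
## space) and harmonic diagonal, for either representation. The coupling
## convention keeps the site relaxation energy equal to eps_v: with distinct
## symmetrized frequencies the constant uses their harmonic mean.
dimer_vib_parts <- function(spec) {
  ops <- pair_ops(spec$M)
  if (spec$representation == "site") {
    hw1 <- spec$mol1$hbar_omega_v; hw2 <- spec$mol2$hbar_omega_v
    hvib <- hw1 * (ops$basis$n1 + 0.5) + hw2 * (ops$basis$n2 + 0.5)
    c1 <- -sqrt(spec$mol1$eps_v * hw1) * ops$X1
    c2 <- -sqrt(spec$mol2$eps_v * hw2) * ops$X2
  } else {
    hwp <- spec$hbar_omega_plus; hwm <- spec$hbar_omega_minus
    eps <- spec$mol1$eps_v
    hvib <- hwp * (ops$basis$n1 + 0.5) + hwm * (ops$basis$n2 + 0.5)
    kappa <- sqrt(4 * eps * hwp * hwm / (hwp + hwm))
    c1 <- -(kappa / 2) * (ops$X1 + ops$X2)
    c2 <- -(kappa / 2) * (ops$X1 - ops$X2)
  }
  list(ops = ops, hvib = hvib, c1 = c1, c2 = c2)
}

#' Build the dimer Hamiltonian on the truncated vibronic basis
#'
#' The Hamiltonian is the sum of the two molecular Hamiltonians plus \code{V}
#' added to every diagonal element whose electronic label is \code{ZZ}. In the
#' symmetrized representation the vibrational part is written on the
#' \code{(Q+, Q-)} oscillators with their own frequencies.
#'
#' @param spec A [dimer_spec] object.
#' @return A symmetric matrix of dimension \code{4 M (M+1) / 2} with the
#'   [build_basis()] data frame attached as attribute \code{"basis"}.
#' @export
build_dimer_hamiltonian <- function(spec) {
  stopifnot(inherits(spec, "dimer_spec"))
  vp <- dimer_vib_parts(spec)
  P <- vp$ops$P
  H <- matrix(0, 4 * P, 4 * P)
  blk <- function(e) ((e - 1) * P + 1):(e * P)
  for (e in 1:4) {
    d <- .occ1[e] * spec$mol1$gap_2z + .occ2[e] * spec$mol2$gap_2z +
      if (e == 4) spec$V else 0
    H[blk(e), blk(e)] <- diag(d + vp$hvib, P) +
      .occ1[e] * vp$c1 + .occ2[e] * vp$c2
  }
  t1 <- diag(-spec$mol1$tau, P)
  t2 <- diag(-spec$mol2$tau, P)
  H[blk(1), blk(2)] <- t1; H[blk(2), blk(1)] <- t1  # NN <-> ZN
  H[blk(3), blk(4)] <- t1; H[blk(4), blk(3)] <- t1  # NZ <-> ZZ
  H[blk(1), blk(3)] <- t2; H[blk(3), blk(1)] <- t2  # NN <-> NZ
  H[blk(2), blk(4)] <- t2; H[blk(4), blk(2)] <- t2  # ZN <-> ZZ
  attr(H, "basis") <- build_basis(spec)
  H
}

#' Symmetrized vibrational coordinate operators of the dimer
#'
#' Returns the dimensionless coordinate operators \code{Q+} and \code{Q-} on
#' the full truncated basis. In the symmetrized representation they are the
#' native mode coordinates; in the site representation they are built as
#' \code{(Q1 +/- Q2)/sqrt(2)}.
#'
#' @param spec A [dimer_spec] object.
#' @return A list with matrices \code{Q_plus}, \code{Q_minus}, \code{Q1},
#'   \code{Q2} (site coordinates; in the symmetrized representation these are
#'   the inverse combinations of the mode coordinates).
#' @export
dimer_coordinate_ops <- function(spec) {
  ops <- pair_ops(spec$M)
  I4 <- diag(4)
  qa <- kronecker(I4, ops$X1 / sqrt(2))
  qb <- kronecker(I4, ops$X2 / sqrt(2))
  if (spec$representation == "site") {
    list(Q_plus = (qa + qb) / sqrt(2), Q_minus = (qa - qb) / sqrt(2),
         Q1 = qa, Q2 = qb)
  } else {
    list(Q_plus = qa, Q_minus = qb,
         Q1 = (qa + qb) / sqrt(2), Q2 = (qa - qb) / sqrt(2))
  }
}

#' Dimer dipole moment operator
#'
#' \code{mu = mu_1 +/- mu_2}, each site dipole acting as \code{mu0_i} times
#' the site ionicity operator; the sign of the second term is set by the
#' geometry (\code{+} parallel, \code{-} antiparallel).
#'
#' @param spec A [dimer_spec] object.
#' @param site \code{"total"} (default), \code{"site1"}, or \code{"site2"} to
#'   obtain the full dimer dipole or a single-site dipole (used for donor-only
#'   excitation).
#' @return A diagonal-matrix representation (numeric matrix) on the truncated
#'   basis.
#' @export
dipole_operator <- function(spec, site = c("total", "site1", "site2")) {
  site <- match.arg(site)
  P <- spec$M * (spec$M + 1) / 2
  sgn <- if (spec$geometry == "parallel") 1 else -1
  d1 <- spec$mol1$mu0 * .occ1
  d2 <- spec$mol2$mu0 * .occ2
  dvals <- switch(site,
    total = d1 + sgn * d2,
    site1 = d1,
    site2 = sgn * d2)
  diag(rep(dvals, each = P))
}

## Site exciton projectors |E_i><E_i| lifted to the 4-state electronic space,
## plus the projectors on the lower/upper one-exciton electronic eigenstates
## (the electronic S1 and S2 states: the one-exciton block of the mean-field
## Hamiltonian, with diagonal transition energies and off-diagonal exciton
## coupling J, split by 2J), all at the joint mean-field ionicities.
exciton_projectors <- function(spec) {
  rho <- solve_mean_field_pair(spec$mol1, spec$mol2, spec$V)
  lift <- function(evec, site) {
    # evec = coefficients of |E> on (|N>, |Z>) for this site
    m <- matrix(0, 4, 4)
    occ <- if (site == 1) .occ1 else .occ2
    other <- if (site == 1) .occ2 else .occ1
    for (e in 1:4) for (f in 1:4) {
      if (other[e] == other[f]) {
        m[e, f] <- evec[occ[e] + 1] * evec[occ[f] + 1]
      }
    }
    m
  }
  ge1 <- ge_transform(spec$mol1, rho[1])
  ge2 <- ge_transform(spec$mol2, rho[2])
  ## product electronic states |E1 G2> and |G1 E2> on (NN, ZN, NZ, ZZ)
  prod_state <- function(v1, v2)
    vapply(1:4, function(e) v1[.occ1[e] + 1] * v2[.occ2[e] + 1], numeric(1))
  v_eg <- prod_state(ge1["E", ], ge2["G", ])
  v_ge <- prod_state(ge1["G", ], ge2["E", ])
  gap1 <- effective_gap(spec$mol1, rho[1], spec$V, rho[2])
  gap2 <- effective_gap(spec$mol2, rho[2], spec$V, rho[1])
  omega1 <- sqrt(gap1^2 + 4 * spec$mol1$tau^2)
  omega2 <- sqrt(gap2^2 + 4 * spec$mol2$tau^2)
  j_mf <- spec$V * sqrt(rho[1] * (1 - rho[1]) * rho[2] * (1 - rho[2]))
  h1 <- matrix(c(omega1, j_mf, j_mf, omega2), 2, 2)
  e1x <- eigen(h1, symmetric = TRUE)
  lo <- e1x$vectors[, which.min(e1x$values)]
  hi <- e1x$vectors[, which.max(e1x$values)]
  psi_s1 <- lo[1] * v_eg + lo[2] * v_ge
  psi_s2 <- hi[1] * v_eg + hi[2] * v_ge
  list(P1 = lift(ge1["E", ], 1), P2 = lift(ge2["E", ], 2),
       PS1 = outer(psi_s1, psi_s1), PS2 = outer(psi_s2, psi_s2), rho = rho)
}

#' Diagonalize the dimer Hamiltonian and label the eigenstates
#'
#' Produces the numerically exact vibronic eigensystem: ascending eigenvalues,
#' eigenvectors with a deterministic sign convention, manifold labels obtained
#' by rounding the expectation of the total mean-field exciton number
#' (\code{G}, \code{S1}, \code{S2}, \code{higher}), transition-dipole matrices
#' (total and per site) on the eigenbasis, the eigenbasis representation of
#' the symmetrized coordinates, and per-site excitation weights used to
#' apportion populations between the two molecules.
#'
#' @param spec A [dimer_spec] object.
#' @return An object of class \code{vibronic_eigensystem} with elements
#'   \code{energies}, \code{vectors}, \code{basis}, \code{manifold},
#'   \code{exciton_number}, \code{w1}, \code{w2}, \code{dipole}, \code{dipole1},
#'   \code{dipole2}, \code{Q_plus}, \code{Q_minus}, \code{Q_minus_sq},
#'   \code{kasha} (index of the lowest S1 state), \code{s2_lowest},
#'   \code{rho_pair}, \code{spec}.
#' @export
dimer_eigensystem <- function(spec) {
  H <- build_dimer_hamiltonian(spec)
  e <- eigen(H, symmetric = TRUE)
  idx <- order(e$values)
  vals <- e$values[idx]
  vecs <- fix_eigvec_signs(e$vectors[, idx, drop = FALSE])

  proj <- exciton_projectors(spec)
  P <- nrow(H) / 4
  lift_full <- function(m4) kronecker(m4, diag(P))
  W1 <- lift_full(proj$P1)
  W2 <- lift_full(proj$P2)
  w1 <- colSums(vecs * (W1 %*% vecs))
  w2 <- colSums(vecs * (W2 %*% vecs))
  exciton_number <- w1 + w2
  ## manifold bookkeeping: G for ~0 excitons, "higher" for ~2 (or more);
  ## one-exciton states are split into S1/S2 by their dominant weight on the
  ## lower/upper one-exciton electronic eigenstate (split by 2J).
  ws1 <- colSums(vecs * (lift_full(proj$PS1) %*% vecs))
  ws2 <- colSums(vecs * (lift_full(proj$PS2) %*% vecs))
  nexc <- pmin(pmax(round(exciton_number), 0), 2)
  nexc[1] <- 0
  manifold <- ifelse(nexc == 0, "G",
                     ifelse(nexc >= 2, "higher",
                            ifelse(ws1 >= ws2, "S1", "S2")))

  to_eig <- function(op) crossprod(vecs, op %*% vecs)
  qops <- dimer_coordinate_ops(spec)
  qp <- to_eig(qops$Q_plus)
  qm <- to_eig(qops$Q_minus)
  mu <- to_eig(dipole_operator(spec, "total"))
  mu1 <- to_eig(dipole_operator(spec, "site1"))
  mu2 <- to_eig(dipole_operator(spec, "site2"))

  structure(list(
    energies = vals, vectors = vecs, basis = attr(H, "basis"),
    manifold = manifold, exciton_number = exciton_number, w1 = w1, w2 = w2,
    dipole = mu, dipole1 = mu1, dipole2 = mu2,
    Q_plus = qp, Q_minus = qm, Q_minus_sq = qm %*% qm,
    kasha = which(manifold == "S1")[1],
    s2_lowest = which(manifold == "S2")[1],
    rho_pair = proj$rho, spec = spec),
    class = "vibronic_eigensystem")
}

#' @export
print.vibronic_eigensystem <- function(x, ...) {
  cat(sprintf("<vibronic_eigensystem> %d states, E in [%.4f, %.4f] eV\n",
              length(x$energies), min(x$energies), max(x$energies)))
  cat(sprintf("  manifolds: %s\n",
              paste(sprintf("%s:%d", names(table(x$manifold)),
                            as.integer(table(x$manifold))), collapse = "  ")))
  invisible(x)
}

#' Exciton-model parameters of the dimer
#'
#' Maps the diabatic model onto the exciton picture: the exciton hopping
#' integral is \code{J = V sqrt(rho1 (1 - rho1)) sqrt(rho2 (1 - rho2))}
#' (reducing to \code{V rho (1 - rho)} for a homodimer), with the
#' isolated-molecule self-consistent ionicities by default. The mean-field
#' transition energies are the \code{|G> -> |E>} gaps at the jointly
#' self-consistent ionicities.
#'
#' @param spec A [dimer_spec] object.
#' @param coupled Use the V-coupled, jointly self-consistent ionicities for J
#'   instead of the isolated-molecule values (default FALSE).
#' @return A list with \code{J} (eV), \code{rho} (the ionicities used for J),
#'   \code{transition_energies} (eV, length 2).
#' @export
exciton_parameters <- function(spec, coupled = FALSE) {
  rho_pair <- solve_mean_field_pair(spec$mol1, spec$mol2, spec$V)
  rho_j <- if (coupled) rho_pair else
    c(solve_mean_field_ionicity(spec$mol1)$rho_bar,
      solve_mean_field_ionicity(spec$mol2)$rho_bar)
  J <- spec$V * sqrt(rho_j[1] * (1 - rho_j[1])) * sqrt(rho_j[2] * (1 - rho_j[2]))
  gap1 <- effective_gap(spec$mol1, rho_pair[1], spec$V, rho_pair[2])
  gap2 <- effective_gap(spec$mol2, rho_pair[2], spec$V, rho_pair[1])
  list(J = J, rho = rho_j,
       transition_energies = c(sqrt(gap1^2 + 4 * spec$mol1$tau^2),
                               sqrt(gap2^2 + 4 * spec$mol2$tau^2)))
}

#' Adiabatic potential energy surfaces on a classical coordinate grid
#'
#' Treats the vibrational coordinates as classical numbers: at each grid point
#' the 4x4 electronic Hamiltonian (with the linear couplings evaluated at the
#' classical coordinates) is diagonalized and the harmonic elastic energy
#' added, giving the adiabatic surfaces S0..S3.
#'
#' @param spec A [dimer_spec] object.
#' @param q_plus,q_minus Numeric grids for the symmetrized classical
#'   coordinates.
#' @return A long-format data frame with columns \code{Q_plus},
#'   \code{Q_minus}, \code{S0}, \code{S1}, \code{S2}, \code{S3}.
#' @export
adiabatic_pes <- function(spec, q_plus = seq(-2, 6, by = 0.1),
                          q_minus = seq(-4, 4, by = 0.1)) {
  stopifnot(length(q_plus) >= 1, length(q_minus) >= 1)
  if (spec$representation == "sym") {
    hwp <- spec$hbar_omega_plus; hwm <- spec$hbar_omega_minus
    kappa <- sqrt(4 * spec$mol1$eps_v * hwp * hwm / (hwp + hwm))
    coup <- function(qp, qm) c(-(kappa / sqrt(2)) * (qp + qm),
                               -(kappa / sqrt(2)) * (qp - qm))
    elastic <- function(qp, qm) 0.5 * hwp * qp^2 + 0.5 * hwm * qm^2
  } else {
    k1 <- sqrt(2 * spec$mol1$eps_v * spec$mol1$hbar_omega_v)
    k2 <- sqrt(2 * spec$mol2$eps_v * spec$mol2$hbar_omega_v)
    coup <- function(qp, qm) {
      q1 <- (qp + qm) / sqrt(2); q2 <- (qp - qm) / sqrt(2)
      c(-k1 * q1, -k2 * q2)
    }
    elastic <- function(qp, qm) {
      q1 <- (qp + qm) / sqrt(2); q2 <- (qp - qm) / sqrt(2)
      0.5 * spec$mol1$hbar_omega_v * q1^2 + 0.5 * spec$mol2$hbar_omega_v * q2^2
    }
  }
  grid <- expand.grid(Q_plus = q_plus, Q_minus = q_minus,
                      KEEP.OUT.ATTRS = FALSE)
  surf <- matrix(0, nrow(grid), 4)
  h <- matrix(0, 4, 4)
  h[1, 2] <- h[2, 1] <- h[3, 4] <- h[4, 3] <- -spec$mol1$tau
  h[1, 3] <- h[3, 1] <- h[2, 4] <- h[4, 2] <- -spec$mol2$tau
  for (i in seq_len(nrow(grid))) {
    qp <- grid$Q_plus[i]; qm <- grid$Q_minus[i]
    cc <- coup(qp, qm)
    diag(h) <- .occ1 * (spec$mol1$gap_2z + cc[1]) +
      .occ2 * (spec$mol2$gap_2z + cc[2]) + c(0, 0, 0, spec$V) +
      elastic(qp, qm)
    surf[i, ] <- sort(eigen(h, symmetric = TRUE, only.values = TRUE)$values)
  }
  colnames(surf) <- paste0("S", 0:3)
  cbind(grid, as.data.frame(surf))
}
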
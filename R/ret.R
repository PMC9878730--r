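## RET workflows: donor-only excitation dynamics, exponential rate fits,
## Forster rates from spectral overlaps of isolated-molecule line shapes, and
## resonance / asymmetry scans.
##
## Forster convention used throughout: golden rule k = (2 pi / hbar) J_DA^2 S
## with J_DA = V sqrt(rho_D (1 - rho_D)) sqrt(rho_A (1 - rho_A)) and S the
## overlap of the unit-area donor emission and acceptor absorption line
## shapes, supplying the density of states. The overlap spectra are broadened
## by default with a damping time 1/gamma (the bath relaxation time), so the
## Lorentzian half-width matches the bath-induced level widths that control
## the dynamical rates; the comparison of Forster and dynamical rates is
## always made under this single documented convention.

#' Spectral overlap of donor emission and acceptor absorption
#'
#' \code{S = integral f_D(nu) a_A(nu) d nu} over the wavenumber axis, with
#' both line shapes normalized to unit area. Spectra on different grids are
#' linearly interpolated onto their common range.
#'
#' @param donor_emission,acceptor_absorption [spectrum] objects.
#' @param n_grid Number of quadrature points on the common range.
#' @return Overlap integral in cm.
#' @export
spectral_overlap <- function(donor_emission, acceptor_absorption,
                             n_grid = 20000) {
  for (s in list(donor_emission, acceptor_absorption)) {
    if (!isTRUE(attr(s, "normalized")))
      stop("overlap requires unit-area spectra (see normalize_spectrum)",
           call. = FALSE)
  }
  lo <- max(min(donor_emission$wavenumber_cm),
            min(acceptor_absorption$wavenumber_cm))
  hi <- min(max(donor_emission$wavenumber_cm),
            max(acceptor_absorption$wavenumber_cm))
  if (hi <= lo) return(0)
  grid <- seq(lo, hi, length.out = n_grid)
  fd <- approx(donor_emission$wavenumber_cm, donor_emission$intensity / .evcm,
               grid, rule = 2)$y
  fa <- approx(acceptor_absorption$wavenumber_cm,
               acceptor_absorption$intensity / .evcm, grid, rule = 2)$y
  trapz(grid, fd * fa)
}

#' Forster RET rate of a donor-acceptor pair
#'
#' Golden-rule rate \code{k = (2 pi / hbar) J_DA^2 S}, with the electrostatic
#' coupling between the transition dipoles
#' \code{J_DA = V sqrt(rho_D (1 - rho_D) rho_A (1 - rho_A))} (isolated-molecule
#' self-consistent ionicities) and the spectral overlap \code{S} supplying the
#' density of states.
#'
#' @param V Electrostatic interaction of the doubly zwitterionic state (eV).
#' @param donor,acceptor [molecule_params] objects.
#' @param overlap_cm Optional precomputed overlap (cm); when NULL it is
#'   computed from the isolated-molecule emission/absorption line shapes.
#' @param damping_a Damping time for the overlap line shapes (fs); default 7,
#'   the same damping used for every other spectrum, so that
#'   Forster-vs-dynamical comparisons are made under one spectral convention.
#'   The absolute Forster scale depends on this convention (see the methods
#'   vignette); ratios and scalings do not.
#' @param n_max Fock truncation of the monomer eigensystems.
#' @return A list with \code{rate_ps} (ps^-1), \code{J_DA} (eV),
#'   \code{overlap_cm} (cm), \code{rho_donor}, \code{rho_acceptor}.
#' @export
forster_rate <- function(V, donor, acceptor, overlap_cm = NULL,
                         damping_a = 7, n_max = 20) {
  rho_d <- solve_mean_field_ionicity(donor)$rho_bar
  rho_a <- solve_mean_field_ionicity(acceptor)$rho_bar
  if (is.null(overlap_cm)) {
    em <- monomer_spectra(donor, n_max = n_max, damping_a = damping_a)$emission
    ab <- monomer_spectra(acceptor, n_max = n_max,
                          damping_a = damping_a)$absorption
    overlap_cm <- spectral_overlap(em, ab)
  }
  j_da <- V * sqrt(rho_d * (1 - rho_d)) * sqrt(rho_a * (1 - rho_a))
  overlap_ev <- overlap_cm * .evcm          # density of states per eV
  rate_fs <- 2 * pi / .hbar * j_da^2 * overlap_ev
  list(rate_ps = rate_fs * 1000, J_DA = j_da, overlap_cm = overlap_cm,
       rho_donor = rho_d, rho_acceptor = rho_a)
}

#' Donor-only excitation dynamics of a RET pair
#'
#' Convenience pipeline: diagonalize the dimer, excite only the energy donor
#' (site 1) impulsively, and propagate under the secular Redfield equation.
#'
#' @param spec A [dimer_spec] with the donor as \code{mol1}.
#' @param bath A [bath_spec()].
#' @param times Output time grid (fs).
#' @param threshold Initial-population threshold of the active space.
#' @param eig Optional precomputed [dimer_eigensystem()] for \code{spec}.
#' @return A [propagate()] trajectory.
#' @export
simulate_ret <- function(spec, bath = bath_spec(), times = seq(0, 1e4, 20),
                         threshold = 1e-6, eig = NULL) {
  if (is.null(eig)) eig <- dimer_eigensystem(spec)
  rates <- redfield_rates(eig, bath)
  sigma0 <- initial_state_impulsive(eig, dipole = "site1",
                                    threshold = threshold)
  propagate(sigma0, rates, eig, times = times)
}

#' Fit a RET rate to the acceptor-excitation population
#'
#' Least-squares fit of the saturating exponential
#' \code{P(t) = P_inf (1 - exp(-k (t - t0)))} to the population of
#' acceptor-localized excitation, with \code{t0} fixed at the start of the fit
#' window (after the vibrational-relaxation transient).
#'
#' @param traj A [propagate()] trajectory from donor-only excitation.
#' @param observable Column of the trajectory observables holding the acceptor
#'   excitation population. The default \code{"p_m2_share"} (excitation share
#'   of molecule 2 among excited states) removes the slow common-mode leakage
#'   toward the ground manifold from the fit; use \code{"p_m2"} for the raw
#'   apportioned population.
#' @param t_min Start of the fit window (fs, default 500).
#' @param goodness_threshold R-squared below which the fit is flagged
#'   unreliable (default 0.9).
#' @return A list of class \code{ret_result}: \code{fitted_rate_ps} (ps^-1),
#'   \code{p_inf}, \code{fit_window_fs}, \code{goodness} (R^2),
#'   \code{reliable}.
#' @export
fit_ret_rate <- function(traj, observable = "p_m2_share", t_min = 500,
                         goodness_threshold = 0.9) {
  obs <- trajectory_observables(traj)
  stopifnot(observable %in% names(obs))
  sel <- obs$time_fs >= t_min
  if (sum(sel) < 5) stop("fit window contains fewer than 5 points",
                         call. = FALSE)
  tt <- obs$time_fs[sel] - t_min
  pp <- obs[[observable]][sel] - obs[[observable]][sel][1]
  p_inf0 <- max(pp[length(pp)], 1e-6)
  ## crude rate guess from the half-rise time
  i_half <- which(pp >= p_inf0 / 2)[1]
  k0 <- if (is.na(i_half) || tt[i_half] <= 0) 1e-4 else log(2) / tt[i_half]
  fit <- try(minpack.lm::nlsLM(
    pp ~ p_inf * (1 - exp(-k * tt)),
    start = list(p_inf = p_inf0, k = k0),
    lower = c(0, 0), upper = c(1, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("exponential fit failed: ", attr(fit, "condition")$message,
         call. = FALSE)
  cf <- coef(fit)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((pp - mean(pp))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(fitted_rate_ps = unname(cf["k"]) * 1000,
                 p_inf = unname(cf["p_inf"]),
                 fit_window_fs = c(t_min, max(obs$time_fs)),
                 goodness = r2,
                 reliable = r2 >= goodness_threshold),
            class = "ret_result")
}

#' @export
print.ret_result <- function(x, ...) {
  cat(sprintf("<ret_result> k = %.4g ps^-1 (P_inf = %.3f, R^2 = %.4f%s)\n",
              x$fitted_rate_ps, x$p_inf, x$goodness,
              if (x$reliable) "" else ", UNRELIABLE"))
  invisible(x)
}

#' Vibronic resonance scan of the RET rate
#'
#' Varies the acceptor diabatic gap (emulating e.g. a local electric field)
#' and, for each value, reports the donor Kasha-state energy, the
#' acceptor-manifold vibronic energies, and the dynamical RET rate fitted
#' from a donor-only-excitation trajectory. Rate maxima co-locate with
#' crossings between the donor Kasha state and acceptor vibronic levels.
#'
#' @param acceptor_gap_values Values of the acceptor \code{2z} gap (eV).
#' @param donor,acceptor Base [molecule_params] (acceptor gap overridden).
#' @param V Electrostatic coupling (eV, weak-coupling regime; default 0.03).
#' @param M Basis truncation for the scan dimers.
#' @param bath A [bath_spec()].
#' @param times Trajectory time grid (fs).
#' @param t_min Fit-window start (fs).
#' @param n_acceptor_levels How many acceptor vibronic energies to report.
#' @return A data frame with one row per gap value: \code{gap_2z},
#'   \code{rate_ps}, \code{goodness}, \code{donor_kasha_ev}, and
#'   \code{acceptor_level_<k>_ev} columns (energies relative to the monomer
#'   ground state).
#' @export
scan_resonance <- function(acceptor_gap_values, donor, acceptor, V = 0.03,
                           M = 10, bath = bath_spec(),
                           times = seq(0, 2e4, 50), t_min = 500,
                           n_acceptor_levels = 5) {
  rows <- lapply(acceptor_gap_values, function(gap) {
    acc <- acceptor
    acc$gap_2z <- gap
    d_es <- monomer_eigensystem(donor, n_max = max(M + 4, 12))
    a_es <- monomer_eigensystem(acc, n_max = max(M + 4, 12))
    donor_kasha <- d_es$energies[d_es$kasha] - d_es$energies[1]
    acc_exc <- which(a_es$manifold == "E")[seq_len(n_acceptor_levels)]
    acc_levels <- a_es$energies[acc_exc] - a_es$energies[1]
    spec <- dimer_spec(donor, acc, V = V, M = M)
    traj <- simulate_ret(spec, bath = bath, times = times)
    fit <- fit_ret_rate(traj, t_min = t_min)
    out <- data.frame(gap_2z = gap, rate_ps = fit$fitted_rate_ps,
                      goodness = fit$goodness, donor_kasha_ev = donor_kasha)
    for (k in seq_along(acc_levels))
      out[[sprintf("acceptor_level_%d_ev", k)]] <- acc_levels[k]
    out
  })
  do.call(rbind, rows)
}

#' Asymmetry scan across the exciton-to-RET crossover
#'
#' Starting from a homodimer, assigns molecule 2 a larger diabatic gap,
#' \code{z2 = z1 + delta_z12}, and follows the population of excitation on
#' molecule 1, \code{P_M1*}, after impulsive excitation, for each combination
#' of asymmetry and coupling. At zero asymmetry and strong coupling the
#' excitation stays delocalized (\code{P_M1* ~ 0.5}); at large asymmetry it
#' localizes on the lower-gap molecule (site 1), regardless of the sign of V.
#'
#' @param delta_z12_values Gap asymmetries \code{z2 - z1} (eV).
#' @param V_values Couplings to scan (eV).
#' @param base [molecule_params] of the reference (site 1) molecule.
#' @param M Basis truncation.
#' @param bath A [bath_spec()].
#' @param times Trajectory time grid (fs).
#' @param hbar_omega_plus,hbar_omega_minus Symmetrized-mode frequencies used
#'   to lift the homodimer degeneracies (defaults 0.15 / 0.13 eV).
#' @param dipole Excitation scheme passed to [initial_state_impulsive()].
#' @return A data frame with columns \code{delta_z12}, \code{V},
#'   \code{time_fs}, \code{p_m1}, \code{p_m2}, \code{pop_G}.
#' @export
scan_asymmetry <- function(delta_z12_values, V_values, base, M = 8,
                           bath = bath_spec(), times = seq(0, 2e4, 50),
                           hbar_omega_plus = 0.15, hbar_omega_minus = 0.13,
                           dipole = "total") {
  combos <- expand.grid(delta_z12 = delta_z12_values, V = V_values,
                        KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    dz <- combos$delta_z12[i]; V <- combos$V[i]
    mol2 <- base
    mol2$gap_2z <- base$gap_2z + 2 * dz   # delta_z12 = z2 - z1
    spec <- dimer_spec(base, mol2, V = V, M = M,
                       hbar_omega_plus = hbar_omega_plus,
                       hbar_omega_minus = hbar_omega_minus)
    eig <- dimer_eigensystem(spec)
    rates <- redfield_rates(eig, bath)
    sigma0 <- initial_state_impulsive(eig, dipole = dipole)
    traj <- propagate(sigma0, rates, eig, times = times)
    obs <- trajectory_observables(traj)
    data.frame(delta_z12 = dz, V = V, time_fs = obs$time_fs,
               p_m1 = obs$p_m1, p_m2 = obs$p_m2, pop_G = obs$pop_G)
  })
  do.call(rbind, rows)
}
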
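## Optical spectra from damped dipole-dipole correlation functions. For a
## time-independent Hamiltonian the real-part Fourier transform of
## C(t) = Tr{mu Omega(t)} exp(-t/a) is exactly a sum of Lorentzians of
## half-width hbar/a at the transition energies, so the closed sum-over-states
## form is the default; a direct time-domain quadrature of the damped
## correlation function is kept as an independent cross-check path.

#' Construct a spectrum object
#'
#' @param energy_ev Energy grid (eV).
#' @param intensity Non-negative intensities on the grid.
#' @param normalized Logical; whether the spectrum is normalized to unit area.
#' @param meta Named list of metadata (damping, kind, delay time, ...).
#' @return A data frame of class \code{spectrum} with columns
#'   \code{energy_ev}, \code{wavenumber_cm}, \code{intensity}.
#' @export
spectrum <- function(energy_ev, intensity, normalized = FALSE, meta = list()) {
  stopifnot(length(energy_ev) == length(intensity))
  s <- data.frame(energy_ev = energy_ev,
                  wavenumber_cm = energy_ev * .evcm,
                  intensity = intensity)
  class(s) <- c("spectrum", "data.frame")
  attr(s, "normalized") <- normalized
  attr(s, "meta") <- meta
  s
}

#' @export
print.spectrum <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("<spectrum>", if (!is.null(meta$kind)) meta$kind else "",
      sprintf("grid %g..%g eV (%d points), area %.6g%s\n",
              min(x$energy_ev), max(x$energy_ev), nrow(x), spectrum_area(x),
              if (isTRUE(attr(x, "normalized"))) ", unit-area" else ""))
  invisible(x)
}

#' Trapezoidal area of a spectrum over its full grid
#' @param spec A [spectrum] object.
#' @return Numeric area (intensity times eV).
#' @export
spectrum_area <- function(spec) {
  trapz(spec$energy_ev, spec$intensity)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Normalize a spectrum to unit area
#' @param spec A [spectrum] object.
#' @return The spectrum rescaled to unit trapezoidal area on its energy grid.
#' @export
normalize_spectrum <- function(spec) {
  a <- spectrum_area(spec)
  if (a <= 0) stop("cannot normalize a spectrum with non-positive area",
                   call. = FALSE)
  spec$intensity <- spec$intensity / a
  attr(spec, "normalized") <- TRUE
  spec
}

## Sum of unit-area Lorentzians (gamma = HWHM in eV) at `positions` with
## `weights`; negative round-off intensities are clipped at zero.
lorentzian_spectrum <- function(positions, weights, gamma, energy_grid,
                                normalize = TRUE, meta = list()) {
  keep <- which(abs(weights) > 0 & positions > 0)
  intensity <- numeric(length(energy_grid))
  for (i in keep) {
    intensity <- intensity +
      weights[i] * (gamma / pi) / ((energy_grid - positions[i])^2 + gamma^2)
  }
  intensity[intensity < 0] <- 0
  s <- spectrum(energy_grid, intensity, normalized = FALSE, meta = meta)
  if (normalize) s <- normalize_spectrum(s)
  s
}

#' Steady-state absorption spectrum of the dimer
#'
#' The absorption generating function is \code{mu |phi_1><phi_1|}; its unitary
#' evolution damped by \code{exp(-t/a)} and Fourier transformed (real part,
#' upward transitions only, i.e. the upper triangle of the dipole matrix)
#' yields Lorentzians of half-width \code{hbar/a} at the transition energies
#' \code{E_a - E_1} with weights \code{|<phi_a|mu|phi_1>|^2}. The closed
#' sum-over-states form is used directly (\code{method = "sos"});
#' \code{method = "ft"} evaluates the damped correlation function on a time
#' grid and integrates it numerically as an independent cross-check.
#'
#' @param eig A [dimer_eigensystem()] (or any object with \code{energies} and
#'   \code{dipole} on the eigenbasis).
#' @param damping_a Damping time \code{a} of the correlation function (fs,
#'   default 7).
#' @param energy_grid Energy grid (eV), default 0 to 5 eV in 1 meV steps.
#' @param normalize Normalize to unit area (default TRUE).
#' @param method \code{"sos"} (closed form) or \code{"ft"} (time-domain
#'   quadrature).
#' @param t_max,dt Time grid for \code{method = "ft"} (fs); default
#'   \code{t_max = 40 * damping_a}.
#' @return A [spectrum] object.
#' @export
absorption_spectrum <- function(eig, damping_a = 7,
                                energy_grid = seq(0, 5, by = 0.001),
                                normalize = TRUE, method = c("sos", "ft"),
                                t_max = NULL, dt = 0.01) {
  method <- match.arg(method)
  up <- seq_along(eig$energies)[-1]
  positions <- eig$energies[up] - eig$energies[1]
  weights <- Re(eig$dipole[up, 1])^2
  meta <- list(kind = "absorption", damping_a = damping_a)
  if (method == "sos") {
    lorentzian_spectrum(positions, weights, .hbar / damping_a, energy_grid,
                        normalize, meta)
  } else {
    spectrum_from_sticks_ft(positions, weights, damping_a, energy_grid,
                            normalize, meta, t_max = t_max, dt = dt)
  }
}

#' Time-resolved fluorescence spectrum at delay t1
#'
#' The fluorescence generating function at delay \code{t1} is
#' \code{mu sigma(t1)}; the damped real-part Fourier transform of its
#' correlation function, restricted to downward transitions (lower triangle of
#' the dipole matrix), gives Lorentzians at \code{E_b - E_a} (upper state b,
#' lower state a) with weights \code{Re[(mu sigma)_{ba} mu_{ab}]}.
#'
#' @param sigma Reduced density matrix on the vibronic eigenbasis: either a
#'   full matrix, or a matrix restricted to an active space with an
#'   \code{"active"} attribute of eigenstate indices (as produced by
#'   [sigma_at()] and [initial_state_impulsive()]).
#' @inheritParams absorption_spectrum
#' @param t1 Optional delay time recorded in the metadata (fs).
#' @return A [spectrum] object.
#' @export
fluorescence_spectrum <- function(sigma, eig, damping_a = 7,
                                  energy_grid = seq(0, 5, by = 0.001),
                                  normalize = TRUE, method = c("sos", "ft"),
                                  t1 = NA_real_, t_max = NULL, dt = 0.01) {
  method <- match.arg(method)
  n <- length(eig$energies)
  sig <- embed_sigma(sigma, n)
  if (max(abs(sig - Conj(t(sig)))) > 1e-8)
    stop("'sigma' is not Hermitian", call. = FALSE)
  if (abs(Re(sum(diag(sig))) - 1) > 1e-6)
    stop("'sigma' does not have unit trace", call. = FALSE)
  musig <- eig$dipole %*% sig
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) # l < u: E_u >= E_l
  l <- pairs[, 1]; u <- pairs[, 2]
  positions <- eig$energies[u] - eig$energies[l]
  ## lower-triangle (downward) branch: for diagonal sigma this reduces to
  ## sigma_uu |mu_ul|^2, the emission from the populated upper state
  weights <- Re(eig$dipole[cbind(u, l)] * musig[cbind(l, u)])
  keep <- abs(weights) > 1e-300
  meta <- list(kind = "emission", damping_a = damping_a, t1 = t1)
  if (method == "sos") {
    lorentzian_spectrum(positions[keep], weights[keep], .hbar / damping_a,
                        energy_grid, normalize, meta)
  } else {
    spectrum_from_sticks_ft(positions[keep], weights[keep], damping_a,
                            energy_grid, normalize, meta, t_max = t_max, dt = dt)
  }
}

embed_sigma <- function(sigma, n) {
  active <- attr(sigma, "active")
  if (is.null(active)) {
    stopifnot(nrow(sigma) == n)
    return(sigma)
  }
  sig <- matrix(0 + 0i, n, n)
  sig[active, active] <- sigma
  sig
}

## Independent time-domain path: C(t) = sum_k w_k exp(-i E_k t / hbar - t/a),
## I(E) = (1/(pi*hbar)) Re Int_0^T C(t) exp(i E t / hbar) dt by Simpson's rule.
spectrum_from_sticks_ft <- function(positions, weights, damping_a, energy_grid,
                                    normalize, meta, t_max = NULL, dt = 0.01) {
  if (is.null(t_max)) t_max <- 40 * damping_a
  nt <- ceiling(t_max / dt)
  if (nt %% 2 == 1) nt <- nt + 1
  tt <- seq(0, by = dt, length.out = nt + 1)
  ct <- vapply(tt, function(t) {
    sum(weights * exp(-1i * positions * t / .hbar)) * exp(-t / damping_a)
  }, complex(1))
  simpson_w <- c(1, rep(c(4, 2), length.out = nt - 1), 4, 1)
  simpson_w <- simpson_w[seq_len(nt + 1)] * dt / 3
  simpson_w[nt + 1] <- dt / 3
  intensity <- vapply(energy_grid, function(E) {
    Re(sum(simpson_w * ct * exp(1i * E * tt / .hbar))) / (pi * .hbar)
  }, numeric(1))
  intensity[intensity < 0 & intensity > -1e-12] <- 0
  s <- spectrum(energy_grid, pmax(intensity, 0), normalized = FALSE, meta = meta)
  if (normalize) s <- normalize_spectrum(s)
  s
}

#' Integrated intensity of a spectrum over an energy window
#'
#' @param spec A [spectrum] object (typically unnormalized).
#' @param window Numeric length-2 vector \code{c(lo, hi)} in eV; defaults to
#'   the full grid.
#' @return Trapezoidal area over the window.
#' @export
integrated_intensity <- function(spec, window = range(spec$energy_ev)) {
  stopifnot(length(window) == 2)
  sel <- spec$energy_ev >= min(window) & spec$energy_ev <= max(window)
  if (sum(sel) < 2) stop("empty integration window", call. = FALSE)
  trapz(spec$energy_ev[sel], spec$intensity[sel])
}

#' Write a spectrum to a two-column CSV with a metadata header
#'
#' @param spec A [spectrum] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  meta <- attr(spec, "meta")
  hdr <- c(
    sprintf("# vibrex spectrum: %s", if (!is.null(meta$kind)) meta$kind else "generic"),
    sprintf("# damping_a_fs: %s", if (!is.null(meta$damping_a)) meta$damping_a else "NA"),
    sprintf("# normalized: %s", isTRUE(attr(spec, "normalized"))),
    sprintf("# grid_ev: %g..%g step %g", min(spec$energy_ev),
            max(spec$energy_ev), spec$energy_ev[2] - spec$energy_ev[1]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(spec), con, row.names = FALSE)
  invisible(path)
}
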
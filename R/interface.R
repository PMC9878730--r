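## Configuration loading, validation, and reproducible experiment runs.
## Configs are YAML with eV/fs/K units (gamma in ps^-1); molecule blocks are
## either inline parameter sets or references to parameter files such as the
## shipped fixtures nile_red.yaml and dans.yaml.

.molecule_keys <- c("gap_2z", "tau", "eps_v", "hbar_omega_v", "mu0")

#' Load molecular parameters from a YAML file
#'
#' @param path Path to a YAML file with keys \code{gap_2z}, \code{tau},
#'   \code{eps_v}, \code{hbar_omega_v} (eV) and optionally \code{mu0}.
#'   The package ships \code{nile_red.yaml} and \code{dans.yaml} under
#'   \code{extdata} (see [vibrex_fixture()]).
#' @return A [molecule_params] object.
#' @export
load_molecule <- function(path) {
  if (!file.exists(path)) stop("molecule file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  y <- y[setdiff(names(y), "name")]
  unknown <- setdiff(names(y), .molecule_keys)
  if (length(unknown))
    stop("unknown molecule keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(setdiff(.molecule_keys, "mu0"), names(y))
  if (length(missing))
    stop("missing molecule keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(molecule_params, y)
}

#' Path to a shipped fixture file
#' @param name File name under the package's \code{extdata} directory; with
#'   no argument, lists the available fixtures.
#' @return A file path (or a vector of file names).
#' @export
vibrex_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "vibrex")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) stop("no fixture named ", name, call. = FALSE)
  path
}

.config_defaults <- list(
  dimer = list(V = 0, geometry = "parallel", M = 8,
               hbar_omega_plus = NULL, hbar_omega_minus = NULL),
  bath = list(temperature = 300, gamma = 5, kind = "constant",
              debye_cutoff = NULL),
  propagation = list(t_max = 2000, dt = 1, stride = 10, threshold = 1e-6),
  spectra = list(damping_a = 7, grid_min = 0, grid_max = 5,
                 grid_step = 0.001, t1 = c(100, 1000)),
  fit = list(t_min = 500))

.known_sections <- c("experiment", "molecules", "dimer", "bath",
                     "propagation", "spectra", "fit", "scan")

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing an experiment
#' (\code{dimer-relaxation}, \code{ret}, \code{scan-resonance}, or
#' \code{scan-asymmetry}), validates the schema (unknown keys are rejected),
#' fills defaults, resolves molecule file references (relative to the config
#' directory, then to the shipped fixtures), and attaches a provenance block
#' (config hash and package version) that [run_experiment()] copies into all
#' outputs.
#'
#' @param path Path to the YAML configuration.
#' @return A list of class \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .known_sections)
  if (length(unknown))
    stop("unknown config sections: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$experiment))
    stop("missing required key: experiment", call. = FALSE)
  if (!cfg$experiment %in% c("dimer-relaxation", "ret", "scan-resonance",
                             "scan-asymmetry"))
    stop("unknown experiment kind: ", cfg$experiment, call. = FALSE)
  if (is.null(cfg$molecules) || is.null(cfg$molecules$mol1) ||
      is.null(cfg$molecules$mol2))
    stop("missing required keys: molecules.mol1 and molecules.mol2",
         call. = FALSE)
  for (sec in names(.config_defaults)) {
    given <- if (is.null(cfg[[sec]])) list() else cfg[[sec]]
    bad <- setdiff(names(given), names(.config_defaults[[sec]]))
    if (length(bad))
      stop(sprintf("unknown keys in '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    cfg[[sec]] <- modifyList(.config_defaults[[sec]], given)
  }
  base_dir <- dirname(normalizePath(path))
  cfg$molecules <- lapply(cfg$molecules, resolve_molecule, base_dir = base_dir)
  cfg$provenance <- list(config_hash = unname(tools::md5sum(path)),
                         package_version = as.character(packageVersion("vibrex")))
  structure(cfg, class = "run_config")
}

resolve_molecule <- function(m, base_dir) {
  if (inherits(m, "molecule_params")) return(m)
  if (!is.null(m$file)) {
    cand <- c(file.path(base_dir, m$file),
              system.file("extdata", m$file, package = "vibrex"))
    cand <- cand[file.exists(cand) & cand != ""]
    if (!length(cand)) stop("molecule file not found: ", m$file, call. = FALSE)
    return(load_molecule(cand[1]))
  }
  unknown <- setdiff(names(m), .molecule_keys)
  if (length(unknown))
    stop("unknown molecule keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(molecule_params, m)
}

config_dimer_spec <- function(cfg) {
  d <- cfg$dimer
  dimer_spec(cfg$molecules$mol1, cfg$molecules$mol2, V = d$V,
             geometry = d$geometry, M = d$M,
             hbar_omega_plus = d$hbar_omega_plus,
             hbar_omega_minus = d$hbar_omega_minus)
}

config_bath <- function(cfg) {
  b <- cfg$bath
  bath_spec(temperature = b$temperature, gamma = b$gamma, kind = b$kind,
            debye_cutoff = b$debye_cutoff)
}

#' Run a configured experiment and persist its outputs
#'
#' Executes the pipeline declared by the configuration (build, diagonalize,
#' excite, propagate, observables / spectra / fits) and writes deterministic
#' CSV outputs carrying a provenance header (config hash, package version)
#' into \code{out_dir}.
#'
#' @param config A [load_config()] object (or a path to one).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a named list of the written file paths and key results.
#' @export
run_experiment <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[3]

  spec <- config_dimer_spec(config)
  bath <- config_bath(config)
  prop <- config$propagation
  times <- seq(0, prop$t_max, by = prop$dt * prop$stride)
  written <- list()

  if (config$experiment %in% c("dimer-relaxation", "ret")) {
    eig <- dimer_eigensystem(spec)
    say("diagonalized: %d basis states, E1 = %.4f eV",
        length(eig$energies), eig$energies[1])
    rates <- redfield_rates(eig, bath)
    dip <- if (config$experiment == "ret") "site1" else "total"
    sigma0 <- initial_state_impulsive(eig, dipole = dip,
                                      threshold = prop$threshold)
    say("active space: %d states (threshold %g)",
        length(attr(sigma0, "active")), prop$threshold)
    traj <- propagate(sigma0, rates, eig, times = times)
    say("propagated to %g fs, trace drift %.2e", prop$t_max, traj$trace_drift)

    traj_path <- file.path(out_dir, "trajectory.csv")
    write_provenance_csv(trajectory_observables(traj), traj_path, config)
    written$trajectory <- traj_path

    sp <- config$spectra
    grid <- seq(sp$grid_min, sp$grid_max, by = sp$grid_step)
    abs_spec <- absorption_spectrum(eig, damping_a = sp$damping_a,
                                    energy_grid = grid)
    abs_path <- file.path(out_dir, "absorption.csv")
    write_spectrum_csv(abs_spec, abs_path)
    written$absorption <- abs_path
    for (t1 in sp$t1) {
      em <- fluorescence_spectrum(sigma_at(traj, t1), eig,
                                  damping_a = sp$damping_a,
                                  energy_grid = grid, t1 = t1)
      p <- file.path(out_dir, sprintf("emission_t%06.0ffs.csv", t1))
      write_spectrum_csv(em, p)
      written[[sprintf("emission_%g", t1)]] <- p
    }
    if (config$experiment == "ret") {
      fit <- fit_ret_rate(traj, t_min = config$fit$t_min)
      fr <- forster_rate(spec$V, spec$mol1, spec$mol2,
                         damping_a = config$spectra$damping_a)
      res <- data.frame(fitted_rate_ps = fit$fitted_rate_ps,
                        goodness = fit$goodness, reliable = fit$reliable,
                        forster_rate_ps = fr$rate_ps, J_DA_ev = fr$J_DA,
                        overlap_cm = fr$overlap_cm)
      p <- file.path(out_dir, "ret_result.csv")
      write_provenance_csv(res, p, config)
      written$ret_result <- p
      written$fit <- fit
    }
  } else if (config$experiment == "scan-resonance") {
    sc <- config$scan
    res <- scan_resonance(sc$acceptor_gap_values, spec$mol1, spec$mol2,
                          V = spec$V, M = spec$M, bath = bath, times = times,
                          t_min = config$fit$t_min)
    p <- file.path(out_dir, "resonance_scan.csv")
    write_provenance_csv(res, p, config)
    written$scan <- p
  } else {
    sc <- config$scan
    res <- scan_asymmetry(sc$delta_z12_values, sc$V_values, spec$mol1,
                          M = spec$M, bath = bath, times = times)
    p <- file.path(out_dir, "asymmetry_scan.csv")
    write_provenance_csv(res, p, config)
    written$scan <- p
  }
  say("done in %.1f s", proc.time()[3] - t0)
  invisible(written)
}

write_provenance_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# vibrex %s", config$provenance$package_version),
               sprintf("# config_hash: %s", config$provenance$config_hash),
               sprintf("# experiment: %s", config$experiment)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by vibrex, skipping provenance headers
#' @param path File path.
#' @return A data frame.
#' @export
read_vibrex_csv <- function(path) {
  lines <- readLines(path)
  skip <- sum(startsWith(lines, "#"))
  utils::read.csv(path, skip = skip)
}
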
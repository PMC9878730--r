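## Physical constants. Energies eV, times fs, temperatures K throughout.

#' Physical constants used by vibrex
#'
#' @format A named list: `hbar_ev_fs` (reduced Planck constant, eV fs),
#'   `kb_ev_k` (Boltzmann constant, eV/K), `ev_to_cm` (wavenumbers per eV).
#' @export
vibrex_constants <- list(
  hbar_ev_fs = 0.6582119569,
  kb_ev_k    = 8.617333262e-5,
  ev_to_cm   = 8065.543937
)

.hbar <- vibrex_constants$hbar_ev_fs
.kb   <- vibrex_constants$kb_ev_k
.evcm <- vibrex_constants$ev_to_cm
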
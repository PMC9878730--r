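---
title: "The vibronic dimer model behind vibrex: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vibronic dimer model behind vibrex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vibrex)
```

# The model

## One molecule: two diabatic states and one quantum vibration

A donor-acceptor (push-pull) dye is described on the two resonance
structures that dominate its low-energy physics: the neutral `|N>` and the
zwitterionic `|Z>` state. They are split by a diabatic gap `2z` and mixed by
a matrix element `-tau`. The ionicity operator `rho_hat = |Z><Z|` measures
the ground-state charge transfer; its expectation `rho` fixes all
electronic observables of the two-state model, e.g. the molecular dipole
`mu_hat = mu0 * rho_hat` (only the zwitterion carries a dipole, in the
Mulliken spirit of keeping a single charge distribution per structure).

One effective vibration per molecule accounts for the different equilibrium
geometries of `|N>` and `|Z>`. The coordinate is quantized,
`Q = (a + a^+)/sqrt(2)`, with vibrational quantum `hbar_omega_v`, and
couples linearly to the ionicity with coupling constant
`sqrt(eps_v * hbar_omega_v)` on `(a + a^+)`. The sign convention displaces
`|Z>` to lower energy, and the constant is *pinned* by a testable identity
rather than by a symbol: on the `|Z>` diabatic surface, the relaxed minimum
lies exactly `eps_v` (the vibrational relaxation energy of the
`|N> -> |Z>` electron transfer) below the energy at the `|N>` equilibrium
geometry. The test suite asserts this identity to 1e-10, so the convention
cannot silently drift.

Reference parameter sets for two well-characterized dyes ship as fixtures
(`vibrex_fixture()`): Nile Red (`2z = 1.76`, `tau = 0.95`, `eps_v = 0.33`,
`hbar_omega_v = 0.14`, all eV) and DANS (`2.64`, `0.72`, `0.30`, `0.17`).
The fixtures set `mu0 = 20` Debye, a typical mesomeric dipole for this
family; `mu0` only scales intensities (all shipped analyses use normalized
spectra or intensity ratios) and never enters energies or rates.

## Mean-field ionicity

Because of the electron-vibration coupling, the ground-state ionicity obeys
a fixed-point equation: the oscillator relaxes to the equilibrium of the
current charge distribution, which lowers the effective gap by
`2 * eps_v * rho`, which changes the charge distribution. With a partner
molecule, the electrostatic coupling `V` adds `V * rho_partner` to the
effective gap. `solve_mean_field_ionicity()` iterates this map with damping
0.5 to `|delta rho| < 1e-10` (at most 1e4 iterations); the damping makes
the iteration robust over the whole physically relevant parameter range,
and an independent brute-force root-bracketing oracle confirms the fixed
point in the tests. For isolated Nile Red the fixed point is
`rho = 0.173`; the bare electronic two-state model (no vibrational
renormalization) gives `0.160`. Quoted reference values of "~0.16" for
this quantity correspond to the latter, rounder number; we report the
renormalized fixed point, which is the self-consistent object the rest of
the model is built on.

## The dimer

Two molecules interact only electrostatically. Neglecting every
interaction that involves a neutral structure (Mulliken approximation),
a single scalar `V` survives: the interaction of the doubly zwitterionic
configuration `|Z1 Z2>`. The dimer Hamiltonian is therefore the sum of the
two molecular Hamiltonians plus `V` on the `ZZ` diagonal. This is built on
the product basis of 4 electronic states times two Fock spaces, truncated
by the *total* vibrational quantum number.

**Truncation convention.** States with `n1 + n2 < M` are retained (strict
inequality). With `M = 14` this gives `4 * 105 = 420` basis states, the
documented reference size; reading the truncation as "does not exceed M"
would give 480 states instead. The strict convention reproduces the
reference count and is what `build_basis()` implements; `M` is
configurable everywhere.

Diagonalization (`dimer_eigensystem()`) uses a dense symmetric eigensolver
and fixes eigenvector signs (largest-magnitude coefficient positive) so
outputs are bit-stable. Exciton bookkeeping works on the mean-field basis:
with the jointly self-consistent ionicities, each site's `|G>`/`|E>` states
define exciton projectors, and the one-exciton block (diagonal mean-field
transition energies, off-diagonal exciton coupling
`J = V * sqrt(rho1(1-rho1) * rho2(1-rho2))`, i.e. `V rho (1 - rho)` for a
homodimer) splits into a lower and an upper electronic state separated by
`2J`.

**Manifold labels.** Each vibronic eigenstate is classified by the rounded
expectation of the total exciton number: 0 is the ground manifold `G`,
2 or more is `higher`. One-exciton states are assigned to `S1` or `S2` by
their dominant weight on the lower or upper one-exciton electronic state.
This reproduces the standard J/H phenomenology: for `V < 0` (J-dimer) the
state carrying the ground-state oscillator strength lies in `S1` and
coincides with the emissive (Kasha) state; for `V > 0` (H-dimer) it lies
in `S2`, a gap `~2J` above the dark Kasha state — which is why the S1/S2
splitting, not the two-exciton energy, controls the residual thermal `S2`
population seen at room temperature. An alternative labeling by exciton
number alone was rejected because it merges both exciton components into
one manifold and cannot express that bookkeeping.

**Symmetrized modes.** For homodimers the site modes are recast as
`Q+ = (Q1 + Q2)/sqrt(2)` and `Q- = (Q1 - Q2)/sqrt(2)` with separately
assignable frequencies (reference values 0.15 and 0.13 eV for Nile Red
dimers, against a site frequency of 0.14 eV). This lifts the accidental
degeneracies of the homodimer — which otherwise make the secular master
equation ill-defined — without breaking the site-exchange symmetry:
`<phi|Q-|phi> = 0` holds for every eigenstate, and the site-basis and
symmetrized constructions are unitarily equivalent when the two
frequencies coincide (asserted to 1e-8 eV). The electron-vibration
constant is rescaled with the harmonic mean of the two frequencies so that
the site relaxation energy stays exactly `eps_v`. The constructor requires
equal vibrational parameters on the two sites for this representation
(electronic asymmetry, as in the asymmetry scans, is allowed).

# Dissipative dynamics

The two vibrational coordinates couple to two *independent* harmonic baths
at temperature `T`. Two baths matter qualitatively: with a single bath
(or coupling through `Q+` alone) relaxation between manifolds of opposite
exchange parity is strictly forbidden; the tests assert those blocked
rates are exactly zero, and that they open as soon as `Q-` couples.

The spectral density is flat, `J(omega) = gamma`, with `gamma = 5 ps^-1`
by default (a Debye form with a user-supplied cutoff is also available but
has no reference-pinned default). In the secular approximation the
populations follow a Pauli master equation with golden-rule rates
`gamma * |<a|Q|b>|^2 * (n(omega)+1)` downhill and `... * n(omega)` uphill
(Bose occupation `n`), which obey detailed balance *exactly* by
construction; each coherence decays independently at half the sum of the
two total outflows. Pure dephasing is zero by default — the `omega -> 0`
thermal limit of a flat spectral density diverges, so any finite constant
would be arbitrary; a configurable override exists. Degenerate pairs
(splitting below 1e-9 eV) get no thermal rate; in practice the
symmetrized-mode splitting removes the homodimer degeneracies before this
guard matters.

**Propagation.** Populations are advanced with matrix exponentials of the
Pauli generator (Pade scaling-and-squaring, one exponential per distinct
step length, renormalized to column-stochastic form to kill round-off
drift); coherences evolve analytically with their own frequency and decay.
This is exact for the secular equation at arbitrary step length, so output
grids can be as sparse as the observables allow — nanosecond horizons cost
no more than picosecond ones. A Short-Iterative-Arnoldi (Krylov) stepper
is provided as an independent cross-check and agrees with the exponential
route to 1e-8; a dense `lsoda` integration of the same equations provides
a third, package-independent oracle in the tests. A detailed-balance
symmetrization of the generator was considered and rejected: with initial
states several eV above the ground state the required Boltzmann factors
(~e^116 at 300 K) make that route catastrophically ill-conditioned.

**Initial state.** Impulsive excitation acts with the dipole operator on
the ground state and projects on the excited eigenstates; donor-only
excitation uses the donor's site dipole instead. Eigenstates with initial
population below 1e-6 are dropped, and the active space keeps everything
below the highest surviving state (the relaxation targets).

# Spectra

Absorption uses the generating function `mu |phi1><phi1|`, time-resolved
emission `mu sigma(t1)`; both correlation functions are damped by
`exp(-t/a)` with `a = 7 fs` by default and Fourier transformed (real
part), keeping only upward (absorption) or downward (emission)
transitions. For a time-independent Hamiltonian this equals a sum of
Lorentzians of half-width `hbar/a` at the transition energies, so the
closed sum-over-states form is the production path; the time-domain
quadrature (Simpson's rule on the damped correlation function) is kept as
a cross-check and agrees to 1e-6 of the peak intensity on toy systems
where its discretization error is negligible. No additional apodization
is applied. Negative round-off intensities are clipped only after any
oracle comparison. The default grid is 0-5 eV in 1 meV steps.

The "thermally equilibrated" emissive state used for long-time emission is
the Boltzmann distribution restricted to the excited manifolds
(`thermal_state(..., subset = )`): inter-manifold relaxation to the ground
state is orders of magnitude slower than intra-manifold thermalization, so
the emitting quasi-equilibrium carries the Kasha state plus the residual
thermal population of the lowest `S2` level — the origin of the
high-energy shoulder in H-dimer long-time emission.

# RET rates

Dynamical rates come from donor-only-excitation trajectories. The fitted
observable is the *excitation share* of the acceptor among excited states,
`p_m2 / (p_m1 + p_m2)`, where each eigenstate's excitation is apportioned
between the molecules by its site-excitation weights. The share is
preferred over the raw acceptor population because the slow (nanosecond)
leakage toward the ground manifold is a common mode of both sites and
cancels in the ratio; with the raw population that leakage adds a small
V-independent offset to every fitted rate. The fit model is the
fewest-parameter saturating exponential
`P(t) = P_inf (1 - exp(-k (t - t0)))` with `t0` fixed at the window start
(default 0.5 ps, after the vibrational-relaxation transient), solved with
Levenberg-Marquardt; fits with R^2 below 0.9 are flagged unreliable.

The Forster comparison uses the golden-rule convention
`k = (2 pi / hbar) * J_DA^2 * S` with
`J_DA = V sqrt(rho_D(1-rho_D) rho_A(1-rho_A))` (isolated-molecule
ionicities; the transition dipoles of the two-state model are proportional
to `sqrt(rho(1-rho))`) and `S` the overlap of the unit-area donor emission
and acceptor absorption line shapes on the wavenumber axis. The overlap
spectra are broadened with the same `a = 7 fs` damping used for every
other spectrum in the package — one uniform spectral convention
throughout. The absolute Forster scale is convention-dependent (the line
width enters `S` directly, and rates shift by a factor of order 2 under
alternative width choices), so only same-convention comparisons, ratios
and scalings are meaningful; the package always computes both rates under
this single convention.

**Where Forster works.** In the weak-coupling regime the fitted dynamical
rate is quadratic in `V` and agrees with the same-convention Forster rate
within a factor of 2. The quadratic-scaling check uses
`V = 5, 10, 20 meV`: at 40 meV the rate (~0.1 ps^-1) is no longer an
order of magnitude slower than vibrational relaxation (~2.4 ps^-1 for
this pair), the time-scale separation underlying the Forster picture
starts to fail, and the measured exponent already bends to ~1.7 — the
onset of the same strong-coupling deviation that becomes a factor >2
discrepancy by `V = 0.1-0.2 eV`.

**Truncation and RET.** RET observables need a slightly larger basis than
homodimer relaxation. Truncating on the total quantum number breaks the
exact separability of the `V = 0` pair, and accidental near-degeneracies
between donor- and acceptor-excited vibronic levels then open a spurious,
V-independent transfer channel. For the DANS-Nile Red pair the artifact
rate is ~2e-3 ps^-1 at `M = 8`, ~4e-5 at `M = 10`, and negligible at
`M = 14`. RET workflows therefore default to `M = 10`, which keeps the
artifact two orders of magnitude below the weakest rate studied; homodimer
spectroscopy and relaxation are well converged at `M = 7-8`, and the
shipped tests use those reduced sizes to keep a full run within minutes on
one CPU.

**Scans.** The resonance scan varies the acceptor gap `2z` (emulating a
local field) at `V = 0.03 eV` and fits a rate at each point; rates peak —
by two orders of magnitude — exactly where the donor Kasha level crosses
acceptor vibronic levels with two or three quanta, the vibronic-resonance
effect that a line-shape-level Forster treatment washes out. The asymmetry
scan raises `z` on molecule 2 (`delta_z12 = z2 - z1`); at zero asymmetry
and strong coupling the excitation stays delocalized (`P_M1* = 0.5`
exactly, by symmetry), while large asymmetry localizes it on the low-gap
molecule with a long-time limit independent of the sign of `V` — the
crossover from exciton pair to RET pair.

# Limitations

Polar solvation (and any slow classical coordinate that could stabilize
the symmetry-broken minima of the H-dimer S1 surface) is outside the
model: the dynamics runs along the ridge between the two minima and shows
large `Q-` fluctuations instead of localization. Aggregates larger than
dimers, more than one effective mode per molecule, geometry-resolved
electrostatics (V is a scalar input), non-secular Redfield, correlated
baths, and anisotropy- or polarization-resolved signals are likewise out
of scope. Absolute emission intensities are in arbitrary units (`mu0^2`);
only ratios are physical.
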
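# Nile Red (9-diethylamino-5-benzo[a]phenoxazinone) essential-state parameters.
# Energies in eV; mu0 in Debye (sets the intensity scale only).
name: nile_red
gap_2z: 1.76
tau: 0.95
eps_v: 0.33
hbar_omega_v: 0.14
mu0: 20
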
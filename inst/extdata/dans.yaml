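# DANS (4-dimethylamino-4'-nitrostilbene) essential-state parameters.
# Energies in eV; mu0 in Debye (sets the intensity scale only).
name: dans
gap_2z: 2.64
tau: 0.72
eps_v: 0.3
hbar_omega_v: 0.17
mu0: 20
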
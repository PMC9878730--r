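# Relaxation of an H-type Nile Red homodimer after impulsive excitation.
experiment: dimer-relaxation
molecules:
  mol1: {file: nile_red.yaml}
  mol2: {file: nile_red.yaml}
dimer:
  V: 0.4
  geometry: parallel
  M: 8
  hbar_omega_plus: 0.15
  hbar_omega_minus: 0.13
bath:
  temperature: 300
  gamma: 5
propagation:
  t_max: 2000
  dt: 1
  stride: 10
spectra:
  damping_a: 7
  t1: [100, 1000]
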
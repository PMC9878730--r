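# Weak-coupling RET in a DANS (donor) - Nile Red (acceptor) pair.
experiment: ret
molecules:
  mol1: {file: dans.yaml}
  mol2: {file: nile_red.yaml}
dimer:
  V: 0.02
  geometry: parallel
  M: 8
bath:
  temperature: 300
  gamma: 5
propagation:
  t_max: 40000
  dt: 1
  stride: 100
fit:
  t_min: 1000
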
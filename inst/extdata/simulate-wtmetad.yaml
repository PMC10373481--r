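# Example configuration for `ldacv simulate`: well-tempered metadynamics on
# the handedness dihedral of the bundled chiral toy system.
n_steps: 50000
stride: 10
seed: 1
temperature: 450
bias:
  method: wtmetad
  cv: dihedral
  height: 0.1
  sigma: 0.15
  gamma: 8
  pace: 200
  qmin: -3.1
  qmax: 3.1
  ngrid: 400
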
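# Monotopic cytochrome c (xi = 1/2) in a 3 mM DPPC bilayer, X-ray probe.
system:
  host: DPPC
  island:
    type: protein
    protein: cytochrome_c
    xi: 0.5
  lattice: {a: 150, ga: 0.3}
  stack: {"N": 1}
  concentration: {host: 3}
probe: {type: xray}
instrument: {kappa: 1, B: 0}
qgrid: {min: 0.01, max: 0.6, "n": 300, spacing: log}
noise: {eps: auto}
seed: 1
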
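# Transmembrane bacteriorhodopsin islands in a 3 mM DPPC bilayer,
# core-shell parameters from the packaged protein table, X-ray probe.
system:
  host: DPPC
  island:
    type: protein
    protein: bacteriorhodopsin
    xi: 1
    embed: full
  lattice: {a: 150, ga: 0.3}
  stack: {"N": 1}
  concentration: {host: 3}
probe: {type: xray}
instrument: {kappa: 1, B: 0}
qgrid: {min: 0.01, max: 0.6, "n": 300, spacing: log}
noise: {eps: auto}
seed: 1
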
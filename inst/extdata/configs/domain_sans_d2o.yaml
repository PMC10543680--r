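# As domain_saxs.yaml but observed by SANS in pure D2O (xD = 1).
system:
  host: DPPC
  island:
    type: domain
    guest: DOPC
    R1: 60
  lattice: {a: 150, ga: 0.3}
  stack: {"N": 1}
  concentration: {host: 3}
probe: {type: neutron, xD: 1}
instrument: {kappa: 1, B: 0}
qgrid: {min: 0.01, max: 0.6, "n": 300, spacing: log}
noise: {eps: auto}
seed: 1
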
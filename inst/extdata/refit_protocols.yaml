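# Ground-truth parameter sets for the simulated-experiment + refit protocols.
# Lengths in Angstrom, electron densities in e/A^3, neutron SLDs in 1e-6/A^2.
domain:
  host:
    name: DPPC
    area: 57
    volume: 1140
    D: [12.0, 10.6, 3.64]
    rhoX: [0.411, 0.316, 0.247]
    rhoN: [4.29, -0.618, -0.126]
    sigma: [2.56, 2.22, 1.74]
  guest:
    name: DOPC
    area: 60
    volume: 1270
    D: [12.3, 12.3, 3.13]
    rhoX: [0.407, 0.296, 0.246]
    rhoN: [4.33, -0.529, -0.106]
    sigma: [3.47, 3.51, 4.12]
  a: 150
  R1: 60
  ga: 0.3
  C_host: 3
transmembrane:
  host:
    name: DPPC
    area: 57
    volume: 1140
    D: [12.0, 10.6, 3.64]
    rhoX: [0.411, 0.316, 0.247]
    rhoN: [4.29, -0.618, -0.126]
    sigma: [2.56, 2.22, 1.74]
  protein:
    name: bacteriorhodopsin
    Vp: 96506
    R: 8.01
    delta: 21.0
    phiI: 0.0195
    phiE: 0.870
    L: 45.5
    rhoPX: 0.411
    rhoPN: 2.732
  a: 150
  ga: 0.3
  C_host: 3
monotopic:
  host:
    name: DPPC
    area: 57
    volume: 1140
    D: [12.0, 10.6, 3.64]
    rhoX: [0.411, 0.316, 0.247]
    rhoN: [4.29, -0.618, -0.126]
    sigma: [2.56, 2.22, 1.74]
  protein:
    name: cytochrome_c
    Vp: 14839
    R: 0.262
    delta: 15.0
    phiI: 0.718
    phiE: 0.886
    L: 22.8
    rhoPX: 0.420
    rhoPN: 3.119
  xi: 0.5
  a: 150
  ga: 0.3
  C_host: 3
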
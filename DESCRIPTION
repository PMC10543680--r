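Package: sasbilayer
Title: Small-Angle Scattering from Flat Lipid Bilayers with Correlated Inhomogeneities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical simulation and global fitting of small-angle X-ray and
    neutron scattering (SAXS/SANS) curves of flat lipid bilayers containing
    laterally correlated cylindrical scattering-length-density inhomogeneities
    (lipid domains, water pores, anchored/monotopic/transmembrane proteins).
    Bilayer and island z-profiles are multi-level error-function-smoothed slabs
    with closed-form one-dimensional Fourier transforms; in-plane island
    correlations follow a distorted two-dimensional hexagonal paracrystal and
    vertical stacking follows paracrystal theory or the modified Caille theory.
    Includes stoichiometric system builders, a core-shell cylinder mapping for
    protein form factors, a synthetic-experiment generator, a multi-curve
    SAXS+SANS global fitter, and a brute-force finite-system Monte Carlo
    reference implementation used to validate the analytic pipeline.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
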
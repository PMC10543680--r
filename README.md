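# sasbilayer

Analytical simulation and global fitting of small-angle X-ray and neutron
scattering (SAXS/SANS) from flat lipid bilayers carrying laterally
correlated cylindrical scattering-length-density inhomogeneities — lipid
domains, water pores, and anchored, monotopic or transmembrane proteins.

It is written for membrane structural biologists and scattering
practitioners who record SAXS/SANS curves of large unilamellar vesicles and
want to extract, by joint model fitting, the size and surface density of
nanoscale heterogeneities together with the bilayer structure, without
relying on contrast matching.

## The model

A bilayer is a stack of SLD levels along the normal with error-function
transitions; its one-dimensional Fourier transform is closed form,

    A(q_perp) = (i/q_perp) * sum_j drho_j * exp(i q_perp z_j - q_perp^2 sigma_j^2 / 2).

An "island" is a set of concentric cylindrical shells (radii R_1 < ... <
R_Ns), each shell carrying a level profile in excess of the host bilayer;
its in-plane transform is a sum of annulus transforms 2*pi*R*J1(qR)/q.
Island centres follow a distorted 2D hexagonal paracrystal (lattice
parameter a, distortion g_a, surface density n_d = 2/(sqrt(3) a^2));
vertical stacking follows 1D paracrystal theory or the modified Caillé
theory with polydispersity over the stack size. After orientational
averaging in the large-sheet limit the measured intensity is

    I(q) = kappa * (c_V / t_eff) * [ (2*pi/q^2) * Z_N(q) * |A_b(q) + n_d A_i(q,0)|^2
           + n_d * <|A_i(q cos b, q sin b)|^2 S_dd(q sin b)>_b ] * 1e8 + B   [1/cm]

— a coherent mean-sheet term (flat-sheet Lorentz factor, stacking factor
Z_N) plus the island fluctuation term with the azimuthally averaged
island–island structure factor S_dd. A brute-force finite-system Monte
Carlo reference implementation (explicit lattice realizations, exact
finite-sheet transforms, no asymptotics) validates this decomposition
end-to-end; the methods vignette
(`vignettes/membrane-sas-model.Rmd`) derives and discusses every term.

## Worked example

Simulate the SAXS curve of DOPC domains (R1 = 60 Å) on a hexagonal
paracrystal (a = 150 Å, g_a = 0.3) in a 3 mM DPPC bilayer, and compare the
implied DOPC concentration and island density:

```r
library(sasbilayer)

dppc <- getLipid("DPPC"); dopc <- getLipid("DOPC")
islandDensity(150)                      # islands per unit area
#> [1] 5.132002e-05
domainConcentration(3, 150, 60, 57, 60) # guest concentration, mM
#> [1] 3.942439

sys <- buildDomainSystem(dppc, dopc, a = 150, R1 = 60, ga = 0.3,
                         C_host = 3, probe = probeContrast("xray"))
q <- exp(seq(log(0.02), log(0.4), length.out = 5))
macroscopicIntensity(sys, q)            # cm^-1, kappa = 1, B = 0
#> [1] 8.355630e-02 7.007191e-03 5.263178e-03 3.109923e-03 1.620255e-06
```

The island density is the reciprocal hexagonal unit-cell area; the 3.94 mM
guest concentration is the unit-cell molecule balance between the domain
disc and the remaining host area. The intensity falls roughly as the
flat-sheet q^-2 envelope times the bilayer form factor, with the domain
contribution filling in the pure-DPPC minima.

A noisy synthetic experiment and a joint SAXS+SANS refit of the full
protocol (four curves, 26 shared structural parameters):

```r
curves <- simulateDomainProtocol(q = exp(seq(log(0.01), log(0.6), length.out = 200)),
                                 seed = 42)
fit <- fitDomainProtocol(curves, seed = 1)
subset(fit$estimates, parameter %in% c("D1_b", "rhoX2_b", "R1", "ga"))
#>    parameter   estimate           se atBound
#> 1       D1_b 12.0177132 0.0388430018   FALSE
#> 5    rhoX2_b  0.3158222 0.0007631119   FALSE
#> 25        R1 59.9963504 0.0603592744   FALSE
#> 26        ga  0.2980789 0.0022993620   FALSE
```

The head-region thickness (truth 12.0 Å), CH2-region electron density
(truth 0.316 e/Å^3), domain radius (60 Å) and lattice distortion (0.3) are
recovered within their reported uncertainties.  (The fit warns that the
weakly identified guest CH3 smoothness sits at its bound — expected for
this protocol; see the methods vignette.)

A shell entry point mirrors the main operations
(`simulate`, `build`, `oracle`, `fit`):

```sh
Rscript inst/cli/sasbilayer.R simulate --config system.yaml --out outdir
```

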
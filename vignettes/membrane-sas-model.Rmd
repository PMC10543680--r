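---
title: "Modelling small-angle scattering from flat bilayers with correlated inhomogeneities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling small-angle scattering from flat bilayers with correlated inhomogeneities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasbilayer)
```

# The model

`sasbilayer` computes SAXS and SANS curves of large unilamellar vesicles
idealized as flat bilayer sheets that carry laterally correlated cylindrical
scattering-length-density (SLD) inhomogeneities — "islands": lipid domains,
water pores, or membrane proteins. The macroscopic differential scattering
cross section is assembled from four ingredients.

## SLD profiles and their transforms

Every z-profile (the host bilayer and each island shell) is a sequence of
constant SLD levels with error-function transitions: level $j$ occupies
$[z_j, z_j + D_j]$, $z_{j+1} = z_j + D_j$, and transition $j$ has smoothness
$\sigma_j$, using the convention
$\rho(z) = \rho_0 + \sum_j \Delta\rho_j\,\Phi\!\big((z-z_j)/\sigma_j\big)$
with $\Phi(u) = \tfrac12(1 + \mathrm{erf}(u/\sqrt2))$ and $\Delta\rho_j$ the
SLD jump across the transition (the sum includes the closing transition to
solvent). Since the derivative of each smoothed step is a Gaussian,
integration by parts gives the closed-form one-dimensional transform

$$A(q_\perp) \;=\; \frac{i}{q_\perp} \sum_j \Delta\rho_j\,
  e^{\,i q_\perp z_j - q_\perp^2 \sigma_j^2/2},$$

with the $q_\perp \to 0$ limit $\sum_j (\rho_j - \rho_0) D_j$ taken
analytically. Transitions with $\sigma_j = 0$ are handled by the same
expression exactly (no small-$\sigma$ surrogate); profile evaluation uses an
exact step branch. The closed form is verified against adaptive quadrature
of the defining integral in the unit tests (relative error below $10^{-8}$
on a representative $q$ grid).

Symmetric bilayers are built by mirroring a three-region half-profile
(polar head, CH$_2$-rich, CH$_3$-rich) into five levels with the CH$_3$
region centred at $z = 0$. For X-rays, electron densities (e/Å$^3$) are
converted to SLDs on construction via the classical electron radius
$r_e = 2.8\times10^{-5}$ Å; for neutrons the solvent SLD interpolates
linearly between H$_2$O ($-0.560\times10^{-6}$ Å$^{-2}$) and D$_2$O
($6.36\times10^{-6}$ Å$^{-2}$) with the deuteration fraction $x_D$.

## Islands

An island is a set of concentric cylindrical shells with radii
$R_1 < \dots < R_{N_s}$; shell $k$ carries its own level profile, and its
scattering amplitude is the transform of the SLD *in excess of the host
bilayer*, multiplied by the annulus transform
$\tilde S_k(q_\parallel) = 2\pi\,[R_k J_1(q_\parallel R_k) -
R_{k-1} J_1(q_\parallel R_{k-1})]/q_\parallel$ (series branch below
$|q_\parallel R| < 10^{-4}$ to avoid cancellation). The island amplitude is
$A_i(q_\perp, q_\parallel) = \sum_k A_k(q_\perp)\tilde S_k(q_\parallel)$.

## In-plane and vertical order

Island centres follow a distorted two-dimensional hexagonal paracrystal:
unit-cell vectors of length $a$ at 60°, cumulative isotropic Gaussian
disorder of standard deviation $\sigma_a = g_a a$ per step. The island
surface density is $n_d = 2/(\sqrt3\,a^2)$. For the infinite lattice the
island–island structure factor is the two-direction product
$\prod_{k=1,2}\mathrm{Re}\,[(1+\Phi_k)/(1-\Phi_k)]$ with
$\Phi_k = \exp(i\,\mathbf q_\parallel\!\cdot\!\mathbf a_k -
q_\parallel^2\sigma_a^2/2)$. A point worth documenting: this product is
*not* six-fold symmetric in azimuth — its symmetry group is generated by
mirror lines at 30° and 120° with 180° periodicity (the ridge where
$\mathbf q \perp \mathbf a_1$ breaks hexagonal symmetry). The azimuthal
average is therefore taken by Gauss–Legendre quadrature over the true
irreducible sector $[30°, 120°]$ (64 nodes by default), which the tests
verify against a dense full-circle average.

Vertical stacking of $N$ bilayers at repeat distance $c$ uses either the
one-dimensional paracrystal (PT, distortion $g_{c\perp}$) or the modified
Caillé theory (MCT, Caillé parameter $\eta_1$, Euler's constant in the
algebraic peak tails); the Zhang relation
$g_{c\perp} = (0.087\,\eta_1)^{1/2}$ converts between them when only one is
specified. A discrete Gaussian polydispersity over $N$ (relative width 0.3
by default, truncated at $\pm3$ widths and at $N \ge 1$, renormalized)
suppresses the low-$q$ oscillations of the monodisperse expression. The PT
branch is validated against a brute-force double sum over
cumulative-Gaussian stack realizations; MCT is validated through its exact
$\eta_1 \to 0$ ideal-lattice limit and its Bragg peak positions, since no
independent MCT implementation is available in this toolchain.

## The orientationally averaged cross section

For a sheet much larger than all other lengths, the orientational average
collapses the sheet transform onto a Dirac delta along the bilayer normal
(the flat-sheet Lorentz factor $2\pi/q^2$). Working per bilayer and per
unit area, the package evaluates

$$\frac{d\Sigma}{d\Omega}(q) \;=\; \frac{2\pi}{q^2}\, Z_N(q)\,
  \big|\,\bar A(q)\,\big|^2 \;+\; n_d \int_0^1
  \big|A_i(qu,\, q\sqrt{1-u^2})\big|^2\,
  \bar S_{dd}(q\sqrt{1-u^2})\; du ,$$

with $\bar A(q) = A_b(q) + n_d A_i(q, 0)$. The decomposition needs a
comment, because the treatment of the bilayer–island cross term is the one
genuinely open design point in this model family. The $q_\parallel \approx
0$ (coherent, forward) part of the island sum is exactly the scattering of
a uniform sheet whose profile is the area-weighted mixture of host and
island profiles; it interferes with the host amplitude and is correlated
across the stack, so it belongs inside the Lorentz-factor term with the
stacking factor $Z_N$. The residual island fluctuations are uncorrelated
between bilayers and carry the infinite-paracrystal $\bar S_{dd}$ (which
contains no forward delta), so they take no stacking factor. This
decomposition reproduces, analytically, both homogenization limits of the
model — the independent-sheet mixture
$(1-x)|A_b|^2 + x|A_{isl}|^2$ at large $a$, and the homogeneous mixture
bilayer $|(1-x)A_b + xA_{isl}|^2$ at small $R_1$ and fixed area fraction
$x = n_d \pi R_1^2$ — and it is confirmed end-to-end by the finite-system
Monte Carlo oracle, which makes no asymptotic replacement at all.

The zenith integral uses Gauss–Legendre quadrature in $\cos\beta$ (256
nodes by default; an open rule, so the singular $q_\parallel = 0$ azimuth
point is never a node; doubling the nodes changes the curves by under
0.1%). The measured intensity is
$I(q) = \kappa\,(c_V / t_\mathrm{eff})\, d\Sigma/d\Omega \times 10^8 + B$
in cm$^{-1}$, with $c_V = N_A \sum_i C_i v_i$ the sample volume fraction
and $t_\mathrm{eff}$ the volume of a bilayer with islands per unit area
($t_b + n_d \sum_k \pi(R_k^2 - R_{k-1}^2)(t_k - t_b)$). No sheet radius
appears anywhere in the pipeline.

# System builders

**Lipid domains.** A single shell of radius $R_1$ carrying the guest
lipid's five-level profile. The guest concentration follows from the
unit-cell balance,
$C_g = C_h (a_h/a_g)\, \pi R_1^2 / [(\sqrt3/2)a^2 - \pi R_1^2]$
(both leaflets contribute equally, so the leaflet factor cancels).

**Proteins.** Protein form factors are condensed into a core–shell
cylinder (core radius $R$, shell thickness $\delta$, occupancies
$\phi_i, \phi_e$, length $L$ derived from the volume closure
$\phi_i \pi R^2 L + \phi_e \pi[(R+\delta)^2 - R^2]L = V_p$; the packaged
parameter table's printed $L$ values are rounded, so the derived value is
used by default). Region SLDs mix the protein SLD with solvent by the
occupancy. Transmembrane islands place one level of length $L$ at
$-L/2$ (or $-L/4$ when half the protein protrudes); anchored islands stack
the protein level on top of the five bilayer levels; monotopic islands
replace the upper bilayer levels above the lower three. The protein
concentration uses the footprint $a_p = \pi(R+\delta)^2$ and the embedding
fraction $\xi \in \{0, \tfrac12, 1\}$:
$C_p = C_b a_h/[\sqrt3 a^2 - 2\xi a_p]$.

**Pores.** A pore of waist radius $R_w$ is the water region bounded by the
inner surface of a torus whose tube radius is the bilayer half-thickness:
at radial distance $s$, lipid remains at $|z| \le z^*(s) =
[r_t^2 - (R_w + r_t - s)^2]^{1/2}$. Two SLD interpretations were examined.
Lining the rim with head-group SLD at constant normal depth $D_1$
(geometrically, the region between the torus and its inner parallel torus)
produces a *positive* X-ray forward excess — replacing low-density chains
near the mid-plane with high-density heads raises the forward scattering,
which contradicts the well-established phenomenology that pores depress
the low-$q$ X-ray signal. The package therefore models the pore as a water
funnel carved out of the otherwise unperturbed bilayer profile. The mapped
three-shell island (hole of radius $R_w$; one level over
$(R_w, R_w + D_1]$; head/chain/head levels over
$(R_w+D_1, R_w+D_1+D_2+D_3]$) takes its level thicknesses from the
remaining material volume per annulus area and its level SLDs from the
volume-weighted mean of the remaining material, which conserves the
removed volume and scattering length exactly (checked against grid and
Monte Carlo integration). Two consequences are documented rather than
hidden: the pore curve crosses *above* the pore-free curve inside the
form-factor minima (the pore partially fills them in), so "below the
pore-free curve" holds for $q$ below the first minimum; and as
$R_w \to 0$ a residual funnel dimple remains (the torus tube radius stays
$t_b/2$), so the island excess decreases monotonically but does not vanish
identically at $R_w = 0$.

# The synthetic-experiment generator

`simulateExperiment()` and `simulateDomainProtocol()` add Gaussian noise
with standard deviation proportional to the square root of the model
intensity, $\sigma(q) = \epsilon\sqrt{I(q)}$, the heteroscedasticity
characteristic of counting detectors after absolute calibration. The noise
constant defaults to 3% relative uncertainty at the first local intensity
maximum — a typical quality for a synchrotron SAXS or reactor SANS curve
on a 3 mM lipid sample. The generator emulates: the $q$-dependence of
counting noise, absolute scale, and the joint SAXS/SANS contrast
situation ($x_D = 1$). It does not emulate instrument resolution
smearing, incoherent backgrounds beyond a flat term, inter-curve
calibration offsets, or correlated systematics — so passing recovery tests
demonstrates identifiability of the model parameters under ideal counting
noise, not robustness to instrumental artefacts in real data.

The reference refit protocol simulates four curves (SAXS and SANS at
$x_D = 1$, for the pure host bilayer and for fluid domains of $R_1 = 60$ Å
on a lattice with $a = 150$ Å, $g_a = 0.3$, at 3 mM host lipid) on 200
log-spaced points in $q \in [0.01, 0.6]$ Å$^{-1}$, and refits all 24 host
and guest profile parameters plus $R_1$ and $g_a$ simultaneously. The
instrumental scale is fixed at its simulated value: the data are synthetic
absolute-scale curves, and with free per-curve scales the absolute SLDs
would be non-identifiable (only SLD ratios shape the curves) — consistent
with recovered densities being meaningful to three or four digits.
Start values are the package's reference lipid table, which differs from
the protocol truth in every parameter.

# Numerical choices

* Gauss–Legendre everywhere: zenith 256 nodes (64 inside the refit
  protocol, where generator and fit share the same quadrature;
  convergence is re-checked in the tests), azimuth 64 nodes on
  $[30°, 120°]$.
* Series switch-overs: $J_1(x)/x$ below $|x| < 10^{-4}$; the profile
  transform's forward limit below $q < 10^{-8}$ Å$^{-1}$.
* Optimizer: bounded Levenberg–Marquardt (`minpack.lm`) on
  $\sigma$-weighted residuals; multi-start available (perturbed starts
  within bounds, seeded), single start from the reference table for the
  refit protocol; uncertainties from the SVD pseudo-inverse of the
  Gauss–Newton Hessian scaled by the reduced $\chi^2$, so weakly
  identified directions (the guest CH$_2$/CH$_3$ split, deep-profile
  neutron SLDs — visibly biased in any refit of this protocol) report
  large, finite uncertainties instead of breaking the solve.
* Degenerate inputs are contracts, not warnings: non-positive $q$,
  $R_{in} \ge R_{out}$, occupancies outside $[0,1]$, lattice spacing below
  twice the island radius, flat form-factor curves, and missing
  uncertainties in fits all raise errors.

# The Monte Carlo oracle

`bruteForceIntensity()` is a test instrument, not a production path: it
averages $|A|^2/N$ over explicit finite-lattice realizations, stack
displacements and orientations, using the exact finite-sheet transform
(no delta asymptotics) and explicit sums over island phase factors. Two of
its design points matter for interpreting agreement. First, island
coverage: the analytic model assumes islands uniformly cover the sheet, so
the oracle oversizes the rhombus lattice patch to tile the whole disc and
clips islands to radius $R_b - R_{max}$ (a patch smaller than the disc
biases the coherent island terms by exactly the uncovered-area fraction).
Second, orientations are sampled by stratified Monte Carlo in
$\cos\beta$ with geometrically refined strata near $q_\parallel = 0$,
where the finite-sheet transform peaks; standard errors come from the
spread over independent realizations. Residual deviations of order a few
percent at the sharpest form-factor minima are finite-$R_b$ effects and
shrink visibly as $R_b$ grows (the tests run $R_b = 8000$ Å with about
10⁴ islands, and the island-free convergence study verifies the trend).

# Problem sizes

The test suite runs the refit protocol once (4 curves × 200 points, 26
free parameters, single start), the oracle on two systems at $R_b = 8000$
Å with 8 realizations each, and Monte Carlo oracles for the structure
factors at a few hundred to a few thousand realizations; these sizes keep
statistical power while completing in minutes. The acceptance script uses
the same protocol sizes.

# Known limitations

* Planar geometry only: no vesicle curvature, size distribution, or
  inter-vesicle interference.
* No correlation between vertical stacking and in-plane island positions;
  islands in different bilayers are independent.
* No instrument resolution smearing; backgrounds are flat.
* The 2D paracrystal product structure factor is anisotropic by
  construction (see above); physical systems with true six-fold
  correlations are approximated.
* Chemical-group (atomistic) lipid parameterization is out of scope; the
  lipid table is a fixture. Protein form factors enter only through the
  core–shell condensation, not from atomic coordinates.
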
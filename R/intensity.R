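#' Surface density of islands on the hexagonal lattice
#'
#' \deqn{n_d = 2/(\sqrt{3}\, a^2),} the reciprocal of the hexagonal
#' unit-cell area \eqn{(\sqrt{3}/2) a^2}.
#'
#' @param a lattice parameter (Angstrom), > 0
#' @return island surface density (1/Angstrom^2)
#' @export
islandDensity <- function(a) {
  stopifnot(all(a > 0))
  2 / (sqrt(3) * a^2)
}

#' Effective bilayer thickness (volume per unit area)
#'
#' Volume of one bilayer with islands divided by its area: the island-free
#' thickness plus the surface-density-weighted difference between each
#' shell's material thickness and the host thickness,
#' \deqn{t_{\mathrm{eff}} = t_b + n_d \sum_k \pi (R_k^2 - R_{k-1}^2)
#'       (t_k - t_b).}
#' Island-free systems reduce to the total host thickness; a water-hole
#' shell (zero levels) removes material.
#'
#' @param system a \code{MembraneSystem}
#' @return effective thickness (Angstrom)
#' @export
bilayerVolumePerArea <- function(system) {
  stopifnot(is(system, "MembraneSystem"))
  tb <- totalThickness(system@bilayer)
  if (is.null(system@island)) return(tb)
  nd <- islandDensity(system@lattice@a)
  radii <- c(0, system@island@radii)
  tk <- vapply(system@island@profiles, totalThickness, numeric(1))
  rings <- pi * diff(radii^2)
  tb + nd * sum(rings * (tk - tb))
}

#' Sample volume fraction from concentrations and molecular volumes
#'
#' \deqn{c_V = N_A \sum_i C_i v_i} with concentrations in mM and molecular
#' volumes in Angstrom^3 (dimensionless result).
#'
#' @param concentrations molar concentrations (mM), nonnegative
#' @param volumes molecular volumes (Angstrom^3), nonnegative
#' @return volume fraction
#' @export
volumeFraction <- function(concentrations, volumes) {
  stopifnot(length(concentrations) == length(volumes),
            all(concentrations >= 0), all(volumes >= 0))
  ## mM * Angstrom^3: 1 mM = 1e-3 mol / 1e27 Angstrom^3
  sum(.N_AVOGADRO * concentrations * 1e-3 * 1e-27 * volumes)
}

#' Orientationally averaged scattering cross section per bilayer, per area
#'
#' Assembles the two terms of the large-radius (flat-sheet) reduction of the
#' island-containing bilayer cross section:
#' \enumerate{
#'   \item the coherent mean-sheet term: the flat-sheet Lorentz factor
#'     \eqn{2\pi/q^2} times the stacking structure factor times
#'     \eqn{|\bar{A}(q)|^2}, where
#'     \eqn{\bar{A}(q) = A_b(q) + n_d A_i(q, 0)} is the laterally averaged
#'     excess amplitude per unit area (host bilayer plus the area-density
#'     weighted forward island excess).  This term carries the island
#'     contribution that is coherent with the sheet (the
#'     \eqn{q_\parallel \approx 0} part of the island sum) and yields both
#'     homogeneous-mixture limits (small islands; large lattice spacing).
#'   \item the island fluctuation term: the zenith average (Gauss-Legendre
#'     in \eqn{\cos\beta}, open rule excluding \eqn{q_\parallel = 0}) of
#'     \eqn{n_d |A_i(q\cos\beta, q\sin\beta)|^2
#'     \bar{S}_{dd}(q\sin\beta)} with the azimuthally averaged infinite
#'     2D-paracrystal island-island structure factor.  Island positions are
#'     uncorrelated across bilayers, so this term carries no stacking
#'     factor.
#' }
#'
#' @param system a \code{MembraneSystem}
#' @param q scattering vector moduli (1/Angstrom), > 0
#' @param nZenith Gauss-Legendre nodes for the zenith average
#' @param nAzimuth Gauss-Legendre nodes for the azimuthal average of the
#'   island-island structure factor
#' @return real nonnegative values (dimensionless; per bilayer, per unit
#'   area)
#' @export
perBilayerCrossSection <- function(system, q, nZenith = 256, nAzimuth = 64) {
  stopifnot(is(system, "MembraneSystem"))
  if (any(q <= 0)) stop("q must be positive")
  Ab <- profileExcessAmplitude(system@bilayer, q)
  Z <- stackSF(q, system@stack)
  isl <- system@island
  if (is.null(isl)) return(2 * pi / q^2 * Z * Mod(Ab)^2)

  nd <- islandDensity(system@lattice@a)
  Abar <- Ab + nd * islandAmplitude(isl, system@bilayer, q, 0)
  sheet <- 2 * pi / q^2 * Z * Mod(Abar)^2

  gl <- .gaussLegendre(nZenith, 0, 1)     # open rule: endpoints excluded
  u <- gl$x
  s <- sqrt(pmax(0, 1 - u^2))
  nq <- length(q)
  qperp <- outer(q, u)                    # nq x nu
  qpar <- outer(q, s)
  Ai <- islandAmplitude(isl, system@bilayer, as.numeric(qperp),
                        as.numeric(qpar))
  Sdd <- islandIslandSF(as.numeric(qpar), system@lattice,
                        nAzimuth = nAzimuth)
  fluct <- matrix(Mod(Ai)^2 * Sdd, nq, nZenith) %*% gl$w
  sheet + nd * as.numeric(fluct)
}

#' Macroscopic differential scattering cross section
#'
#' \deqn{I(q) = \kappa \, \frac{c_V}{t_{\mathrm{eff}}}
#'       \left.\frac{d\Sigma}{d\Omega}\right|_{\mathrm{bilayer,area}}(q)
#'       \times 10^8 + B \quad [\mathrm{cm}^{-1}],}
#' the per-bilayer per-area cross section scaled by the sample volume
#' fraction over the effective bilayer thickness (so that the sheet radius
#' appears nowhere), an instrumental scale factor kappa and a flat
#' background B.  The factor 1e8 converts 1/Angstrom to 1/cm.
#'
#' @inheritParams perBilayerCrossSection
#' @param kappa instrumental scale factor, > 0
#' @param B flat background (cm^-1), >= 0
#' @return intensities (cm^-1)
#' @export
macroscopicIntensity <- function(system, q, kappa = 1, B = 0,
                                 nZenith = 256, nAzimuth = 64) {
  if (length(kappa) != 1 || !is.finite(kappa) || kappa <= 0)
    stop("kappa must be a single positive number")
  if (length(B) != 1 || !is.finite(B) || B < 0)
    stop("B must be a single nonnegative number")
  cV <- volumeFraction(system@concentrations, system@volumes)
  if (cV == 0) cV <- 1   # unnormalized curve when no concentrations given
  teff <- bilayerVolumePerArea(system)
  kappa * cV / teff *
    perBilayerCrossSection(system, q, nZenith, nAzimuth) * 1e8 + B
}
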
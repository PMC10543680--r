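#' Packaged lipid parameter table
#'
#' Reference parameterizations of DPPC (gel) and DOPC (fluid) symmetric
#' bilayers: area per molecule, molecular volume, and the three-region
#' half-profile (head, CH2-rich, CH3-rich) with X-ray electron densities,
#' neutron SLDs in pure D2O, and transition smoothness.
#'
#' @return data.frame, one row per species
#' @export
lipidTable <- function() {
  utils::read.csv(system.file("extdata", "lipids.csv",
                              package = "sasbilayer"),
                  stringsAsFactors = FALSE)
}

#' Retrieve a packaged lipid species
#'
#' @param name species name as in \code{lipidTable()} (e.g. "DPPC")
#' @return a \code{LipidSpecies}
#' @export
getLipid <- function(name) {
  tab <- lipidTable()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1) stop("unknown lipid species: ", name)
  lipidSpecies(row$name, row$area, row$volume,
               D = c(row$D1, row$D2, row$D3),
               rhoX = c(row$rhoX1, row$rhoX2, row$rhoX3),
               rhoN1e6 = c(row$rhoN1, row$rhoN2, row$rhoN3),
               sigma = c(row$sigma1, row$sigma2, row$sigma3))
}

#' Packaged protein core-shell cylinder table
#'
#' Core-shell cylinder parameterizations of four reference proteins
#' (aquaporin, bacteriorhodopsin, ATPase, cytochrome c): molecular weight and
#' volume, core radius R, shell thickness delta, occupancy fractions, length
#' L, and X-ray/neutron protein SLDs.
#'
#' @return data.frame, one row per protein
#' @export
proteinTable <- function() {
  utils::read.csv(system.file("extdata", "proteins.csv",
                              package = "sasbilayer"),
                  stringsAsFactors = FALSE)
}

#' Retrieve a packaged protein parameterization
#'
#' @param name protein name as in \code{proteinTable()}
#' @param deriveL if TRUE (default) derive L from the volume closure; if
#'   FALSE use the printed (rounded) L
#' @return a \code{CoreShellCylinderParams}
#' @export
getProtein <- function(name, deriveL = TRUE) {
  tab <- proteinTable()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1) stop("unknown protein: ", name)
  coreShellCylinderParams(R = row$R, delta = row$delta, phiI = row$phiI,
                          phiE = row$phiE, Vp = row$Vp,
                          L = if (deriveL) NULL else row$L,
                          rhoPX = row$rhoPX, rhoPN = row$rhoPN * 1e-6)
}

#' Guest concentration implied by the domain unit-cell balance
#'
#' Per unit cell, the guest lipid occupies the domain disc and the host the
#' remaining area; with both leaflets contributing equally the molecule
#' balance gives
#' \deqn{C_{guest} = C_{host} \frac{a_{host}}{a_{guest}}
#'       \frac{\pi R_1^2}{(\sqrt{3}/2) a^2 - \pi R_1^2}.}
#'
#' @param C_host host lipid concentration (mM)
#' @param a lattice parameter (Angstrom), must exceed 2 R1
#' @param R1 domain radius (Angstrom)
#' @param aHost host area per molecule (Angstrom^2)
#' @param aGuest guest area per molecule (Angstrom^2)
#' @return guest concentration (mM)
#' @export
domainConcentration <- function(C_host, a, R1, aHost, aGuest) {
  if (a <= 2 * R1) stop("lattice parameter must exceed twice the domain radius")
  rest <- sqrt(3) / 2 * a^2 - pi * R1^2
  if (rest <= 0) stop("domain area exceeds the unit cell")
  C_host * (aHost / aGuest) * pi * R1^2 / rest
}

#' Protein concentration implied by the lattice parameter
#'
#' \deqn{C_p = C_b\, a_{host} / [\sqrt{3}\, a^2 - 2 \xi a_p],} with
#' \eqn{a_p} the protein footprint toward the bilayer plane
#' (\eqn{\pi (R+\delta)^2}) and \eqn{\xi} the embedding fraction (0 anchored,
#' 1/2 monotopic, 1 transmembrane); an anchored protein removes no lipid.
#'
#' @param C_b host lipid concentration (mM)
#' @param a lattice parameter (Angstrom)
#' @param ap protein footprint area (Angstrom^2)
#' @param xi embedding fraction in [0, 1]
#' @param aHost host area per molecule (Angstrom^2)
#' @return protein concentration (mM)
#' @export
proteinConcentration <- function(C_b, a, ap, xi = 1, aHost = 57) {
  if (xi < 0 || xi > 1) stop("xi must lie in [0, 1]")
  denom <- sqrt(3) * a^2 - 2 * xi * ap
  if (denom <= 0) stop("protein footprint exceeds the unit cell")
  C_b * aHost / denom
}

#' Build a lipid-domain membrane system
#'
#' Single-shell island of radius R1 carrying the guest lipid's symmetric
#' 5-level profile as excess over the host bilayer; guest concentration set
#' by \code{domainConcentration}.
#'
#' @param host,guest \code{LipidSpecies}
#' @param a lattice parameter (Angstrom), > 2 R1
#' @param R1 domain radius (Angstrom)
#' @param ga lattice distortion factor
#' @param C_host host concentration (mM)
#' @param probe a \code{ProbeContrast}
#' @param stack a \code{StackModel}
#' @return a \code{MembraneSystem}
#' @export
buildDomainSystem <- function(host, guest, a, R1, ga, C_host = 3,
                              probe = probeContrast("xray"),
                              stack = stackModel()) {
  stopifnot(is(host, "LipidSpecies"), is(guest, "LipidSpecies"))
  bil <- bilayerProfile(host, probe)
  dom <- bilayerProfile(guest, probe)
  isl <- island(R1, list(dom))
  Cg <- domainConcentration(C_host, a, R1, host@area, guest@area)
  conc <- stats::setNames(c(C_host, Cg), c(host@name, guest@name))
  vols <- stats::setNames(c(host@volume, guest@volume),
                          c(host@name, guest@name))
  membraneSystem(bil, isl, paracrystalLattice(a, ga), stack, conc, vols,
                 probe)
}

## Occupancy-mixed SLD of a protein region: phi parts protein, rest solvent.
.mixedSLD <- function(phi, rhoP, rhoSolv) phi * rhoP + (1 - phi) * rhoSolv

## Protein SLD for the probe carried by a bilayer profile.
.proteinSLD <- function(params, probe) {
  if (probe@probe == "xray") electronDensityToSLD(params@rhoPX)
  else params@rhoPN
}

#' Build a transmembrane protein island
#'
#' Two cylindrical shells with radii R and R + delta; each carries a single
#' level of thickness L whose SLD mixes the protein SLD with the solvent by
#' the core/shell occupancy fractions.  \code{embed = "full"} centres the
#' protein in the bilayer (z = -L/2); \code{embed = "half"} places it with
#' one quarter below the mid-plane (z = -L/4), as appropriate when about
#' half the protein length protrudes.
#'
#' @param R core radius (Angstrom)
#' @param delta shell thickness (Angstrom)
#' @param phiI,phiE core/shell occupancy fractions in [0, 1]
#' @param L cylinder length (Angstrom)
#' @param rhoP protein SLD (1/Angstrom^2, matching the bilayer's probe)
#' @param embed "full" or "half"
#' @param bilayer host bilayer \code{SLDLevelProfile} (supplies the solvent
#'   SLD)
#' @return an \code{Island}
#' @export
buildTransmembraneProtein <- function(R, delta, phiI, phiE, L, rhoP,
                                      embed = c("full", "half"), bilayer) {
  embed <- match.arg(embed)
  if (any(c(phiI, phiE) < 0) || any(c(phiI, phiE) > 1))
    stop("occupancy fractions must lie in [0, 1]")
  stopifnot(R > 0, delta > 0, L > 0)
  rhoS <- bilayer@sldSolvent
  z0 <- if (embed == "full") -L / 2 else -L / 4
  core <- sldProfile(L, .mixedSLD(phiI, rhoP, rhoS), smoothness = 0,
                     zBase = z0, sldSolvent = rhoS)
  shell <- sldProfile(L, .mixedSLD(phiE, rhoP, rhoS), smoothness = 0,
                      zBase = z0, sldSolvent = rhoS)
  island(c(R, R + delta), list(core, shell))
}

#' Build an anchored, monotopic or transmembrane protein island
#'
#' Geometry selected by the embedding fraction xi:
#' \itemize{
#'   \item xi = 0 (anchored): both shells carry the five bilayer levels plus
#'     a sixth protein level of thickness L sitting on the membrane surface;
#'   \item xi = 1/2 (monotopic): both shells carry the lower three bilayer
#'     levels (head, CH2, CH3) with a fourth protein level of thickness L
#'     replacing the upper portion;
#'   \item xi = 1 (transmembrane): as \code{buildTransmembraneProtein} with
#'     \code{embed = "full"}.
#' }
#' Within each shell the protein level SLD mixes the protein SLD with
#' solvent by that shell's occupancy fraction.
#'
#' @param params a \code{CoreShellCylinderParams}
#' @param xi embedding fraction: 0, 0.5 or 1
#' @param bilayer host bilayer \code{SLDLevelProfile} (5-level symmetric)
#' @param probe the \code{ProbeContrast} used to build \code{bilayer}
#' @return an \code{Island}
#' @export
buildPeripheralProtein <- function(params, xi, bilayer,
                                   probe = probeContrast("xray")) {
  stopifnot(is(params, "CoreShellCylinderParams"))
  if (!xi %in% c(0, 0.5, 1)) stop("xi must be 0, 0.5 or 1")
  rhoP <- .proteinSLD(params, probe)
  rhoS <- bilayer@sldSolvent
  if (xi == 1)
    return(buildTransmembraneProtein(params@R, params@delta, params@phiI,
                                     params@phiE, params@L, rhoP,
                                     "full", bilayer))
  if (length(bilayer@thickness) != 5)
    stop("peripheral geometries require the 5-level symmetric bilayer")
  shellFor <- function(phi) {
    mix <- .mixedSLD(phi, rhoP, rhoS)
    if (xi == 0) {
      ## bilayer levels + protein level above the upper surface
      D <- c(bilayer@thickness, params@L)
      rho <- c(bilayer@sld, mix)
      sig <- c(bilayer@smoothness[seq_len(5)], 0, 0)
      sldProfile(D, rho, smoothness = sig, zBase = bilayer@zBase,
                 sldSolvent = rhoS)
    } else {
      ## lower three bilayer levels + protein level replacing the top
      D <- c(bilayer@thickness[1:3], params@L)
      rho <- c(bilayer@sld[1:3], mix)
      sig <- c(bilayer@smoothness[1:4], 0)
      sldProfile(D, rho, smoothness = sig, zBase = bilayer@zBase,
                 sldSolvent = rhoS)
    }
  }
  island(c(params@R, params@R + params@delta),
         list(shellFor(params@phiI), shellFor(params@phiE)))
}

#' Build a protein-containing membrane system
#'
#' Convenience wrapper: builds the host bilayer for the probe, the protein
#' island for the requested geometry, and the stoichiometric concentrations.
#'
#' @param host a \code{LipidSpecies}
#' @param params a \code{CoreShellCylinderParams}
#' @param a lattice parameter (Angstrom)
#' @param ga lattice distortion factor
#' @param C_host host concentration (mM)
#' @param xi embedding fraction: 0, 0.5 or 1
#' @param embed "full" or "half" vertical positioning for transmembrane
#'   proteins
#' @param probe a \code{ProbeContrast}
#' @param stack a \code{StackModel}
#' @return a \code{MembraneSystem}
#' @export
buildProteinSystem <- function(host, params, a, ga, C_host = 3, xi = 1,
                               embed = c("full", "half"),
                               probe = probeContrast("xray"),
                               stack = stackModel()) {
  embed <- match.arg(embed)
  bil <- bilayerProfile(host, probe)
  isl <- if (xi == 1)
    buildTransmembraneProtein(params@R, params@delta, params@phiI,
                              params@phiE, params@L,
                              .proteinSLD(params, probe), embed, bil)
  else buildPeripheralProtein(params, xi, bil, probe)
  ap <- pi * (params@R + params@delta)^2
  Cp <- proteinConcentration(C_host, a, ap, xi, host@area)
  conc <- stats::setNames(c(C_host, Cp), c(host@name, "protein"))
  vols <- stats::setNames(c(host@volume, params@Vp), c(host@name, "protein"))
  membraneSystem(bil, isl, paracrystalLattice(a, ga), stack, conc, vols,
                 probe)
}

## ---- toroidal pore mapping -------------------------------------------------

## Half-height of the lipid material at radial distance s from the pore axis,
## bounded by the inner surface of a torus of tube radius rt whose waist
## radius is Rw (pore water where s < Rw + rt - sqrt(rt^2 - z^2)).
.poreLipidHalfHeight <- function(s, Rw, rt) {
  ifelse(s >= Rw + rt, rt,
         ifelse(s <= Rw, 0, sqrt(pmax(0, rt^2 - (Rw + rt - s)^2))))
}

.annulusIntegral <- function(fun, r1, r2) {
  f <- function(s) 2 * pi * s * fun(s)
  stats::integrate(f, r1, r2, rel.tol = 1e-10,
                   subdivisions = 1000L)$value
}

#' Torus-segment volumes and scattering lengths of a toroidal pore
#'
#' The pore is the water region bounded by the inner surface of a torus of
#' tube radius \code{rt} (the bilayer half-thickness) and waist radius
#' \code{Rw}: at radial distance s from the pore axis the remaining lipid
#' occupies \code{|z| <= z*(s)} with
#' \code{z*(s) = sqrt(rt^2 - (Rw + rt - s)^2)}; the funnel carves the
#' otherwise unperturbed bilayer profile (no SLD rearrangement).  This
#' helper integrates, per radial zone, the remaining material volumes and
#' (sharp-profile) scattering lengths: zone A \code{[Rw, Rw + D1]} as a
#' whole, zone B \code{[Rw + D1, R3]} split into the chain region
#' (\code{|z| <= D2 + D3/2}) and the head region above it.
#'
#' @param Rw pore waist radius (Angstrom), > 0
#' @param bilayer host 5-level symmetric \code{SLDLevelProfile}
#' @return list with volumes \code{VA}, \code{VBchain}, \code{VBhead}
#'   (Angstrom^3), mean SLDs \code{rhoA}, \code{rhoBchain} (1/Angstrom^2)
#'   and geometry \code{R2}, \code{R3}
#' @keywords internal
.poreSegments <- function(Rw, bilayer) {
  D <- bilayer@thickness
  D1 <- D[1]; D2 <- D[2]; D3 <- D[3]
  rt <- sum(D) / 2
  zc <- D2 + D3 / 2                  # chain-region half-extent
  R2 <- Rw + D1
  R3 <- Rw + D1 + D2 + D3
  rho <- bilayer@sld                  # head, CH2, CH3, CH2, head
  zs <- function(s) .poreLipidHalfHeight(s, Rw, rt)
  ## remaining chain material below |z| = m(s): CH3 core plus CH2
  chainSL <- function(m) 2 * (rho[3] * pmin(m, D3 / 2) +
                              rho[2] * pmax(0, m - D3 / 2))
  VA <- .annulusIntegral(function(s) 2 * zs(s), Rw, R2)
  SA <- .annulusIntegral(function(s) {
    m <- pmin(zs(s), zc)
    chainSL(m) + 2 * rho[1] * pmax(0, zs(s) - zc)
  }, Rw, R2)
  VBchain <- .annulusIntegral(function(s) 2 * pmin(zs(s), zc), R2, R3)
  SBchain <- .annulusIntegral(function(s) chainSL(pmin(zs(s), zc)), R2, R3)
  VBhead <- .annulusIntegral(function(s) 2 * pmax(0, zs(s) - zc), R2, R3)
  list(VA = VA, VBchain = VBchain, VBhead = VBhead,
       rhoA = SA / VA, rhoBchain = SBchain / VBchain, R2 = R2, R3 = R3)
}

#' Build a toroidal water pore island
#'
#' Maps the inner-torus pore geometry onto a three-shell cylinder island:
#' shell 1 (radius R_w) is a water hole through the whole bilayer; shell 2
#' \code{(R_w, R_w + D_1]} carries one level; shell 3
#' \code{(R_w + D_1, R_w + D_1 + D_2 + D_3]} carries three symmetric levels
#' (head / chain / head).  The pore is a water funnel carved out of the
#' otherwise unperturbed bilayer: level thicknesses equal the remaining
#' material volume per unit annulus area (so every mapped shell volume
#' equals the corresponding torus-segment volume), and level SLDs are the
#' volume-weighted means of the remaining material, which conserves the
#' island's excess scattering length exactly.  All level parameters are
#' solved from the volume-equality conditions by numerical integration of
#' the torus-segment volumes.
#'
#' @param Rw pore waist radius (Angstrom), > 0
#' @param bilayer host bilayer \code{SLDLevelProfile} in the 5-level
#'   symmetric form
#' @return an \code{Island}
#' @export
buildPore <- function(Rw, bilayer) {
  stopifnot(is(bilayer, "SLDLevelProfile"))
  if (Rw <= 0) stop("pore radius must be positive")
  D <- bilayer@thickness
  if (length(D) != 5 || abs(D[1] - D[5]) > 1e-9 || abs(D[2] - D[4]) > 1e-9)
    stop("buildPore requires the 5-level symmetric bilayer profile")
  rt <- sum(D) / 2
  if (rt <= D[1]) stop("bilayer too thin for the toroidal pore mapping")
  rhoS <- bilayer@sldSolvent
  seg <- .poreSegments(Rw, bilayer)
  areaA <- pi * (seg$R2^2 - Rw^2)
  areaB <- pi * (seg$R3^2 - seg$R2^2)
  DA <- seg$VA / areaA
  Dch <- seg$VBchain / areaB
  Dhd <- seg$VBhead / 2 / areaB
  if (!is.finite(DA) || !is.finite(Dch) || !is.finite(Dhd) ||
      DA <= 0 || Dch <= 0 || Dhd <= 0)
    stop("pore level solving degenerated (Rw too small for this bilayer)")
  sig <- bilayer@smoothness
  hole <- sldProfile(numeric(0), numeric(0), smoothness = sig[1],
                     zBase = 0, sldSolvent = rhoS)
  rim <- sldProfile(DA, seg$rhoA, smoothness = c(sig[1], sig[1]),
                    zBase = -DA / 2, sldSolvent = rhoS)
  outerShell <- sldProfile(c(Dhd, Dch, Dhd),
                           c(bilayer@sld[1], seg$rhoBchain, bilayer@sld[1]),
                           smoothness = c(sig[1], sig[2], sig[2], sig[1]),
                           zBase = -(Dch / 2 + Dhd), sldSolvent = rhoS)
  island(c(Rw, seg$R2, seg$R3), list(hole, rim, outerShell))
}

#' Build a pore-containing membrane system
#'
#' @param host a \code{LipidSpecies}
#' @param Rw pore waist radius (Angstrom)
#' @param a lattice parameter (Angstrom)
#' @param ga lattice distortion factor
#' @param C_host host concentration (mM)
#' @param probe a \code{ProbeContrast}
#' @param stack a \code{StackModel}
#' @return a \code{MembraneSystem}
#' @export
buildPoreSystem <- function(host, Rw, a, ga, C_host = 3,
                            probe = probeContrast("xray"),
                            stack = stackModel()) {
  bil <- bilayerProfile(host, probe)
  isl <- buildPore(Rw, bil)
  conc <- stats::setNames(C_host, host@name)
  vols <- stats::setNames(host@volume, host@name)
  membraneSystem(bil, isl, paracrystalLattice(a, ga), stack, conc, vols,
                 probe)
}

#' Build a plain single-lipid bilayer system
#'
#' @param host a \code{LipidSpecies}
#' @param C_host concentration (mM)
#' @param probe a \code{ProbeContrast}
#' @param stack a \code{StackModel}
#' @return a \code{MembraneSystem}
#' @export
buildBilayerSystem <- function(host, C_host = 3,
                               probe = probeContrast("xray"),
                               stack = stackModel()) {
  bil <- bilayerProfile(host, probe)
  membraneSystem(bil, NULL, paracrystalLattice(1e6, 0.3), stack,
                 stats::setNames(C_host, host@name),
                 stats::setNames(host@volume, host@name), probe)
}
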
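#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Multi-level erf-smoothed scattering length density profile
#'
#' An \code{SLDLevelProfile} represents a one-dimensional SLD profile along
#' the bilayer normal z as a sequence of constant levels with error-function
#' transitions.  Level j occupies \code{[z_j, z_j + D_j]} with
#' \code{z_{j+1} = z_j + D_j}; below level 1 and above the last level the
#' profile tends to the solvent SLD.  Transition j (between level j-1 and
#' level j) has smoothness \code{sigma_j}; there are \code{nLevels + 1}
#' transitions including the closing one to solvent.  A profile with zero
#' levels is a pure-solvent region (used for water holes in pores).
#'
#' @slot thickness numeric vector of level thicknesses D_j (Angstrom)
#' @slot sld numeric vector of level SLDs rho_j (1/Angstrom^2)
#' @slot smoothness numeric vector of length nLevels + 1, transition widths
#'   sigma_j (Angstrom)
#' @slot zBase lower edge of level 1 (Angstrom)
#' @slot sldSolvent solvent SLD (1/Angstrom^2)
#' @export
setClass("SLDLevelProfile",
  representation(
    thickness  = "numeric",
    sld        = "numeric",
    smoothness = "numeric",
    zBase      = "numeric",
    sldSolvent = "numeric"
  ),
  prototype(thickness = numeric(0), sld = numeric(0),
            smoothness = 0, zBase = 0, sldSolvent = 0)
)

setValidity("SLDLevelProfile", function(object) {
  n <- length(object@thickness)
  msgs <- character(0)
  if (length(object@sld) != n)
    msgs <- c(msgs, "lengths of 'thickness' and 'sld' must match")
  if (n > 0 && any(object@thickness <= 0))
    msgs <- c(msgs, "all level thicknesses must be positive")
  if (length(object@smoothness) != max(n + 1, 1))
    msgs <- c(msgs, "smoothness must have length nLevels + 1")
  if (any(object@smoothness < 0))
    msgs <- c(msgs, "smoothness values must be nonnegative")
  if (length(object@zBase) != 1 || !is.finite(object@zBase))
    msgs <- c(msgs, "zBase must be a single finite number")
  if (length(object@sldSolvent) != 1 || !is.finite(object@sldSolvent))
    msgs <- c(msgs, "sldSolvent must be a single finite number")
  if (length(msgs)) msgs else TRUE
})

#' Construct an SLD level profile
#'
#' @param thickness level thicknesses D_j (Angstrom)
#' @param sld level SLDs; in 1/Angstrom^2 when \code{units = "sld"}, in
#'   e/Angstrom^3 when \code{units = "electron"} (converted on construction
#'   via the classical electron radius)
#' @param smoothness transition widths sigma (Angstrom); either one value per
#'   transition (nLevels + 1), one per level (recycled with the first value
#'   reused for the closing transition), or a single value
#' @param zBase lower edge of level 1 (Angstrom)
#' @param sldSolvent solvent SLD, same units convention as \code{sld}
#' @param units \code{"sld"} or \code{"electron"}
#' @return an \code{SLDLevelProfile}
#' @export
sldProfile <- function(thickness, sld, smoothness = 0, zBase = 0,
                       sldSolvent = 0, units = c("sld", "electron")) {
  units <- match.arg(units)
  if (units == "electron") {
    sld <- electronDensityToSLD(sld)
    sldSolvent <- electronDensityToSLD(sldSolvent)
  }
  n <- length(thickness)
  nt <- max(n + 1, 1)
  if (length(smoothness) == 1) smoothness <- rep(smoothness, nt)
  else if (length(smoothness) == n) smoothness <- c(smoothness, smoothness[1])
  new("SLDLevelProfile", thickness = as.numeric(thickness),
      sld = as.numeric(sld), smoothness = as.numeric(smoothness),
      zBase = as.numeric(zBase), sldSolvent = as.numeric(sldSolvent))
}

#' Cylindrical island of concentric SLD shells
#'
#' An island is an ordered set of concentric cylindrical shells with strictly
#' increasing outer radii; shell k occupies the annulus
#' \code{(R_{k-1}, R_k]} with \code{R_0 = 0} and carries its own z-profile
#' (absolute SLD within the shell; the scattering amplitude uses the excess
#' over the host bilayer profile).  A shell whose profile has zero levels is
#' a water hole.
#'
#' @slot radii strictly increasing outer shell radii (Angstrom)
#' @slot profiles list of \code{SLDLevelProfile}, one per shell
#' @export
setClass("Island",
  representation(radii = "numeric", profiles = "list"))

setValidity("Island", function(object) {
  msgs <- character(0)
  r <- object@radii
  if (length(r) < 1) msgs <- c(msgs, "island needs at least one shell")
  if (any(r <= 0) || any(diff(r) <= 0))
    msgs <- c(msgs, "radii must be positive and strictly increasing")
  if (length(object@profiles) != length(r))
    msgs <- c(msgs, "one profile per shell required")
  if (!all(vapply(object@profiles, is, logical(1), class2 = "SLDLevelProfile")))
    msgs <- c(msgs, "profiles must be SLDLevelProfile objects")
  if (length(msgs)) msgs else TRUE
})

#' @param radii strictly increasing outer shell radii (Angstrom)
#' @param profiles list of \code{SLDLevelProfile}, one per shell
#' @rdname Island-class
#' @export
island <- function(radii, profiles) {
  if (is(profiles, "SLDLevelProfile")) profiles <- list(profiles)
  new("Island", radii = as.numeric(radii), profiles = profiles)
}

#' Distorted two-dimensional hexagonal paracrystal lattice
#'
#' In-plane island arrangement: unit-cell vectors of length \code{a} at 60
#' degrees, cumulative Gaussian distortion of relative width \code{ga}
#' (sigma_a = ga * a).  \code{Na} is the average number of islands per lattice
#' direction, used only by finite-lattice diagnostics (the analytic pipeline
#' works in the infinite-lattice limit).
#'
#' @slot a lattice parameter, average island-island distance (Angstrom)
#' @slot ga dimensionless distortion factor
#' @slot Na average islands per lattice direction (finite-lattice diagnostics)
#' @export
setClass("ParacrystalLattice2D",
  representation(a = "numeric", ga = "numeric", Na = "numeric"),
  prototype(Na = 24))

setValidity("ParacrystalLattice2D", function(object) {
  msgs <- character(0)
  if (length(object@a) != 1 || object@a <= 0)
    msgs <- c(msgs, "lattice parameter a must be a single positive number")
  if (length(object@ga) != 1 || object@ga < 0)
    msgs <- c(msgs, "distortion factor ga must be nonnegative")
  if (length(object@Na) != 1 || object@Na < 1)
    msgs <- c(msgs, "Na must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @param a lattice parameter (Angstrom)
#' @param ga dimensionless distortion factor (sigma_a = ga * a)
#' @param Na average islands per lattice direction (diagnostics only)
#' @rdname ParacrystalLattice2D-class
#' @export
paracrystalLattice <- function(a, ga, Na = 24)
  new("ParacrystalLattice2D", a = as.numeric(a), ga = as.numeric(ga),
      Na = as.numeric(Na))

#' Vertical bilayer stacking model
#'
#' Describes a stack of N bilayers with average repeat distance c.  Disorder
#' follows either one-dimensional paracrystal theory (PT, Gaussian
#' distortion \code{gcPerp}) or the modified Caille theory (MCT, Caille
#' parameter \code{eta1}).  When only one of \code{gcPerp}/\code{eta1} is
#' given the other is filled in through the Zhang relation
#' \code{gcPerp = sqrt(0.087 * eta1)}.  A discrete Gaussian polydispersity of
#' relative width \code{polyWidth} over N suppresses the low-q oscillations
#' of the monodisperse paracrystalline structure factor.
#'
#' @slot N average number of bilayers per stack (>= 1)
#' @slot c stacking distance (Angstrom)
#' @slot theory "PT" or "MCT"
#' @slot gcPerp perpendicular distortion factor (PT)
#' @slot eta1 Caille parameter (MCT)
#' @slot polyWidth relative width of the discrete Gaussian over N
#' @export
setClass("StackModel",
  representation(N = "numeric", c = "numeric", theory = "character",
                 gcPerp = "numeric", eta1 = "numeric", polyWidth = "numeric"),
  prototype(N = 1, c = 65, theory = "PT", gcPerp = 0, eta1 = 0,
            polyWidth = 0.3))

setValidity("StackModel", function(object) {
  msgs <- character(0)
  if (object@N < 1 || object@N != round(object@N))
    msgs <- c(msgs, "N must be an integer >= 1")
  if (object@c <= 0) msgs <- c(msgs, "stacking distance c must be positive")
  if (!object@theory %in% c("PT", "MCT"))
    msgs <- c(msgs, "theory must be 'PT' or 'MCT'")
  if (object@gcPerp < 0) msgs <- c(msgs, "gcPerp must be nonnegative")
  if (object@eta1 < 0) msgs <- c(msgs, "eta1 must be nonnegative")
  if (object@polyWidth < 0) msgs <- c(msgs, "polyWidth must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' @param N bilayers per stack
#' @param c stacking distance (Angstrom)
#' @param theory "PT" or "MCT"
#' @param gcPerp PT distortion factor; if missing and \code{eta1} given,
#'   derived via the Zhang relation
#' @param eta1 Caille parameter; if missing and \code{gcPerp} given, derived
#'   via the inverse Zhang relation
#' @param polyWidth relative width of the discrete Gaussian over N
#' @rdname StackModel-class
#' @export
stackModel <- function(N = 1, c = 65, theory = c("PT", "MCT"),
                       gcPerp = NULL, eta1 = NULL, polyWidth = 0.3) {
  theory <- match.arg(theory)
  if (is.null(gcPerp) && is.null(eta1)) { gcPerp <- 0; eta1 <- 0 }
  else if (is.null(gcPerp)) gcPerp <- zhangGFromEta(eta1)
  else if (is.null(eta1)) eta1 <- gcPerp^2 / 0.087
  new("StackModel", N = as.numeric(N), c = as.numeric(c), theory = theory,
      gcPerp = as.numeric(gcPerp), eta1 = as.numeric(eta1),
      polyWidth = as.numeric(polyWidth))
}

#' Probe contrast description
#'
#' @slot probe "xray" or "neutron"
#' @slot xD solvent deuteration fraction (neutron only)
#' @slot sldSolvent solvent SLD (1/Angstrom^2)
#' @export
setClass("ProbeContrast",
  representation(probe = "character", xD = "numeric", sldSolvent = "numeric"))

setValidity("ProbeContrast", function(object) {
  msgs <- character(0)
  if (!object@probe %in% c("xray", "neutron"))
    msgs <- c(msgs, "probe must be 'xray' or 'neutron'")
  if (object@xD < 0 || object@xD > 1)
    msgs <- c(msgs, "xD must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @param probe "xray" or "neutron"
#' @param xD solvent deuteration fraction in [0,1] (neutron only)
#' @param sldSolvent override for the solvent SLD (1/Angstrom^2); by default
#'   water electron density times the classical electron radius for X-rays and
#'   the H2O/D2O interpolation for neutrons
#' @rdname ProbeContrast-class
#' @export
probeContrast <- function(probe = c("xray", "neutron"), xD = 0,
                          sldSolvent = NULL) {
  probe <- match.arg(probe)
  if (is.null(sldSolvent)) {
    sldSolvent <- if (probe == "xray") electronDensityToSLD(.WATER_EDENS)
                  else solventNeutronSLD(xD)
  }
  new("ProbeContrast", probe = probe, xD = as.numeric(xD),
      sldSolvent = as.numeric(sldSolvent))
}

setClassUnion("IslandOrNULL", c("Island", "NULL"))

#' A complete membrane scattering system
#'
#' Bundles the host bilayer profile, an optional island with its in-plane
#' paracrystal lattice, the vertical stacking model, species concentrations
#' and molecular volumes (for the sample volume fraction), and the probe
#' contrast.  This is the unit of simulation and fitting.
#'
#' @slot bilayer host \code{SLDLevelProfile}
#' @slot island an \code{Island} or NULL
#' @slot lattice \code{ParacrystalLattice2D} (required when island present)
#' @slot stack \code{StackModel}
#' @slot concentrations named molar concentrations (mM)
#' @slot volumes named molecular volumes (Angstrom^3), same names
#' @slot probe \code{ProbeContrast}
#' @export
setClass("MembraneSystem",
  representation(bilayer = "SLDLevelProfile", island = "IslandOrNULL",
                 lattice = "ParacrystalLattice2D", stack = "StackModel",
                 concentrations = "numeric", volumes = "numeric",
                 probe = "ProbeContrast"))

setValidity("MembraneSystem", function(object) {
  msgs <- character(0)
  if (!is.null(object@island)) {
    rmax <- max(object@island@radii)
    if (object@lattice@a <= 2 * rmax)
      msgs <- c(msgs, sprintf(
        "lattice parameter a = %.3g must exceed twice the maximum island radius (2 x %.3g)",
        object@lattice@a, rmax))
  }
  if (length(object@concentrations) &&
      (is.null(names(object@concentrations)) ||
       !identical(names(object@concentrations), names(object@volumes))))
    msgs <- c(msgs, "concentrations and volumes must share names")
  if (any(object@concentrations < 0) || any(object@volumes < 0))
    msgs <- c(msgs, "concentrations and volumes must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' @param bilayer host \code{SLDLevelProfile}
#' @param island an \code{Island} or NULL for a plain bilayer
#' @param lattice \code{ParacrystalLattice2D}; ignored when no island
#' @param stack \code{StackModel}
#' @param concentrations named molar concentrations (mM)
#' @param volumes named molecular volumes (Angstrom^3)
#' @param probe \code{ProbeContrast}
#' @rdname MembraneSystem-class
#' @export
membraneSystem <- function(bilayer, island = NULL,
                           lattice = paracrystalLattice(1e6, 0.3),
                           stack = stackModel(),
                           concentrations = numeric(0),
                           volumes = numeric(0),
                           probe = probeContrast("xray")) {
  new("MembraneSystem", bilayer = bilayer, island = island, lattice = lattice,
      stack = stack, concentrations = concentrations, volumes = volumes,
      probe = probe)
}

#' A scattering curve
#'
#' @slot q scattering vector moduli (1/Angstrom), ascending
#' @slot I intensities
#' @slot sigma point uncertainties, or NULL when absent
#' @slot probe probe tag ("xray", "neutron" or "")
#' @slot label free-text label
#' @slot comments header comment lines preserved from file input
#' @export
setClass("ScatteringCurve",
  representation(q = "numeric", I = "numeric", sigma = "numericOrNULL",
                 probe = "character", label = "character",
                 comments = "character"),
  prototype(sigma = NULL, probe = "", label = "", comments = character(0)))

setValidity("ScatteringCurve", function(object) {
  msgs <- character(0)
  if (length(object@q) != length(object@I))
    msgs <- c(msgs, "q and I must have equal length")
  if (any(object@q <= 0)) msgs <- c(msgs, "q values must be positive")
  if (is.unsorted(object@q, strictly = TRUE))
    msgs <- c(msgs, "q must be strictly ascending")
  if (!is.null(object@sigma)) {
    if (length(object@sigma) != length(object@q))
      msgs <- c(msgs, "sigma must match q in length")
    if (any(object@sigma <= 0))
      msgs <- c(msgs, "sigma values must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param q scattering vector moduli (1/Angstrom)
#' @param I intensities
#' @param sigma optional point uncertainties
#' @param probe probe tag
#' @param label free-text label
#' @param comments preserved header comments
#' @rdname ScatteringCurve-class
#' @export
scatteringCurve <- function(q, I, sigma = NULL, probe = "", label = "",
                            comments = character(0)) {
  new("ScatteringCurve", q = as.numeric(q), I = as.numeric(I),
      sigma = if (is.null(sigma)) NULL else as.numeric(sigma),
      probe = probe, label = label, comments = comments)
}

#' Lipid species parameterization
#'
#' Half-profile description of a symmetric phospholipid bilayer: three
#' regions (polar head, CH2-rich intermediate, terminal CH3-rich), each with
#' thickness, X-ray electron density, neutron SLD (in pure D2O) and
#' transition smoothness, plus area per molecule and molecular volume.
#'
#' @slot name species name
#' @slot area area per molecule (Angstrom^2)
#' @slot volume molecular volume (Angstrom^3)
#' @slot D region thicknesses, length 3 (Angstrom)
#' @slot rhoX region electron densities (e/Angstrom^3)
#' @slot rhoN region neutron SLDs (1/Angstrom^2)
#' @slot sigma region transition smoothness, length 3 (Angstrom)
#' @export
setClass("LipidSpecies",
  representation(name = "character", area = "numeric", volume = "numeric",
                 D = "numeric", rhoX = "numeric", rhoN = "numeric",
                 sigma = "numeric"))

setValidity("LipidSpecies", function(object) {
  msgs <- character(0)
  for (s in c("D", "rhoX", "rhoN", "sigma"))
    if (length(slot(object, s)) != 3)
      msgs <- c(msgs, sprintf("slot '%s' must have length 3", s))
  if (any(object@D <= 0)) msgs <- c(msgs, "region thicknesses must be positive")
  if (object@area <= 0 || object@volume <= 0)
    msgs <- c(msgs, "area and volume must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @param name species name
#' @param area area per molecule (Angstrom^2)
#' @param volume molecular volume (Angstrom^3)
#' @param D region thicknesses (head, CH2, CH3), Angstrom
#' @param rhoX region electron densities (e/Angstrom^3)
#' @param rhoN region neutron SLDs in pure D2O (1/Angstrom^2); values given
#'   in the conventional 1e-6 unit may be passed via \code{rhoN1e6}
#' @param sigma region transition smoothness (Angstrom)
#' @param rhoN1e6 alternative to \code{rhoN}: neutron SLDs in 1e-6/Angstrom^2
#' @rdname LipidSpecies-class
#' @export
lipidSpecies <- function(name, area, volume, D, rhoX, rhoN = NULL,
                         sigma, rhoN1e6 = NULL) {
  if (is.null(rhoN)) {
    stopifnot(!is.null(rhoN1e6))
    rhoN <- rhoN1e6 * 1e-6
  }
  new("LipidSpecies", name = name, area = as.numeric(area),
      volume = as.numeric(volume), D = as.numeric(D),
      rhoX = as.numeric(rhoX), rhoN = as.numeric(rhoN),
      sigma = as.numeric(sigma))
}

#' Core-shell cylinder parameterization of a protein form factor
#'
#' @slot R core radius (Angstrom)
#' @slot delta shell thickness (Angstrom)
#' @slot phiI polypeptide occupancy fraction in the core
#' @slot phiE polypeptide occupancy fraction in the shell
#' @slot L cylinder length (Angstrom); derived from the volume closure
#'   phiI*pi*R^2*L + phiE*pi*((R+delta)^2-R^2)*L = Vp unless pinned
#' @slot Vp protein molecular volume (Angstrom^3)
#' @slot rhoPX protein X-ray electron density (e/Angstrom^3)
#' @slot rhoPN protein neutron SLD (1/Angstrom^2)
#' @export
setClass("CoreShellCylinderParams",
  representation(R = "numeric", delta = "numeric", phiI = "numeric",
                 phiE = "numeric", L = "numeric", Vp = "numeric",
                 rhoPX = "numeric", rhoPN = "numeric"))

setValidity("CoreShellCylinderParams", function(object) {
  msgs <- character(0)
  if (object@R <= 0 || object@delta <= 0 || object@L <= 0)
    msgs <- c(msgs, "R, delta and L must be positive")
  if (object@phiI < 0 || object@phiI > 1 || object@phiE < 0 || object@phiE > 1)
    msgs <- c(msgs, "occupancy fractions must lie in [0, 1]")
  if (object@Vp > 0) {
    vocc <- object@phiI * pi * object@R^2 * object@L +
      object@phiE * pi * ((object@R + object@delta)^2 - object@R^2) * object@L
    if (abs(vocc - object@Vp) > 1e-6 * object@Vp)
      msgs <- c(msgs, "occupied volume does not close to Vp")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param R core radius (Angstrom)
#' @param delta shell thickness (Angstrom)
#' @param phiI core occupancy fraction
#' @param phiE shell occupancy fraction
#' @param Vp protein molecular volume (Angstrom^3)
#' @param L cylinder length; if NULL, derived from the volume closure
#' @param rhoPX protein electron density (e/Angstrom^3)
#' @param rhoPN protein neutron SLD (1/Angstrom^2)
#' @rdname CoreShellCylinderParams-class
#' @export
coreShellCylinderParams <- function(R, delta, phiI, phiE, Vp, L = NULL,
                                    rhoPX = 0.42, rhoPN = 3e-6) {
  if (is.null(L)) {
    denom <- phiI * pi * R^2 + phiE * pi * ((R + delta)^2 - R^2)
    if (denom <= 0) stop("cannot derive L: occupied cross-section is zero")
    L <- Vp / denom
  }
  new("CoreShellCylinderParams", R = as.numeric(R), delta = as.numeric(delta),
      phiI = as.numeric(phiI), phiE = as.numeric(phiE), L = as.numeric(L),
      Vp = as.numeric(Vp), rhoPX = as.numeric(rhoPX), rhoPN = as.numeric(rhoPN))
}
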
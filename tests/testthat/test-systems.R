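test_that("island surface density follows the unit-cell geometry", {
  expect_equal(islandDensity(1.5), 0.51, tolerance = 1e-2)
  expect_equal(islandDensity(150), 5.132e-5, tolerance = 1e-3)
  expect_lt(islandDensity(1e8), 1e-15)
  a <- c(10, 150, 4000)
  expect_equal(islandDensity(a) * sqrt(3) / 2 * a^2, rep(1, 3))
})

test_that("domain stoichiometry reproduces the unit-cell balance", {
  expect_equal(domainConcentration(3, 150, 60, 57, 60), 3.94,
               tolerance = 2e-3)
  expect_equal(domainConcentration(3, 150, 0 + 1e-12, 57, 60), 0,
               tolerance = 1e-6)
  ## consistency: molecule-weighted area fraction equals n_d pi R1^2
  Cg <- domainConcentration(3, 150, 60, 57, 60)
  frac <- Cg * 60 / (Cg * 60 + 3 * 57)
  expect_equal(frac, islandDensity(150) * pi * 60^2, tolerance = 1e-10)
  expect_error(domainConcentration(3, 100, 60, 57, 60), "exceed")
})

test_that("domain system builder enforces the lattice exclusion", {
  sys <- buildDomainSystem(dppc, dopc, 150, 60, 0.3, 3, probeX)
  expect_s4_class(sys, "MembraneSystem")
  expect_equal(sys@concentrations[["DOPC"]],
               domainConcentration(3, 150, 60, 57, 60))
  expect_silent(buildDomainSystem(dppc, dopc, 150, 74.9, 0.3, 3, probeX))
  expect_error(buildDomainSystem(dppc, dopc, 150, 75, 0.3, 3, probeX))
  ## zero-contrast guest reproduces the host curve (exercised upstream too)
  sys0 <- buildDomainSystem(dppc, dppc, 150, 60, 0.3, 3, probeX)
  expect_equal(islandExcessScatteringLength(sys0@island, sys0@bilayer), 0)
})

test_that("transmembrane protein islands assemble from core-shell params", {
  bil <- bilayerProfile(dppc, probeX)
  bR <- getProtein("bacteriorhodopsin")
  isl <- buildTransmembraneProtein(bR@R, bR@delta, bR@phiI, bR@phiE, bR@L,
                                   electronDensityToSLD(bR@rhoPX), "full",
                                   bil)
  expect_equal(isl@radii, c(8.01, 29.01))
  expect_equal(isl@profiles[[1]]@zBase, -bR@L / 2)
  ## half embedding shifts the base to -L/4
  islH <- buildTransmembraneProtein(bR@R, bR@delta, bR@phiI, bR@phiE, bR@L,
                                    electronDensityToSLD(bR@rhoPX), "half",
                                    bil)
  expect_equal(islH@profiles[[1]]@zBase, -bR@L / 4)
  ## ATPase total radius fixture
  atp <- getProtein("ATPase")
  expect_equal(atp@R + atp@delta, 42.8)
  ## occupancy-matched SLD gives a zero-contrast island at q = 0 only when
  ## the mixed SLD reproduces the local bilayer; check the mixing rule
  rhoS <- bil@sldSolvent
  islM <- buildTransmembraneProtein(10, 10, 0.5, 0.5, 20, rhoS, "full", bil)
  expect_equal(islM@profiles[[1]]@sld, rhoS)  # phi*rho + (1-phi)*rho = rho
  expect_error(buildTransmembraneProtein(10, 10, 1.2, 0.5, 20, 1e-6,
                                         "full", bil), "occupancy")
})

test_that("protein concentration follows the footprint formula", {
  ap <- pi * 29.01^2
  ## direct substitution oracle
  expect_equal(proteinConcentration(3, 150, ap, 1, 57),
               3 * 57 / (sqrt(3) * 150^2 - 2 * ap))
  ## anchored proteins remove no lipid
  expect_equal(proteinConcentration(3, 150, ap, 0, 57),
               3 * 57 / (sqrt(3) * 150^2))
  ## monotone decreasing in a
  Cp <- vapply(c(100, 150, 250, 400), proteinConcentration,
               numeric(1), C_b = 3, ap = ap, xi = 1, aHost = 57)
  expect_true(all(diff(Cp) < 0))
  expect_error(proteinConcentration(3, 8, ap, 1, 57), "exceed")
  expect_error(proteinConcentration(3, 150, ap, 1.5, 57), "xi")
})

test_that("peripheral protein geometries stack the documented levels", {
  bil <- bilayerProfile(dppc, probeX)
  cyt <- getProtein("cytochrome_c")
  anch <- buildPeripheralProtein(cyt, 0, bil, probeX)
  mono <- buildPeripheralProtein(cyt, 0.5, bil, probeX)
  trans <- buildPeripheralProtein(cyt, 1, bil, probeX)
  ## anchored: six levels (five bilayer + protein); monotopic: four
  expect_equal(length(anch@profiles[[1]]@thickness), 6)
  expect_equal(length(mono@profiles[[1]]@thickness), 4)
  expect_equal(length(trans@profiles[[1]]@thickness), 1)
  ## occupied z extent: anchored reaches bilayer top + L, above monotopic
  top <- function(p) p@zBase + totalThickness(p)
  expect_equal(top(anch@profiles[[1]]), 48.9 / 2 + cyt@L)
  expect_gt(top(anch@profiles[[1]]), top(mono@profiles[[1]]))
  ## anchored protein level at solvent SLD leaves no excess above the
  ## membrane: whole island has zero excess
  match <- coreShellCylinderParams(cyt@R, cyt@delta, 1, 1, Vp = 0,
                                   L = cyt@L, rhoPX = 0.334,
                                   rhoPN = bil@sldSolvent)
  islM <- buildPeripheralProtein(match, 0, bil, probeX)
  expect_equal(islandExcessScatteringLength(islM, bil), 0, tolerance = 1e-9)
  expect_error(buildPeripheralProtein(cyt, 0.3, bil, probeX), "xi")
})

test_that("pore mapping conserves torus-segment volumes and scattering length", {
  bil <- bilayerProfile(dppc, probeX)
  isl <- buildPore(20, bil)
  expect_equal(isl@radii, c(20, 32, 46.2))
  expect_equal(length(isl@profiles[[1]]@thickness), 0)  # water hole
  seg <- sasbilayer:::.poreSegments(20, bil)
  ringArea <- pi * diff(c(0, isl@radii^2))
  ## mapped shell volumes equal the torus-segment volumes
  expect_equal(totalThickness(isl@profiles[[2]]) * ringArea[2], seg$VA,
               tolerance = 1e-8)
  expect_equal(totalThickness(isl@profiles[[3]]) * ringArea[3],
               seg$VBchain + seg$VBhead, tolerance = 1e-8)
  ## independent Monte Carlo volume integration of the zone-A segment
  set.seed(99)
  n <- 4e5
  rt <- 48.9 / 2
  s <- sqrt(stats::runif(n, 20^2, 32^2))
  z <- stats::runif(n, -rt, rt)
  inside <- abs(z) <= sasbilayer:::.poreLipidHalfHeight(s, 20, rt)
  vmc <- mean(inside) * pi * (32^2 - 20^2) * 2 * rt
  expect_equal(vmc, seg$VA, tolerance = 0.02)
  ## carve-out conserves the removed scattering length: compare against an
  ## independent radial integration using the exact sharp-profile column
  ## (sum of level-interval overlaps with [-z*, z*])
  sharp <- sldProfile(bil@thickness, bil@sld, smoothness = 0,
                      zBase = bil@zBase, sldSolvent = bil@sldSolvent)
  islS <- buildPore(20, sharp)
  edges <- sharp@zBase + c(0, cumsum(sharp@thickness))
  colRemaining <- function(h) {
    lo <- pmax(edges[-6], -h)
    hi <- pmin(edges[-1], h)
    sum((sharp@sld - sharp@sldSolvent) * pmax(0, hi - lo))
  }
  colFull <- colRemaining(Inf)
  removed <- stats::integrate(function(s) {
    zs <- sasbilayer:::.poreLipidHalfHeight(s, 20, rt)
    2 * pi * s * (colFull - vapply(zs, colRemaining, numeric(1)))
  }, 0, 46.2, rel.tol = 1e-10, subdivisions = 1000L)$value
  expect_equal(islandExcessScatteringLength(islS, sharp), -removed,
               tolerance = 1e-7)
  ## |excess| decreases monotonically as the pore closes
  ex <- vapply(c(20, 10, 5, 2), function(Rw)
    abs(islandExcessScatteringLength(buildPore(Rw, bil), bil)), numeric(1))
  expect_true(all(diff(ex) < 0))
  expect_error(buildPore(-1, bil), "positive")
  expect_error(buildPore(10, sldProfile(c(1, 2), c(1, 2) * 1e-6)),
               "5-level")
})

test_that("pore systems scatter below the pore-free bilayer at low q", {
  qlow <- seq(0.01, 0.04, length.out = 8)
  IB <- macroscopicIntensity(buildBilayerSystem(dppc, 3, probeX), qlow)
  IP <- macroscopicIntensity(buildPoreSystem(dppc, 20, 150, 0.3, 3, probeX),
                             qlow, nZenith = 64, nAzimuth = 32)
  expect_true(all(IP < IB))
})

test_that("builders respect island invariants and the lattice exclusion", {
  bil <- bilayerProfile(dppc, probeX)
  bR <- getProtein("bacteriorhodopsin")
  systems <- list(
    buildDomainSystem(dppc, dopc, 150, 60, 0.3, 3, probeX),
    buildPoreSystem(dppc, 20, 150, 0.3, 3, probeX),
    buildProteinSystem(dppc, bR, 150, 0.3, 3, xi = 1, probe = probeX),
    buildProteinSystem(dppc, getProtein("cytochrome_c"), 150, 0.3, 3,
                       xi = 0.5, probe = probeX))
  for (sys in systems) {
    expect_true(validObject(sys))
    r <- sys@island@radii
    expect_true(all(r > 0) && all(diff(r) > 0))
    expect_gt(sys@lattice@a, 2 * max(r))
  }
})
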
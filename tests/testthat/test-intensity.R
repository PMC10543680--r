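qGrid <- exp(seq(log(0.015), log(0.5), length.out = 120))

test_that("zero-contrast islands leave the bilayer curve unchanged", {
  sys0 <- buildDomainSystem(dppc, dppc, 150, 60, 0.3, 3, probeX)
  sysB <- buildBilayerSystem(dppc, 3, probeX)
  a <- perBilayerCrossSection(sys0, qGrid)
  b <- perBilayerCrossSection(sysB, qGrid)
  expect_equal(a, b)
  expect_error(perBilayerCrossSection(sysB, c(-0.1, 0.1)), "positive")
})

test_that("macroscopic intensity is nonnegative, affine in B, linear in kappa", {
  sysD <- buildDomainSystem(dppc, dopc, 150, 60, 0.3, 3, probeX)
  q5 <- seq(0.005, 0.6, length.out = 500)
  I <- macroscopicIntensity(sysD, q5, kappa = 1, B = 0,
                            nZenith = 64, nAzimuth = 32)
  expect_true(all(I >= 0))
  I2 <- macroscopicIntensity(sysD, q5, kappa = 1, B = 0.1,
                             nZenith = 64, nAzimuth = 32)
  expect_equal(I2 - I, rep(0.1, length(q5)))
  I3 <- macroscopicIntensity(sysD, q5, kappa = 2.5, B = 0,
                             nZenith = 64, nAzimuth = 32)
  expect_equal(I3, 2.5 * I)
  expect_error(macroscopicIntensity(sysD, q5, kappa = -1), "positive")
  expect_error(macroscopicIntensity(sysD, q5, B = -0.1), "nonnegative")
})

test_that("pure-bilayer X-ray minima coincide with the amplitude zeros", {
  sysB <- buildBilayerSystem(dppc, 3, probeX)
  I <- macroscopicIntensity(sysB, qGrid)
  bil <- bilayerProfile(dppc, probeX)
  ## symmetric profile: amplitude is real; find its first zero
  z1 <- stats::uniroot(function(q) Re(profileExcessAmplitude(bil, q)),
                       c(0.05, 0.15))$root
  qmin <- qGrid[which(diff(sign(diff(I))) == 2) + 1]
  expect_equal(qmin[1], z1, tolerance = 0.02)
})

test_that("bilayer volume bookkeeping responds to islands as material", {
  sysB <- buildBilayerSystem(dppc, 3, probeX)
  expect_equal(bilayerVolumePerArea(sysB), 48.9)
  ## pores remove material
  sysP <- buildPoreSystem(dppc, 20, 150, 0.3, 3, probeX)
  expect_lt(bilayerVolumePerArea(sysP), 48.9)
  ## the island correction vanishes continuously as n_d -> 0
  v <- vapply(c(300, 1000, 3000, 1e5), function(a) {
    bilayerVolumePerArea(buildPoreSystem(dppc, 20, a, 0.3, 3, probeX))
  }, numeric(1))
  expect_true(all(diff(v) > 0))
  expect_equal(v[4], 48.9, tolerance = 1e-4)
  ## volume fraction: arithmetic and additivity
  expect_equal(volumeFraction(3, 1140), 2.06e-3, tolerance = 1e-2)
  expect_equal(volumeFraction(numeric(0), numeric(0)), 0)
  expect_equal(volumeFraction(c(3, 4), c(1140, 1270)),
               volumeFraction(3, 1140) + volumeFraction(4, 1270))
})

test_that("zenith quadrature is converged at the default node count", {
  sysD <- buildDomainSystem(dppc, dopc, 150, 60, 0.3, 3, probeX)
  i256 <- perBilayerCrossSection(sysD, qGrid, nZenith = 256)
  i512 <- perBilayerCrossSection(sysD, qGrid, nZenith = 512)
  expect_lt(max(abs(i256 / i512 - 1)), 1e-3)
})

test_that("large-spacing limit converges to independent flat-sheet mixing", {
  ## independent implementation of the two-component flat-sheet mixture
  bil <- bilayerProfile(dppc, probeX)
  dom <- bilayerProfile(dopc, probeX)
  Ab2 <- Mod(profileExcessAmplitude(bil, qGrid))^2
  Ad2 <- Mod(profileExcessAmplitude(dom, qGrid))^2
  devs <- vapply(c(300, 600, 1200, 2400), function(a) {
    x <- islandDensity(a) * pi * 60^2
    lim <- 2 * pi / qGrid^2 * ((1 - x) * Ab2 + x * Ad2)
    sys <- buildDomainSystem(dppc, dopc, a, 60, 0.3, 3, probeX)
    ana <- perBilayerCrossSection(sys, qGrid, nZenith = 256)
    ## floored relative deviation: the independent-sheet mixture nearly
    ## vanishes at shared form-factor minima where the island interference
    ## term of the full model stays finite
    max(abs(ana - lim) / (lim + 1e-3 * max(lim)))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[4], 0.01)
})

test_that("small-island limit converges to the homogeneous mixture bilayer", {
  bil <- bilayerProfile(dppc, probeX)
  dom <- bilayerProfile(dopc, probeX)
  x <- islandDensity(150) * pi * 60^2   # fixed area fraction
  Amix <- (1 - x) * profileExcessAmplitude(bil, qGrid) +
    x * profileExcessAmplitude(dom, qGrid)
  lim <- 2 * pi / qGrid^2 * Mod(Amix)^2
  devs <- vapply(c(40, 20, 10, 5), function(R1) {
    a <- sqrt(pi * R1^2 / x / (sqrt(3) / 2))
    sys <- buildDomainSystem(dppc, dopc, a, R1, 0.3, 3, probeX)
    ana <- perBilayerCrossSection(sys, qGrid)
    ## floored relative deviation: the limiting curve has exact zeros where
    ## the finite-size island term keeps the analytic curve positive
    max(abs(ana - lim) / (lim + 1e-3 * max(lim)))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[4], 0.5)
})
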
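test_that("level positions follow the thickness recursion", {
  p <- sldProfile(c(4, 6), c(1e-6, 2e-6), zBase = -10)
  expect_equal(levelPositions(p), c(-10, -6))
  expect_equal(totalThickness(p), 10)

  bil <- bilayerProfile(dppc, probeX)
  expect_equal(totalThickness(bil), 48.9)       # 2*12.0 + 2*10.7 + 3.50
  expect_equal(levelPositions(bil),
               c(-24.45, -12.45, -1.75, 1.75, 12.45))

  p1 <- sldProfile(5, 1e-6, zBase = 0)
  expect_equal(levelPositions(p1), 0)

  expect_error(sldProfile(c(4, -1), c(1, 2)), "positive")
  expect_error(sldProfile(4, 1, smoothness = -0.1), "nonnegative")
})

test_that("erf profile evaluation matches a direct term-by-term oracle", {
  bil <- bilayerProfile(dppc, probeX)
  z <- seq(-60, 60, length.out = 500)
  direct <- directErfProfile(bil@thickness, bil@sld, bil@smoothness,
                             bil@zBase, bil@sldSolvent, z)
  expect_equal(evaluateSLD(bil, z), direct, tolerance = 1e-12)

  ## erf tails reach the solvent reference
  far <- bil@zBase - 50 * max(bil@smoothness)
  expect_equal(evaluateSLD(bil, far), bil@sldSolvent, tolerance = 1e-10)

  ## sigma = 0 reduces to the exact step profile
  sharp <- sldProfile(c(10, 5), c(3e-6, -1e-6), smoothness = 0,
                      zBase = 0, sldSolvent = 1e-6)
  expect_equal(evaluateSLD(sharp, c(2, 12)), c(3e-6, -1e-6))
  expect_equal(evaluateSLD(sharp, c(-1, 16)), c(1e-6, 1e-6))
})

test_that("closed-form partial amplitude equals the quadrature oracle", {
  bil <- bilayerProfile(dppc, probeX)
  for (q in c(0.02, 0.05, 0.1, 0.3, 0.45)) {
    expect_equal(profileExcessAmplitude(bil, q),
                 quadratureAmplitude(bil, q),
                 tolerance = 1e-8)
  }
  ## asymmetric profile with mixed smoothness (exercises every term)
  asym <- sldProfile(c(7, 3, 12), c(4e-6, -2e-6, 1e-6),
                     smoothness = c(1.2, 0.6, 2.5, 3.1), zBase = -4,
                     sldSolvent = 0.5e-6)
  for (q in c(0.04, 0.21)) {
    expect_equal(profileExcessAmplitude(asym, q),
                 quadratureAmplitude(asym, q), tolerance = 1e-8)
  }
  ## sharp single slab against the textbook analytic transform
  slab <- sldProfile(18, 2.5e-6, smoothness = 0, zBase = -5)
  for (q in c(0.05, 0.3)) {
    expect_equal(profileExcessAmplitude(slab, q),
                 2.5e-6 * (exp(1i * q * 13) - exp(1i * q * -5)) / (1i * q))
  }
  ## excess relative to a reference profile
  dom <- bilayerProfile(dopc, probeX)
  expect_equal(profileExcessAmplitude(dom, 0.1, reference = bil),
               quadratureAmplitude(dom, 0.1, reference = bil),
               tolerance = 1e-8)
})

test_that("amplitude limits and symmetries hold", {
  bil <- bilayerProfile(dppc, probeX)
  ## zero contrast
  expect_equal(profileExcessAmplitude(bil, c(0, 0.1, 0.3), reference = bil),
               complex(real = rep(0, 3)))
  ## forward limit is the contrast-weighted thickness
  expect_equal(Re(profileExcessAmplitude(bil, 0)),
               sum((bil@sld - bil@sldSolvent) * bil@thickness))
  expect_equal(excessScatteringLengthPerArea(bil),
               sum((bil@sld - bil@sldSolvent) * bil@thickness))
  ## continuity of the small-q branch
  expect_equal(profileExcessAmplitude(bil, 1e-9),
               profileExcessAmplitude(bil, 0), tolerance = 1e-6)
  ## conjugate symmetry when extended to signed q via the defining integral
  a <- quadratureAmplitude(bil, 0.17)
  expect_equal(quadratureAmplitude(bil, -0.17), Conj(a), tolerance = 1e-8)
  expect_error(profileExcessAmplitude(bil, -0.1), "nonnegative")
})

test_that("X-ray unit conversion is self-inverse and used on construction", {
  rho <- c(0.412, 0.317, 0.245)
  expect_equal(xraySLDToElectronDensity(electronDensityToSLD(rho)), rho)
  p <- sldProfile(c(1, 1, 1), rho, sldSolvent = 0.334, units = "electron")
  expect_equal(p@sld, rho * 2.8e-5)
  expect_equal(p@sldSolvent, 0.334 * 2.8e-5)
  ## neutron solvent interpolation endpoints and linearity
  expect_equal(solventNeutronSLD(0), -0.560e-6)
  expect_equal(solventNeutronSLD(1), 6.36e-6)
  expect_equal(solventNeutronSLD(0.5),
               (solventNeutronSLD(0) + solventNeutronSLD(1)) / 2)
})
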
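test_that("island-island structure factor has the right limits and peak", {
  lat <- paracrystalLattice(150, 0.1)
  ## strong damping -> 1
  expect_equal(islandIslandSF(10 / (0.1 * 150), lat), 1, tolerance = 1e-4)
  expect_equal(islandIslandSF(0.3, paracrystalLattice(150, 3)), 1,
               tolerance = 1e-4)
  ## first maximum of the azimuthal average at the {10} reciprocal vector
  qs <- seq(0.03, 0.07, by = 2e-4)
  S <- islandIslandSF(qs, lat)
  expect_equal(qs[which.max(S)], 4 * pi / (sqrt(3) * 150),
               tolerance = 2e-2)
  ## real, nonnegative
  expect_true(all(S >= 0))
  expect_error(islandIslandSF(0, lat), "positive")
})

test_that("azimuthal sector average equals the full-circle average", {
  ## the two-direction paracrystal product is 180-degree periodic with
  ## mirror lines at 30 and 120 degrees; the packaged sector average must
  ## reproduce a dense full-circle average
  lat <- paracrystalLattice(150, 0.25)
  qv <- c(0.03, 0.0484, 0.1, 0.25)
  psis <- seq(0, 2 * pi, length.out = 4001)[-4001]
  full <- rowMeans(islandIslandSF(qv, lat, azimuth = psis))
  sect <- islandIslandSF(qv, lat, nAzimuth = 256)
  expect_equal(sect, full, tolerance = 2e-3)
})

test_that("island-island structure factor matches a finite-lattice MC pair sum", {
  lat <- paracrystalLattice(150, 0.3)
  qv <- c(0.0484, 0.08, 0.15)
  nreal <- 400
  acc <- matrix(0, nreal, length(qv))
  set.seed(10)
  phis <- stats::runif(nreal, 0, 2 * pi)
  for (r in seq_len(nreal)) {
    cen <- realizeLattice(lat, 32, seed = r)
    proj <- cen[, 1] * cos(phis[r]) + cen[, 2] * sin(phis[r])
    acc[r, ] <- vapply(qv, function(q) Mod(sum(exp(1i * q * proj)))^2,
                       numeric(1)) / nrow(cen)
  }
  mc <- colMeans(acc)
  se <- apply(acc, 2, stats::sd) / sqrt(nreal)
  ana <- islandIslandSF(qv, lat, nAzimuth = 96)
  expect_true(all(abs(mc - ana) < 3.5 * se + 0.02 * ana))
})

test_that("stacking structure factor: limits, peaks and MC double-sum oracle", {
  ## N = 1 is exactly 1
  expect_equal(stackSF(c(0.01, 0.1, 0.4), stackModel(N = 1)), rep(1, 3))

  stk <- stackModel(N = 10, c = 65, theory = "PT", gcPerp = 0.05,
                    polyWidth = 0)
  ## principal maxima within 1% of 2 pi h / c for h = 1, 2
  for (h in 1:2) {
    qb <- 2 * pi * h / 65
    qg <- seq(qb * 0.9, qb * 1.1, length.out = 801)
    S <- stackSF(qg, stk)
    expect_equal(qg[which.max(S)], qb, tolerance = 1e-2)
  }
  ## brute-force double sum over cumulative-Gaussian stack realizations
  qv <- c(0.05, 2 * pi / 65, 0.12, 0.3)
  nreal <- 8000
  set.seed(4)
  acc <- matrix(0, nreal, length(qv))
  for (r in seq_len(nreal)) {
    z <- cumsum(c(0, stats::rnorm(9, 65, 0.05 * 65)))
    acc[r, ] <- vapply(qv, function(q) Mod(sum(exp(1i * q * z)))^2 / 10,
                       numeric(1))
  }
  mc <- colMeans(acc)
  se <- apply(acc, 2, stats::sd) / sqrt(nreal)
  ana <- stackSF(qv, stk)
  expect_true(all(abs(mc - ana) < 4 * se))

  ## structure factors tend to 1 at large q
  expect_equal(stackSF(5, stk), 1, tolerance = 1e-6)
  expect_error(stackSF(-0.1, stk), "positive")
})

test_that("MCT reduces to the ideal lattice at eta1 = 0 and obeys Zhang", {
  qg <- seq(0.02, 0.3, length.out = 200)
  mct0 <- stackSF(qg, stackModel(N = 6, c = 60, theory = "MCT", eta1 = 0,
                                 polyWidth = 0))
  pt0 <- stackSF(qg, stackModel(N = 6, c = 60, theory = "PT", gcPerp = 0,
                                polyWidth = 0))
  expect_equal(mct0, pt0)
  ## Zhang relation values and monotonicity
  expect_equal(zhangGFromEta(0), 0)
  expect_equal(zhangGFromEta(1), 0.294958, tolerance = 1e-5)
  eta <- seq(0, 10, length.out = 50)
  expect_true(all(diff(zhangGFromEta(eta)) > 0))
  expect_error(zhangGFromEta(-1), "nonnegative")
  ## stackModel fills in the missing disorder parameter via Zhang
  s1 <- stackModel(N = 5, theory = "MCT", eta1 = 0.8)
  expect_equal(s1@gcPerp, sqrt(0.087 * 0.8))
  s2 <- stackModel(N = 5, theory = "PT", gcPerp = 0.2)
  expect_equal(s2@eta1, 0.2^2 / 0.087)
  ## MCT peaks broaden with eta1 but stay near the Bragg position
  qb <- 2 * pi / 60
  qg2 <- seq(qb * 0.9, qb * 1.1, length.out = 801)
  Sm <- stackSF(qg2, stackModel(N = 10, c = 60, theory = "MCT",
                                eta1 = 0.05, polyWidth = 0))
  expect_equal(qg2[which.max(Sm)], qb, tolerance = 1e-2)
})

test_that("polydispersity over N is normalized and suppresses oscillations", {
  w <- sasbilayer:::.stackWeights(10, 0.3)
  expect_equal(sum(w), 1)
  expect_true(all(as.integer(names(w)) >= 1))
  ## polyWidth -> 0 reproduces the monodisperse expression
  qg <- seq(0.01, 0.2, length.out = 150)
  expect_equal(stackSF(qg, stackModel(N = 8, c = 65, theory = "PT",
                                      gcPerp = 0.04, polyWidth = 0)),
               stackSF(qg, stackModel(N = 8, c = 65, theory = "PT",
                                      gcPerp = 0.04, polyWidth = 1e-9)),
               tolerance = 1e-6)
  ## low-q intrinsic oscillation amplitude decreases with polyWidth
  qlow <- seq(0.01, 0.08, by = 2e-4)
  osc <- function(pw) {
    S <- stackSF(qlow, stackModel(N = 10, c = 65, theory = "PT",
                                  gcPerp = 0.05, polyWidth = pw))
    sum(abs(diff(S)))
  }
  oscs <- vapply(c(0, 0.1, 0.3), osc, numeric(1))
  expect_true(all(diff(oscs) < 0))
})
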
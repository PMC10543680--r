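## Shared fixtures: reference lipids/probes and independent oracle helpers.

dppc <- getLipid("DPPC")
dopc <- getLipid("DOPC")
probeX <- probeContrast("xray")
probeN <- probeContrast("neutron", xD = 1)

## Independent quadrature oracle for the 1D profile transform: integrates
## the erf-profile excess directly, term by term, without the closed form.
quadratureAmplitude <- function(profile, q, reference = NULL, span = 300) {
  f <- function(z) {
    ex <- evaluateSLD(profile, z) - profile@sldSolvent
    if (!is.null(reference))
      ex <- ex - (evaluateSLD(reference, z) - reference@sldSolvent)
    ex
  }
  re <- stats::integrate(function(z) f(z) * cos(q * z), -span, span,
                         rel.tol = 1e-11, subdivisions = 4000L)$value
  im <- stats::integrate(function(z) f(z) * sin(q * z), -span, span,
                         rel.tol = 1e-11, subdivisions = 4000L)$value
  complex(real = re, imaginary = im)
}

## Independent direct evaluation of the erf level profile (re-derivation
## written without looking at the package internals): solvent plus one
## smoothed step per transition.
directErfProfile <- function(thickness, sld, sigma, zBase, sldSolvent, z) {
  zj <- zBase + c(0, cumsum(thickness))
  rho <- c(sldSolvent, sld, sldSolvent)
  out <- rep(sldSolvent, length(z))
  for (j in seq_along(zj)) {
    step <- if (sigma[j] == 0) as.numeric(z >= zj[j])
            else stats::pnorm((z - zj[j]) / sigma[j])
    out <- out + (rho[j + 1] - rho[j]) * step
  }
  out
}

## 2D quadrature oracle for the disc transform on a polar grid.
discFT2D <- function(q, R) {
  stats::integrate(function(r) 2 * pi * r * besselJ(q * r, 0), 0, R,
                   rel.tol = 1e-12)$value
}
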
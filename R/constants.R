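## Physical constants and unit conversions used throughout the package.
## Internal SLD unit is 1/Angstrom^2; lengths are Angstrom, q is 1/Angstrom.

#' Classical electron radius in Angstrom (0.28e-12 cm)
#' @keywords internal
.RE_ANGSTROM <- 2.8e-5

#' Electron density of water at room temperature, e/Angstrom^3
#' @keywords internal
.WATER_EDENS <- 0.334

## Coherent neutron SLDs of light and heavy water (1/Angstrom^2)
.SLD_H2O <- -0.560e-6
.SLD_D2O <- 6.36e-6

## Avogadro constant
.N_AVOGADRO <- 6.02214076e23

#' Convert an electron density to an X-ray scattering length density
#'
#' Multiplies an electron density in e/Angstrom^3 by the classical electron
#' radius to obtain the X-ray SLD in 1/Angstrom^2.  The conversion is
#' self-inverse via \code{xraySLDToElectronDensity}.
#'
#' @param rho_e electron density, e/Angstrom^3
#' @return SLD in 1/Angstrom^2
#' @export
electronDensityToSLD <- function(rho_e) rho_e * .RE_ANGSTROM

#' @rdname electronDensityToSLD
#' @param sld X-ray SLD in 1/Angstrom^2
#' @export
xraySLDToElectronDensity <- function(sld) sld / .RE_ANGSTROM

#' Neutron SLD of an H2O/D2O mixture
#'
#' Linear interpolation between pure H2O and pure D2O coherent scattering
#' length densities with the solvent deuteration fraction.
#'
#' @param xD deuteration fraction in [0, 1]
#' @return solvent SLD in 1/Angstrom^2
#' @export
solventNeutronSLD <- function(xD) {
  stopifnot(is.numeric(xD), all(xD >= 0 & xD <= 1))
  (1 - xD) * .SLD_H2O + xD * .SLD_D2O
}

#' Convert q from 1/nm to 1/Angstrom
#'
#' All package interfaces take q in 1/Angstrom; this is the single documented
#' helper for data recorded in 1/nm.
#'
#' @param q_nm scattering vector modulus in 1/nm
#' @return q in 1/Angstrom
#' @export
qFromInverseNm <- function(q_nm) q_nm / 10

## Gauss-Legendre nodes/weights on (a, b), cached by (n, a, b)
.gl_cache <- new.env(parent = emptyenv())
.gaussLegendre <- function(n, a = 0, b = 1) {
  key <- paste(n, a, b, sep = "_")
  got <- .gl_cache[[key]]
  if (!is.null(got)) return(got)
  gl <- pracma::gaussLegendre(n, a, b)
  out <- list(x = gl$x, w = gl$w)
  .gl_cache[[key]] <- out
  out
}
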
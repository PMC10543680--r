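#' Zhang relation between the Caille parameter and the PT distortion factor
#'
#' \code{gcPerp = sqrt(0.087 * eta1)}: the perpendicular paracrystal
#' distortion factor that reproduces, near the first diffraction order, the
#' lamellar disorder described by the Caille parameter eta1.
#'
#' @param eta1 Caille parameter, >= 0
#' @return distortion factor g_c-perp
#' @export
zhangGFromEta <- function(eta1) {
  if (any(eta1 < 0)) stop("eta1 must be nonnegative")
  sqrt(0.087 * eta1)
}

## 1D infinite-paracrystal interference factor along one lattice direction:
## Re[(1 + Phi)/(1 - Phi)] with Phi = exp(i theta - eps), theta = qpar a cos(psi),
## eps = qpar^2 sigma_a^2 / 2.  Stable for small |1 - Phi| because ga > 0
## keeps eps > 0 at any qpar > 0.
.paracrystal1D <- function(theta, eps) {
  phi <- exp(complex(real = -eps, imaginary = theta))
  Re((1 + phi) / (1 - phi))
}

#' Island-island structure factor of the infinite 2D hexagonal paracrystal
#'
#' Product over the two unit-cell directions (at 60 degrees) of the
#' one-dimensional paracrystal interference factor
#' \eqn{\mathrm{Re}[(1+\Phi_k)/(1-\Phi_k)]} with
#' \eqn{\Phi_k = \exp(i\, q_\parallel a \cos(\psi - \psi_k) -
#' q_\parallel^2 \sigma_a^2/2)}.  This is the infinite-lattice limit of the
#' paracrystal pair-correlation transform; the \eqn{q_\parallel = 0}
#' delta-function (forward) contribution is excluded and handled by the
#' intensity module's mean-sheet term.
#'
#' @param qpar in-plane scattering vector modulus (1/Angstrom), > 0
#' @param lattice a \code{ParacrystalLattice2D}
#' @param azimuth azimuth angle(s) psi in radians, or NULL to return the
#'   azimuthal average over the irreducible sector.  The two-direction
#'   product is 180-degree periodic with mirror lines at 30 and 120
#'   degrees, so the irreducible sector is [pi/6, 2*pi/3] and its average
#'   equals the full-circle average.
#' @param nAzimuth Gauss-Legendre nodes for the azimuthal average
#' @return real nonnegative values, vectorized over \code{qpar}
#' @export
islandIslandSF <- function(qpar, lattice, azimuth = NULL, nAzimuth = 64) {
  stopifnot(is(lattice, "ParacrystalLattice2D"))
  if (any(qpar <= 0)) stop("qpar must be positive (q = 0 is handled by the mean-sheet term)")
  a <- lattice@a
  sig2 <- (lattice@ga * a)^2
  eps <- qpar^2 * sig2 / 2
  one <- function(psi) {
    .paracrystal1D(qpar * a * cos(psi), eps) *
      .paracrystal1D(qpar * a * cos(psi - pi / 3), eps)
  }
  if (!is.null(azimuth)) {
    if (length(azimuth) == 1) return(one(azimuth))
    return(vapply(azimuth, one, numeric(length(qpar))))
  }
  gl <- .gaussLegendre(nAzimuth, pi / 6, 2 * pi / 3)
  out <- numeric(length(qpar))
  for (i in seq_along(gl$x)) out <- out + gl$w[i] * one(gl$x[i])
  out / (pi / 2)
}

## Monodisperse stacking structure factor, per-bilayer normalized:
## Z_N(q) = 1 + (2/N) sum_{m=1}^{N-1} (N - m) cos(m q c) w(m, q)
## PT:  w = exp(-m q^2 sigma_c^2 / 2), sigma_c = gcPerp * c
## MCT: w = exp(-kappa_q (gamma + log(pi m))) with kappa_q = (q c / 2 pi)^2 eta1
##      (gamma = Euler's constant), i.e. the Caille algebraic peak tails.
.stackSFMono <- function(qperp, N, cst, theory, gcPerp, eta1) {
  if (N <= 1) return(rep(1, length(qperp)))
  m <- seq_len(N - 1)
  osc <- cos(outer(qperp * cst, m))        # nq x (N-1)
  w <- if (theory == "PT") {
    exp(outer(-qperp^2 * (gcPerp * cst)^2 / 2, m))
  } else {
    kq <- (qperp * cst / (2 * pi))^2 * eta1
    exp(-outer(kq, rep(1, length(m))) *
          (-digamma(1) + matrix(log(pi * m), length(qperp), length(m),
                                byrow = TRUE)))
  }
  1 + (2 / N) * as.numeric((osc * w) %*% (N - m))
}

## Discrete Gaussian weights over stack size N, truncated at +-3 widths and
## at N >= 1, renormalized.
.stackWeights <- function(N, polyWidth) {
  if (polyWidth <= 0) return(stats::setNames(1, N))
  sdN <- polyWidth * N
  lo <- max(1, floor(N - 3 * sdN))
  hi <- ceiling(N + 3 * sdN)
  Ns <- lo:hi
  w <- exp(-(Ns - N)^2 / (2 * sdN^2))
  stats::setNames(w / sum(w), Ns)
}

#' Bilayer-bilayer stacking structure factor
#'
#' Vertical interference function of a stack of N bilayers with repeat
#' distance c, following one-dimensional paracrystal theory (PT) or the
#' modified Caille theory (MCT), averaged over a discrete Gaussian
#' distribution of stack sizes (relative width \code{polyWidth}, truncated
#' at three widths and at N >= 1).  Normalized per bilayer so that N = 1
#' gives 1 at all q.
#'
#' @param qperp out-of-plane scattering vector modulus (1/Angstrom), > 0
#' @param stack a \code{StackModel}
#' @return real nonnegative values, vectorized over \code{qperp}
#' @export
stackSF <- function(qperp, stack) {
  stopifnot(is(stack, "StackModel"))
  if (any(qperp <= 0)) stop("qperp must be positive")
  if (stack@gcPerp < 0 || stack@eta1 < 0)
    stop("negative disorder parameter")
  if (stack@N == 1) return(rep(1, length(qperp)))
  w <- .stackWeights(stack@N, stack@polyWidth)
  out <- numeric(length(qperp))
  for (i in seq_along(w)) {
    Ni <- as.integer(names(w)[i])
    out <- out + w[[i]] *
      .stackSFMono(qperp, Ni, stack@c, stack@theory, stack@gcPerp, stack@eta1)
  }
  out
}
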
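#' In-plane Fourier transform of a filled disc
#'
#' \deqn{\tilde{S}(q_\parallel) = 2\pi R\, J_1(q_\parallel R)/q_\parallel,}
#' the two-dimensional Fourier transform of the indicator function of a disc
#' of radius R.  The \eqn{q_\parallel \to 0} limit \eqn{\pi R^2} is taken
#' analytically with a series branch below \eqn{|q_\parallel R| < 10^{-4}}
#' to avoid cancellation.
#'
#' @param qpar in-plane scattering vector modulus (1/Angstrom), >= 0
#' @param R disc radius (Angstrom), > 0
#' @return real values (Angstrom^2), vectorized over \code{qpar}
#' @export
discFT <- function(qpar, R) {
  stopifnot(R > 0)
  if (any(qpar < 0)) stop("qpar must be nonnegative")
  x <- qpar * R
  out <- numeric(length(x))
  small <- x < 1e-4
  ## J1(x)/x = 1/2 - x^2/16 + x^4/384 - ...
  out[small] <- 2 * pi * R^2 * (0.5 - x[small]^2 / 16 + x[small]^4 / 384)
  if (any(!small))
    out[!small] <- 2 * pi * R^2 * besselJ(x[!small], 1) / x[!small]
  out
}

#' In-plane Fourier transform of an annulus
#'
#' Difference of two disc transforms; at \eqn{q_\parallel = 0} equals the
#' annulus area \eqn{\pi(R_{out}^2 - R_{in}^2)}.  \code{Rin = 0} reduces to
#' \code{discFT}.
#'
#' @param qpar in-plane scattering vector modulus (1/Angstrom), >= 0
#' @param Rin inner radius (Angstrom), >= 0
#' @param Rout outer radius (Angstrom), > Rin
#' @return real values (Angstrom^2)
#' @export
annulusFT <- function(qpar, Rin, Rout) {
  if (Rin >= Rout) stop("Rin must be smaller than Rout")
  if (Rin < 0) stop("Rin must be nonnegative")
  if (Rin == 0) discFT(qpar, Rout)
  else discFT(qpar, Rout) - discFT(qpar, Rin)
}

#' Scattering amplitude of an island in excess of the host bilayer
#'
#' Assembles the island amplitude
#' \deqn{A_i(q_\perp, q_\parallel) = \sum_k A_k(q_\perp)\,
#'       \tilde{S}_k(q_\parallel),}
#' where \eqn{A_k} is the closed-form transform of the SLD of shell k in
#' excess of the host bilayer profile and \eqn{\tilde{S}_k} is the annulus
#' transform of the shell footprint \eqn{(R_{k-1}, R_k]}.  Vectorized over
#' paired \code{qperp}/\code{qpar} (equal length or length-1 recycling).
#'
#' @param island an \code{Island}
#' @param host host bilayer \code{SLDLevelProfile}
#' @param qperp out-of-plane component(s) (1/Angstrom), >= 0
#' @param qpar in-plane component(s) (1/Angstrom), >= 0
#' @return complex amplitudes (Angstrom; SLD x volume)
#' @export
islandAmplitude <- function(island, host, qperp, qpar) {
  stopifnot(is(island, "Island"), is(host, "SLDLevelProfile"))
  n <- max(length(qperp), length(qpar))
  qperp <- rep_len(qperp, n)
  qpar <- rep_len(qpar, n)
  radii <- c(0, island@radii)
  out <- complex(length.out = n)
  for (k in seq_along(island@profiles)) {
    ak <- profileExcessAmplitude(island@profiles[[k]], qperp, reference = host)
    if (all(ak == 0)) next
    out <- out + ak * annulusFT(qpar, radii[k], radii[k + 1])
  }
  out
}

#' Excess scattering length of an island
#'
#' The q = 0 island amplitude: direct volume integral of the SLD excess over
#' the island cylinder.
#'
#' @inheritParams islandAmplitude
#' @return numeric value (Angstrom)
#' @export
islandExcessScatteringLength <- function(island, host) {
  Re(islandAmplitude(island, host, 0, 0))
}
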
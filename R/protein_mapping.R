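#' Orientationally averaged core-shell cylinder form factor
#'
#' Form factor of a two-region cylinder (core radius R, shell outer radius
#' R + delta, length L) whose region SLDs mix the protein SLD with solvent
#' by the occupancy fractions phiI/phiE.  The fixed-orientation amplitude is
#' \deqn{F(q,\beta) = \phi_i \Delta\rho\, V_c f(q,\beta;R) +
#'       \phi_e \Delta\rho\, [V_o f(q,\beta;R{+}\delta) - V_c f(q,\beta;R)]}
#' with \eqn{f(q,\beta;X) = j_0(q L \cos\beta / 2)\,
#' 2 J_1(q X \sin\beta)/(q X \sin\beta)} and \eqn{\Delta\rho = \rho_p -
#' \rho_{solv}}; the zenith average of \eqn{|F|^2} is taken by
#' Gauss-Legendre quadrature.  P(0) equals the squared total excess
#' scattering length.
#'
#' @param params a \code{CoreShellCylinderParams}
#' @param q scattering vector moduli (1/Angstrom), >= 0
#' @param rhoSolv solvent SLD (1/Angstrom^2)
#' @param probe "xray" or "neutron" (selects the protein SLD)
#' @param nZenith quadrature nodes
#' @return real nonnegative values (Angstrom^2; scattering length squared)
#' @export
coreShellCylinderPq <- function(params, q, rhoSolv,
                                probe = c("xray", "neutron"),
                                nZenith = 128) {
  stopifnot(is(params, "CoreShellCylinderParams"))
  probe <- match.arg(probe)
  if (any(q < 0)) stop("q must be nonnegative")
  rhoP <- if (probe == "xray") electronDensityToSLD(params@rhoPX)
          else params@rhoPN
  drho <- rhoP - rhoSolv
  R <- params@R; Ro <- params@R + params@delta; L <- params@L
  Vc <- pi * R^2 * L; Vo <- pi * Ro^2 * L
  gl <- .gaussLegendre(nZenith, 0, 1)
  out <- numeric(length(q))
  j0 <- function(x) ifelse(abs(x) < 1e-8, 1, sin(x) / x)
  j1c <- function(x) ifelse(abs(x) < 1e-4, 0.5 - x^2 / 16, besselJ(x, 1) / x)
  for (i in seq_along(gl$x)) {
    u <- gl$x[i]; s <- sqrt(1 - u^2)
    ax <- j0(q * L * u / 2)
    fR <- ax * 2 * j1c(q * R * s)
    fRo <- ax * 2 * j1c(q * Ro * s)
    amp <- params@phiI * drho * Vc * fR +
      params@phiE * drho * (Vo * fRo - Vc * fR)
    out <- out + gl$w[i] * amp^2
  }
  out
}

#' Fit a core-shell cylinder model to a protein form-factor curve
#'
#' Least-squares fit of (R, delta, phiI, phiE) to a P(q) curve, honouring
#' the volume closure (L derived from Vp and the occupancies at every
#' step).  The objective is unweighted least squares on log10 intensity
#' with the overall scale profiled out analytically, so the fit is
#' invariant to curve scaling.  Multi-start: the first start is
#' \code{init}; further starts perturb it within bounds using the seed.
#'
#' @param curve a \code{ScatteringCurve} holding P(q) (>= 20 points over at
#'   least one decade in q)
#' @param Vp protein molecular volume (Angstrom^3)
#' @param rhoP protein SLD in the curve's units (e/Angstrom^3 for "xray")
#' @param rhoSolv solvent SLD (1/Angstrom^2)
#' @param probe "xray" or "neutron"
#' @param init named start values (R, delta, phiI, phiE)
#' @param lower,upper named bounds for the four parameters
#' @param nStarts number of starts
#' @param seed RNG seed for start perturbations
#' @return a \code{CoreShellCylinderParams} with attributes
#'   \code{"objective"} (residual sum of squares) and \code{"fit"}
#'   (the underlying optimizer object)
#' @export
fitCoreShell <- function(curve, Vp, rhoP, rhoSolv,
                         probe = c("xray", "neutron"),
                         init = c(R = 10, delta = 20, phiI = 0.5,
                                  phiE = 0.5),
                         lower = c(R = 0.05, delta = 0.5, phiI = 0,
                                   phiE = 0),
                         upper = c(R = 80, delta = 80, phiI = 1, phiE = 1),
                         nStarts = 8, seed = 1) {
  probe <- match.arg(probe)
  stopifnot(is(curve, "ScatteringCurve"))
  q <- curve@q; I <- curve@I
  if (length(q) < 20 || max(q) / min(q) < 10)
    stop("curve must have >= 20 points spanning at least one decade in q")
  if (any(I <= 0)) stop("P(q) values must be positive for the log objective")
  if (diff(range(log10(I))) < 0.5)
    stop("degenerate (flat) form-factor curve: no shape information to fit")
  logI <- log10(I)
  pnames <- c("R", "delta", "phiI", "phiE")
  makeParams <- function(p) {
    rhoPX <- if (probe == "xray") rhoP else 0.42
    rhoPN <- if (probe == "neutron") rhoP else 3e-6
    coreShellCylinderParams(R = p[["R"]], delta = p[["delta"]],
                            phiI = p[["phiI"]], phiE = p[["phiE"]], Vp = Vp,
                            rhoPX = rhoPX, rhoPN = rhoPN)
  }
  resid <- function(p) {
    p <- stats::setNames(pmin(pmax(p, lower[pnames]), upper[pnames]), pnames)
    cs <- tryCatch(makeParams(p), error = function(e) NULL)
    if (is.null(cs)) return(rep(1e3, length(q)))
    mod <- coreShellCylinderPq(cs, q, rhoSolv, probe)
    if (any(mod <= 0)) return(rep(1e3, length(q)))
    d <- log10(mod) - logI
    d - mean(d)          # profile out the overall scale
  }
  set.seed(seed)
  starts <- list(init[pnames])
  for (k in seq_len(max(0, nStarts - 1))) {
    p <- init[pnames] * exp(stats::runif(4, -0.4, 0.4))
    starts[[k + 1]] <- pmin(pmax(p, lower[pnames] + 1e-6),
                            upper[pnames] - 1e-6)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower[pnames],
                         upper = upper[pnames], fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("core-shell fit failed to converge from any start")
  out <- makeParams(stats::setNames(best$par, pnames))
  attr(out, "objective") <- best$deviance
  attr(out, "fit") <- best
  out
}
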
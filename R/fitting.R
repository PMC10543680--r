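## First local maximum of an intensity curve (used to calibrate the noise
## constant); falls back to the global maximum when the curve is monotone.
.firstLocalMax <- function(I) {
  n <- length(I)
  if (n >= 3) {
    for (i in 2:(n - 1)) if (I[i] > I[i - 1] && I[i] >= I[i + 1]) return(I[i])
  }
  max(I)
}

#' Simulate a noisy scattering experiment
#'
#' Evaluates the model intensity and adds Gaussian noise whose standard
#' deviation is proportional to the square root of the model intensity:
#' \deqn{I_{obs}(q) = I(q) + \epsilon \sqrt{I(q)}\, Z,\qquad
#'       \sigma(q) = \epsilon \sqrt{I(q)}.}
#' When \code{eps = NULL} the noise constant is calibrated to give 3\%
#' relative uncertainty at the first local intensity maximum
#' (\eqn{\epsilon = 0.03 \sqrt{I_{max}}}).
#'
#' @param system a \code{MembraneSystem}
#' @param q scattering vector grid (1/Angstrom)
#' @param eps noise proportionality constant; 0 gives the exact model curve
#' @param seed RNG seed (fixed-seed runs are identical)
#' @param kappa,B instrumental scale and flat background
#' @param nZenith,nAzimuth quadrature nodes
#' @param label curve label
#' @return a \code{ScatteringCurve} with the probe tag of the system
#' @export
simulateExperiment <- function(system, q, eps = NULL, seed = 1,
                               kappa = 1, B = 0, nZenith = 256,
                               nAzimuth = 64, label = "") {
  if (!is.null(eps) && eps < 0) stop("eps must be nonnegative")
  Imod <- macroscopicIntensity(system, q, kappa, B, nZenith, nAzimuth)
  if (is.null(eps)) eps <- 0.03 * sqrt(.firstLocalMax(Imod))
  sig <- eps * sqrt(pmax(Imod, 0))
  set.seed(seed)
  Iobs <- Imod + sig * stats::rnorm(length(q))
  if (eps == 0) sig <- rep(max(Imod) * 1e-6, length(q))
  scatteringCurve(q, Iobs, sig, probe = system@probe@probe, label = label)
}

## SVD pseudo-inverse of the (possibly near-singular) Gauss-Newton Hessian;
## directions with relative singular value below tol get infinite variance
## suppressed to the largest finite scale rather than breaking the solve.
.pseudoInverse <- function(H, tol = 1e-10) {
  sv <- tryCatch(svd(H), error = function(e) NULL)
  if (is.null(sv)) return(NULL)
  d <- sv$d
  keep <- d > tol * max(d)
  dinv <- ifelse(keep, 1 / d, 0)
  sv$v %*% (dinv * t(sv$u))
}

#' Global multi-curve least-squares fit
#'
#' Minimizes \eqn{\sum_{c}\sum_i [(I_{obs} - I_{fit})/\sigma]^2} over all
#' curves simultaneously with bounded Levenberg-Marquardt, optionally from
#' multiple starts.  \code{model} maps a full named parameter vector to a
#' list of model intensity vectors matching \code{curves}; only the
#' parameters named in \code{free} are varied.
#'
#' @param curves list of \code{ScatteringCurve} with uncertainties
#' @param model function(par) -> list of intensity vectors
#' @param parInit full named start vector
#' @param lower,upper named bounds for the free parameters
#' @param free names of free parameters (default: all in \code{parInit})
#' @param nStarts number of starts (start 1 is \code{parInit}; further
#'   starts perturb the free parameters within bounds)
#' @param seed RNG seed for start perturbations
#' @param maxIter maximum optimizer iterations per start
#' @param startSpread relative spread of the multi-start perturbations
#' @return list with elements \code{par} (full parameter vector at the
#'   optimum), \code{estimates} (data.frame: estimate, se, atBound per free
#'   parameter), \code{redChi2}, \code{chi2}, \code{nObs}, \code{fitted}
#'   (list of model curves), \code{converged}, \code{fit} (optimizer
#'   object)
#' @export
globalFit <- function(curves, model, parInit, lower, upper,
                      free = names(parInit), nStarts = 1, seed = 1,
                      maxIter = 100, startSpread = 0.05) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, is, logical(1), class2 = "ScatteringCurve")))
  if (!all(free %in% names(parInit))) stop("free names must be in parInit")
  lower <- lower[free]; upper <- upper[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("finite bounds required for all free parameters")
  obs <- unlist(lapply(curves, function(cu) cu@I))
  sig <- unlist(lapply(curves, function(cu) {
    if (is.null(cu@sigma)) stop("all curves need uncertainties")
    cu@sigma
  }))
  full <- parInit
  resid <- function(p) {
    full[free] <- p
    mod <- unlist(model(full))
    (obs - mod) / sig
  }
  set.seed(seed)
  starts <- list(parInit[free])
  for (k in seq_len(max(0, nStarts - 1))) {
    p <- parInit[free] + startSpread * (upper - lower) *
      stats::runif(length(free), -1, 1)
    starts[[k + 1]] <- pmin(pmax(p, lower), upper)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxIter, ptol = 1e-8, ftol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("global fit failed to converge from any start")
  full[free] <- best$par
  nObs <- length(obs)
  dof <- max(1, nObs - length(free))
  redChi2 <- best$deviance / dof
  se <- rep(NA_real_, length(free))
  covm <- .pseudoInverse(best$hessian)
  if (!is.null(covm)) se <- sqrt(pmax(0, diag(covm) * redChi2))
  atBound <- best$par <= lower + 1e-10 | best$par >= upper - 1e-10
  est <- data.frame(parameter = free, estimate = unname(best$par),
                    se = unname(se), atBound = unname(atBound),
                    stringsAsFactors = FALSE)
  conv <- best$info %in% 1:4
  if (!conv) warning("optimizer did not report convergence (info = ",
                     best$info, ")")
  if (any(atBound)) warning("parameters at bounds: ",
                            paste(free[atBound], collapse = ", "))
  list(par = full, estimates = est, redChi2 = redChi2, chi2 = best$deviance,
       nObs = nObs, fitted = model(full), converged = conv, fit = best)
}

## ---- the domain simulated-experiment + refit protocol ----------------------

#' Ground-truth parameters of the domain refit protocol
#'
#' Loads the packaged truth set for the simulated-experiment protocol:
#' DOPC-like fluid domains (R1 = 60 A) on a hexagonal paracrystal
#' (a = 150 A, ga = 0.3) in a DPPC-like host bilayer at 3 mM, observed by
#' SAXS and by SANS in pure D2O.
#'
#' @return list with \code{par} (named parameter vector), \code{const}
#'   (fixed protocol constants: a, C_host, areas, volumes)
#' @export
domainProtocolTruth <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "refit_protocols.yaml",
                                     package = "sasbilayer"))$domain
  par <- c(
    stats::setNames(cfg$host$D, paste0("D", 1:3, "_b")),
    stats::setNames(cfg$host$rhoX, paste0("rhoX", 1:3, "_b")),
    stats::setNames(cfg$host$rhoN, paste0("rhoN", 1:3, "_b")),
    stats::setNames(cfg$host$sigma, paste0("sig", 1:3, "_b")),
    stats::setNames(cfg$guest$D, paste0("D", 1:3, "_d")),
    stats::setNames(cfg$guest$rhoX, paste0("rhoX", 1:3, "_d")),
    stats::setNames(cfg$guest$rhoN, paste0("rhoN", 1:3, "_d")),
    stats::setNames(cfg$guest$sigma, paste0("sig", 1:3, "_d")),
    R1 = cfg$R1, ga = cfg$ga)
  const <- list(a = cfg$a, C_host = cfg$C_host,
                areaHost = cfg$host$area, areaGuest = cfg$guest$area,
                volHost = cfg$host$volume, volGuest = cfg$guest$volume,
                nameHost = cfg$host$name, nameGuest = cfg$guest$name)
  list(par = par, const = const)
}

.lipidFromPar <- function(par, suffix, name, area, volume) {
  g <- function(stem) unname(par[paste0(stem, 1:3, "_", suffix)])
  lipidSpecies(name, area, volume, D = g("D"), rhoX = g("rhoX"),
               rhoN1e6 = g("rhoN"), sigma = g("sig"))
}

#' Model curves of the domain refit protocol
#'
#' Maps a named parameter vector (host and guest region thicknesses,
#' electron densities, neutron SLDs, smoothness, domain radius R1 and
#' lattice distortion ga) to the four model curves of the protocol:
#' pure host SAXS, pure host SANS (xD = 1), domain system SAXS, domain
#' system SANS.  Electron densities are in e/A^3 and neutron SLDs in
#' 1e-6/A^2, as in the parameter tables.
#'
#' @param par named parameter vector (see \code{domainProtocolTruth()$par})
#' @param q scattering vector grid
#' @param const protocol constants (see \code{domainProtocolTruth()$const})
#' @param nZenith,nAzimuth quadrature nodes
#' @return list of four intensity vectors (hostX, hostN, domainX, domainN)
#' @export
domainProtocolModel <- function(par, q, const = domainProtocolTruth()$const,
                                nZenith = 64, nAzimuth = 32) {
  host <- .lipidFromPar(par, "b", const$nameHost, const$areaHost,
                        const$volHost)
  guest <- .lipidFromPar(par, "d", const$nameGuest, const$areaGuest,
                         const$volGuest)
  probes <- list(X = probeContrast("xray"), N = probeContrast("neutron", 1))
  out <- vector("list", 4)
  names(out) <- c("hostX", "hostN", "domainX", "domainN")
  for (nm in c("X", "N")) {
    sysH <- buildBilayerSystem(host, const$C_host, probes[[nm]])
    out[[paste0("host", nm)]] <- macroscopicIntensity(sysH, q,
                                                      nZenith = nZenith,
                                                      nAzimuth = nAzimuth)
    sysD <- buildDomainSystem(host, guest, const$a, par[["R1"]],
                              par[["ga"]], const$C_host, probes[[nm]])
    out[[paste0("domain", nm)]] <- macroscopicIntensity(sysD, q,
                                                        nZenith = nZenith,
                                                        nAzimuth = nAzimuth)
  }
  out
}

#' Simulate the four curves of the domain refit protocol
#'
#' @param q scattering vector grid
#' @param seed RNG seed
#' @param truth protocol truth as from \code{domainProtocolTruth()}
#' @param eps noise constant; NULL calibrates 3\% at the first maximum,
#'   separately per curve
#' @param nZenith,nAzimuth quadrature nodes
#' @return list of four \code{ScatteringCurve}s
#' @export
simulateDomainProtocol <- function(q, seed = 1,
                                   truth = domainProtocolTruth(),
                                   eps = NULL, nZenith = 64,
                                   nAzimuth = 32) {
  mods <- domainProtocolModel(truth$par, q, truth$const, nZenith, nAzimuth)
  probes <- c(hostX = "xray", hostN = "neutron", domainX = "xray",
              domainN = "neutron")
  out <- vector("list", 4)
  names(out) <- names(mods)
  set.seed(seed)
  for (i in seq_along(mods)) {
    Imod <- mods[[i]]
    e <- if (is.null(eps)) 0.03 * sqrt(.firstLocalMax(Imod)) else eps
    sig <- e * sqrt(pmax(Imod, 0))
    Iobs <- Imod + sig * stats::rnorm(length(q))
    if (e == 0) sig <- rep(max(Imod) * 1e-6, length(q))
    out[[i]] <- scatteringCurve(q, Iobs, sig, probe = probes[[i]],
                                label = names(mods)[i])
  }
  out
}

#' Global fit of the domain refit protocol
#'
#' Fits the shared structural parameters of the host (and optionally the
#' guest) bilayer to the four protocol curves.  The default free set frees
#' all host and guest profile parameters plus the domain radius R1 and
#' lattice distortion ga, as in the reference refit; the instrumental scale
#' is fixed at the simulated value (absolute-scale synthetic data).
#'
#' @param curves list of four curves as from \code{simulateDomainProtocol}
#' @param init full named start vector (e.g. the packaged Table-1-style
#'   lipid values via \code{domainProtocolInit()})
#' @param free names of free parameters
#' @param const protocol constants
#' @param nZenith,nAzimuth quadrature nodes for the fit model
#' @param ... passed to \code{globalFit}
#' @return a \code{globalFit} result
#' @export
fitDomainProtocol <- function(curves, init = domainProtocolInit(),
                              free = NULL,
                              const = domainProtocolTruth()$const,
                              nZenith = 64, nAzimuth = 32, ...) {
  if (is.null(free)) free <- names(init)
  model <- function(par) domainProtocolModel(par, curves[[1]]@q, const,
                                             nZenith, nAzimuth)
  bounds <- .domainParBounds(init)
  globalFit(curves, model, init, bounds$lower, bounds$upper, free, ...)
}

#' Generic start values for the domain protocol fit
#'
#' The packaged reference lipid parameterizations (DPPC host, DOPC guest)
#' with a neutral guess for the island geometry; deliberately distinct from
#' the protocol truth.
#'
#' @return named parameter vector
#' @export
domainProtocolInit <- function() {
  dppc <- getLipid("DPPC"); dopc <- getLipid("DOPC")
  c(stats::setNames(dppc@D, paste0("D", 1:3, "_b")),
    stats::setNames(dppc@rhoX, paste0("rhoX", 1:3, "_b")),
    stats::setNames(dppc@rhoN * 1e6, paste0("rhoN", 1:3, "_b")),
    stats::setNames(dppc@sigma, paste0("sig", 1:3, "_b")),
    stats::setNames(dopc@D, paste0("D", 1:3, "_d")),
    stats::setNames(dopc@rhoX, paste0("rhoX", 1:3, "_d")),
    stats::setNames(dopc@rhoN * 1e6, paste0("rhoN", 1:3, "_d")),
    stats::setNames(dopc@sigma, paste0("sig", 1:3, "_d")),
    R1 = 55, ga = 0.25)
}

## Physically motivated box bounds for the protocol parameters.
.domainParBounds <- function(init) {
  lower <- upper <- init
  for (nm in names(init)) {
    stem <- sub("[0-9].*$", "", nm)
    b <- switch(stem,
      D = c(1, 25), rhoX = c(0.15, 0.6), rhoN = c(-3, 8),
      sig = c(0.3, 8), R = c(10, 74), ga = c(0.02, 0.6),
      c(-Inf, Inf))
    lower[nm] <- b[1]; upper[nm] <- b[2]
  }
  list(lower = lower, upper = upper)
}
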
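#' Read a scattering curve from a text file
#'
#' Whitespace-delimited 2- or 3-column text (q, I[, sigma]); lines starting
#' with '#' are treated as comments and preserved in the curve metadata;
#' blank lines are skipped.  q is forced ascending (sorted with a warning
#' if needed).
#'
#' @param path file path
#' @param probe probe tag to attach
#' @return a \code{ScatteringCurve}
#' @export
readCurve <- function(path, probe = "") {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty curve file: ", path)
  stripped <- trimws(lines)
  isComment <- startsWith(stripped, "#")
  isBlank <- stripped == ""
  dataIdx <- which(!isComment & !isBlank)
  if (length(dataIdx) == 0) stop("no data rows in curve file: ", path)
  rows <- lapply(dataIdx, function(i) {
    fields <- strsplit(stripped[i], "[ \t,]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)) || !length(vals) %in% 2:3)
      stop(sprintf("non-numeric or malformed row at line %d of %s: '%s'",
                   i, path, lines[i]))
    vals
  })
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1)
    stop("inconsistent column counts in ", path)
  m <- do.call(rbind, rows)
  if (any(m[, 1] <= 0)) {
    bad <- dataIdx[which(m[, 1] <= 0)[1]]
    stop(sprintf("non-positive q at line %d of %s", bad, path))
  }
  if (is.unsorted(m[, 1], strictly = TRUE)) {
    warning("q not strictly ascending in ", path, "; sorting")
    m <- m[order(m[, 1]), , drop = FALSE]
    m <- m[!duplicated(m[, 1]), , drop = FALSE]
  }
  scatteringCurve(m[, 1], m[, 2],
                  sigma = if (ncols == 3) m[, 3] else NULL,
                  probe = probe, label = basename(path),
                  comments = stripped[isComment])
}

#' Write a scattering curve to a text file
#'
#' Three columns (q, I, sigma) or two when no uncertainties; a '#' header
#' records the column names and any preserved comments.
#'
#' @param curve a \code{ScatteringCurve}
#' @param path output file path
#' @return invisibly, the path
#' @export
writeCurve <- function(curve, path) {
  stopifnot(is(curve, "ScatteringCurve"))
  hdr <- c(curve@comments,
           if (is.null(curve@sigma)) "# q[1/A]  I" else "# q[1/A]  I  sigma")
  body <- if (is.null(curve@sigma))
    sprintf("%.8e %.8e", curve@q, curve@I)
  else sprintf("%.8e %.8e %.8e", curve@q, curve@I, curve@sigma)
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- declarative system configs --------------------------------------------

.configSchema <- list(
  system = list(
    host = NULL,
    island = list(type = NULL, guest = NULL, R1 = NULL, Rw = NULL,
                  protein = NULL, xi = NULL, embed = NULL),
    lattice = list(a = NULL, ga = NULL),
    stack = list(N = NULL, c = NULL, theory = NULL, gcPerp = NULL,
                 eta1 = NULL, polyWidth = NULL),
    concentration = list(host = NULL)
  ),
  probe = list(type = NULL, xD = NULL),
  instrument = list(kappa = NULL, B = NULL),
  qgrid = list(min = NULL, max = NULL, n = NULL, spacing = NULL),
  noise = list(eps = NULL),
  seed = NULL
)

.checkKeys <- function(cfg, schema, path = "") {
  unknown <- character(0)
  for (key in names(cfg)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(schema)) {
      unknown <- c(unknown, here)
    } else if (is.list(schema[[key]]) && is.list(cfg[[key]])) {
      unknown <- c(unknown, .checkKeys(cfg[[key]], schema[[key]], here))
    }
  }
  unknown
}

.lipidFromConfig <- function(x) {
  if (is.character(x)) return(getLipid(x))
  lipidSpecies(x$name %||% "lipid", x$area, x$volume, D = unlist(x$D),
               rhoX = unlist(x$rhoX), rhoN1e6 = unlist(x$rhoN),
               sigma = unlist(x$sigma))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a declarative system configuration
#'
#' Parses a YAML system description (host lipid, island archetype, lattice,
#' stack, concentrations, probe, instrument, q-grid, noise, seed) into a
#' resolved \code{MembraneSystem} plus simulation settings.  Unknown keys
#' are an error listing every offending key.
#'
#' @param path YAML file path, or a pre-parsed list
#' @return list with elements \code{system}, \code{kappa}, \code{B},
#'   \code{q}, \code{eps}, \code{seed}, \code{config} (the parsed list)
#' @export
readSystemConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- .checkKeys(cfg, .configSchema)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  sc <- cfg$system
  if (is.null(sc) || is.null(sc$host)) stop("config requires system.host")
  host <- .lipidFromConfig(sc$host)
  probe <- probeContrast(cfg$probe$type %||% "xray",
                         cfg$probe$xD %||% 0)
  stk <- sc$stack
  stack <- stackModel(N = stk$N %||% 1, c = stk$c %||% 65,
                      theory = stk$theory %||% "PT",
                      gcPerp = stk$gcPerp, eta1 = stk$eta1,
                      polyWidth = stk$polyWidth %||% 0.3)
  C_host <- sc$concentration$host %||% 3
  lat <- sc$lattice
  islType <- sc$island$type %||% "none"
  sys <- switch(islType,
    none = buildBilayerSystem(host, C_host, probe, stack),
    domain = {
      guest <- .lipidFromConfig(sc$island$guest)
      buildDomainSystem(host, guest, lat$a, sc$island$R1, lat$ga %||% 0.3,
                        C_host, probe, stack)
    },
    pore = buildPoreSystem(host, sc$island$Rw, lat$a, lat$ga %||% 0.3,
                           C_host, probe, stack),
    protein = {
      pr <- sc$island$protein
      params <- if (is.character(pr)) getProtein(pr)
        else coreShellCylinderParams(R = pr$R, delta = pr$delta,
                                     phiI = pr$phiI, phiE = pr$phiE,
                                     Vp = pr$Vp, L = pr$L,
                                     rhoPX = pr$rhoPX %||% 0.42,
                                     rhoPN = (pr$rhoPN %||% 3) * 1e-6)
      buildProteinSystem(host, params, lat$a, lat$ga %||% 0.3, C_host,
                         xi = sc$island$xi %||% 1,
                         embed = sc$island$embed %||% "full", probe, stack)
    },
    stop("unknown island type: ", islType))
  qg <- cfg$qgrid
  q <- if (is.null(qg)) NULL else {
    n <- qg$n %||% 300
    if ((qg$spacing %||% "log") == "log")
      exp(seq(log(qg$min %||% 0.01), log(qg$max %||% 0.6), length.out = n))
    else seq(qg$min %||% 0.01, qg$max %||% 0.6, length.out = n)
  }
  eps <- cfg$noise$eps
  if (!is.null(eps) && identical(eps, "auto")) eps <- NULL
  list(system = sys, kappa = cfg$instrument$kappa %||% 1,
       B = cfg$instrument$B %||% 0, q = q, eps = eps,
       seed = cfg$seed %||% 1, config = cfg)
}

#' Write a system configuration
#'
#' Emits the declarative configuration (as parsed or hand-built) to YAML;
#' configurations written by the package re-parse to an identical system.
#'
#' @param config a configuration list (e.g. the \code{config} element
#'   returned by \code{readSystemConfig})
#' @param path output YAML path
#' @return invisibly, the path
#' @export
writeSystemConfig <- function(config, path) {
  unknown <- .checkKeys(config, .configSchema)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  yaml::write_yaml(config, path)
  invisible(path)
}
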
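# Multivalent bond free energy: per-bond free energy (hybridization +
# configurational cost), partition function over bond matchings of mobile
# linkers, landscape over the grid, strand-number calibration and
# temperature sweeps.

#' @importFrom Matrix sparseMatrix Diagonal solve
NULL

.avogadro <- 6.02214076e23

#' Reference concentration in superball units
#'
#' Converts a molar concentration to particles per sigma_c^3; the default
#' standard state 1 M with sigma_c = 1.04 micrometers gives the rho0 used
#' throughout.
#'
#' @param molar concentration in mol/L.
#' @param sigmaUm sigma_c expressed in micrometers.
#' @return concentration in 1/sigma_c^3.
#' @export
rho0FromMolar <- function(molar = 1, sigmaUm = 1.04) {
  perUm3 <- molar * .avogadro / 1e15
  perUm3 * sigmaUm^3
}

#' Bond model parameters
#'
#' @param betaDG0 hybridization free energy in k_BT (from
#'   \code{\link{duplexDG0}}).
#' @param rho0 reference concentration in 1/sigma_c^3.
#' @param nGamma number of mobile sticky-end strands on the sphere.
#' @param nDelta number of mobile sticky-end strands on the cube.
#' @param l linker length in sigma_c.
#' @return a validated list of class `BondParams`.
#' @export
bondParams <- function(betaDG0, rho0 = rho0FromMolar(), nGamma, nDelta,
                       l = 0.025) {
  if (rho0 <= 0) stop("rho0 must be positive")
  if (nGamma < 1 || nDelta < 1) stop("strand counts must be >= 1")
  if (l <= 0) stop("l must be positive")
  structure(list(betaDG0 = betaDG0, rho0 = rho0,
                 nGamma = as.integer(round(nGamma)),
                 nDelta = as.integer(round(nDelta)), l = l),
            class = "BondParams")
}

#' Configurational cost of forming one bond
#'
#' `beta*dG_cnf = -ln( Omega_gammadelta / (rho0 * Omega_gamma *
#' Omega_delta) )`: the entropy lost when a sphere strand and a cube
#' strand, each free to roam its own shell, become confined to the
#' overlap region.  An empty overlap returns +Inf (unbindable site).
#'
#' @param spaces a \linkS4class{ConfigSpaces} object, or a list/data.frame
#'   with elements `omegaGamma`, `omegaDelta`, `omegaGammaDelta`.
#' @param rho0 reference concentration (1/sigma_c^3).
#' @return configurational cost in k_BT (vectorized over rows).
#' @export
configCost <- function(spaces, rho0 = rho0FromMolar()) {
  if (is(spaces, "ConfigSpaces"))
    spaces <- list(omegaGamma = spaces@omegaGamma,
                   omegaDelta = spaces@omegaDelta,
                   omegaGammaDelta = spaces@omegaGammaDelta)
  og <- spaces$omegaGamma; od <- spaces$omegaDelta
  ogd <- spaces$omegaGammaDelta
  if (any(og <= 0) || any(od <= 0))
    stop("shell volumes must be positive")
  out <- -log(ogd / (rho0 * og * od))
  out[ogd <= 0] <- Inf
  out
}

#' Per-bond free energy
#'
#' `beta*dG_gammadelta = beta*dG0 + beta*dG_cnf`: hybridization gain plus
#' configurational cost of one sphere-cube linker bond.
#'
#' @param betaDG0 hybridization free energy (k_BT).
#' @param betaDGcnf configurational cost (k_BT), may be +Inf.
#' @return bond free energy in k_BT.
#' @export
bondStrength <- function(betaDG0, betaDGcnf) betaDG0 + betaDGcnf

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Multivalent bond free energy of a mobile-linker patch
#'
#' Exact partition function over bond matchings of n_gamma identical
#' mobile sphere strands and n_delta identical mobile cube strands with a
#' single bond strength:
#' `Z = sum_b C(n_gamma, b) C(n_delta, b) b! q^b`, `q = exp(-beta*dG)`,
#' and `beta*F_bond = -ln Z <= 0`.  Evaluated with log-sum-exp for large
#' counts; vectorized over `betaDGbond`.
#'
#' @param nGamma,nDelta strand counts (>= 0).
#' @param betaDGbond per-bond free energy in k_BT (may be +Inf for an
#'   unbindable geometry, giving 0).
#' @return beta*F_bond in k_BT (<= 0), same length as `betaDGbond`.
#' @export
multivalentFreeEnergy <- function(nGamma, nDelta, betaDGbond) {
  if (nGamma < 0 || nDelta < 0) stop("strand counts must be non-negative")
  bmax <- min(nGamma, nDelta)
  if (bmax == 0) return(rep(0, length(betaDGbond)))
  b <- 0:bmax
  base <- lchoose(nGamma, b) + lchoose(nDelta, b) + lfactorial(b)
  out <- numeric(length(betaDGbond))
  logq <- -betaDGbond
  chunk <- max(1L, floor(5e6 / (bmax + 1)))
  for (s in seq(1, length(logq), by = chunk)) {
    e <- min(length(logq), s + chunk - 1)
    lq <- logq[s:e]
    m <- outer(lq, b) + rep(base, each = length(lq))
    m[lq == -Inf, ] <- -Inf
    m[lq == -Inf, 1] <- 0
    mx <- apply(m, 1, max)
    out[s:e] <- -(mx + log(rowSums(exp(m - mx))))
  }
  out
}

#' Joint bond free energy of two spheres sharing the cube's strand pool
#'
#' Partition function for two bound spheres, each with n_gamma strands,
#' drawing bonds from the same n_delta cube strands:
#' `Z = sum_{b1,b2} C(ng,b1) C(ng,b2) C(nd,b1) C(nd-b1,b2) b1! b2!
#' q1^b1 q2^b2`.  Used to quantify how little the per-sphere free energy
#' depends on the number of bound spheres when n_delta is large.
#'
#' @param nGamma per-sphere strand count.
#' @param nDelta cube strand count.
#' @param betaDG1,betaDG2 per-bond free energies at the two spheres'
#'   contact sites (k_BT).
#' @return total beta*F_bond of the two-sphere system (k_BT).
#' @export
pairBondFreeEnergy <- function(nGamma, nDelta, betaDG1, betaDG2) {
  b1 <- 0:min(nGamma, nDelta)
  a1 <- lchoose(nGamma, b1) + lfactorial(b1) - b1 * betaDG1 +
    lchoose(nDelta, b1)
  terms <- lapply(seq_along(b1), function(i) {
    bb <- b1[i]
    b2 <- 0:min(nGamma, nDelta - bb)
    a1[i] + lchoose(nGamma, b2) + lfactorial(b2) - b2 * betaDG2 +
      lchoose(nDelta - bb, b2)
  })
  -.logSumExp(unlist(terms))
}

# Per-site configurational cost, computed once per octahedral orbit.
.landscapeCnf <- function(grid, alpha, l, rho0, nSamples, seed) {
  og <- shellVolumeSphere(alpha * grid@sigmaC / 2, l)
  od <- shellVolumeSuperball(grid, l, seed = seed)
  reps <- grid@orbitRep
  ov <- overlapVolume(grid, reps, alpha, l, nSamples, seed)
  cnfRep <- configCost(list(omegaGamma = og, omegaDelta = od$volume,
                            omegaGammaDelta = ov$volume), rho0)
  list(cnf = cnfRep[grid@orbit], cnfRep = cnfRep,
       omegaGamma = og, omegaDelta = od$volume)
}

.betaDFfromF <- function(betaF, faces) {
  mins <- tapply(betaF, faces, min)
  betaF - mean(mins)
}

#' Bond free energy at arbitrary surface points
#'
#' Evaluates the multivalent bond free energy beta*F_bond at explicit
#' surface positions (not necessarily grid sites), e.g. the exact face
#' center, edge midpoint or corner; useful for barrier scans that do not
#' need a whole landscape.
#'
#' @param grid a \linkS4class{SuperballGrid} (supplies n, sigma_c and the
#'   superball shell volume).
#' @param points m x 3 matrix of on-surface points.
#' @param alpha size ratio.
#' @param params a `BondParams` list.
#' @param mc list with `nSamples` and `seed`.
#' @return data.frame with columns `betaDGcnf`, `betaDGbond`,
#'   `betaFbond`.
#' @export
pointFreeEnergy <- function(grid, points, alpha, params,
                            mc = list(nSamples = 2e5, seed = 1)) {
  stopifnot(inherits(params, "BondParams"))
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  nrm <- surfaceNormal(p, grid@n, grid@sigmaC)
  og <- shellVolumeSphere(alpha * grid@sigmaC / 2, params$l)
  od <- shellVolumeSuperball(grid, params$l, seed = mc$seed)
  ov <- overlapVolume(grid, p, alpha, params$l, mc$nSamples, mc$seed,
                      normals = nrm)
  cnf <- configCost(list(omegaGamma = og, omegaDelta = od$volume,
                         omegaGammaDelta = ov$volume), params$rho0)
  bond <- bondStrength(params$betaDG0, cnf)
  data.frame(betaDGcnf = cnf, betaDGbond = bond,
             betaFbond = multivalentFreeEnergy(params$nGamma,
                                               params$nDelta, bond))
}

#' Free-energy landscape over the superball surface
#'
#' Per-site multivalent bond free energy beta*F_bond for a single bound
#' sphere (N_s = 1) and the barrier beta*dF relative to the face-center
#' minimum (averaged over the six faces).  The configurational cost is
#' evaluated by Monte Carlo once per octahedral orbit of the grid.
#'
#' @param grid a \linkS4class{SuperballGrid}.
#' @param params a `BondParams` list from \code{\link{bondParams}}.
#' @param alpha sphere-to-cube size ratio.
#' @param temperature temperature in Kelvin recorded with the landscape
#'   (must match the temperature at which `params$betaDG0` was computed).
#' @param mc list with `nSamples` (per site) and `seed`.
#' @return a \linkS4class{Landscape}.
#' @export
computeLandscape <- function(grid, params, alpha,
                             temperature = 297.15,
                             mc = list(nSamples = 2e5, seed = 1)) {
  stopifnot(inherits(params, "BondParams"))
  geo <- .landscapeCnf(grid, alpha, params$l, params$rho0,
                       mc$nSamples, mc$seed)
  bondRep <- bondStrength(params$betaDG0, geo$cnfRep)
  betaFRep <- multivalentFreeEnergy(params$nGamma, params$nDelta, bondRep)
  betaF <- betaFRep[grid@orbit]
  betaDF <- .betaDFfromF(betaF, faceLabels(grid))
  new("Landscape", gridId = grid@id, alpha = alpha,
      temperature = temperature, betaFbond = betaF,
      betaDGcnf = geo$cnf, betaDF = betaDF,
      params = list(nGamma = params$nGamma, nDelta = params$nDelta,
                    betaDG0 = params$betaDG0, rho0 = params$rho0,
                    l = params$l, omegaGamma = geo$omegaGamma,
                    omegaDelta = geo$omegaDelta,
                    nSamples = mc$nSamples, seed = mc$seed))
}

# Rebuild a landscape from stored configurational costs at a new
# hybridization free energy (the geometry term is temperature independent).
.relandscape <- function(grid, landscape, betaDG0, temperature) {
  cnfRep <- landscape@betaDGcnf[grid@orbitRep]
  bondRep <- bondStrength(betaDG0, cnfRep)
  betaFRep <- multivalentFreeEnergy(landscape@params$nGamma,
                                    landscape@params$nDelta, bondRep)
  betaF <- betaFRep[grid@orbit]
  p <- landscape@params
  p$betaDG0 <- betaDG0
  new("Landscape", gridId = landscape@gridId, alpha = landscape@alpha,
      temperature = temperature, betaFbond = betaF,
      betaDGcnf = landscape@betaDGcnf,
      betaDF = .betaDFfromF(betaF, faceLabels(grid)), params = p)
}

#' Landscapes across a temperature sweep
#'
#' Recomputes the hybridization free energy beta*dG0(T) of the linker
#' duplex at each requested temperature and rebuilds the landscape from a
#' single set of configurational-cost integrals (the configurational
#' entropy term does not change with temperature).
#'
#' @inheritParams computeLandscape
#' @param temperaturesC temperatures in degrees Celsius.
#' @param thermo list with `seqA`, `seqB`, `saltM` and optionally
#'   `tailPenalty` describing the sticky-end duplex.
#' @return named list of \linkS4class{Landscape} objects, one per
#'   temperature.
#' @export
temperatureSweep <- function(grid, params, alpha, temperaturesC,
                             thermo = list(seqA = "GTAGAAGTAGG",
                                           seqB = "CCTACTTCTAC",
                                           saltM = 0.2, tailPenalty = 0),
                             mc = list(nSamples = 2e5, seed = 1)) {
  tp <- if (is.null(thermo$tailPenalty)) 0 else thermo$tailPenalty
  base <- computeLandscape(grid, params, alpha,
                           temperature = 273.15 + temperaturesC[1],
                           mc = mc)
  out <- lapply(temperaturesC, function(tc) {
    tk <- 273.15 + tc
    d <- duplexDG0(thermo$seqA, thermo$seqB, temperature = tk,
                   saltM = thermo$saltM, tailPenalty = tp)
    .relandscape(grid, base, d@betaDG0, tk)
  })
  names(out) <- sprintf("T%gC", temperaturesC)
  out
}

#' Facet crossing rate of a single sphere from the landscape
#'
#' Probability per MC sweep that a sphere starting at the face-center site
#' of one face reaches any site of a different face, computed as the
#' inverse mean first-passage time of the actual Metropolis chain (sparse
#' linear solve), so the entropic prefactor of the barrier crossing is
#' included.
#'
#' @param grid a \linkS4class{SuperballGrid}.
#' @param energy per-site beta*F (k_BT), e.g. `betaFbond(landscape)`.
#' @param face face whose center the sphere starts from.
#' @return crossing probability per sweep (1/MFPT).
#' @export
crossingRate <- function(grid, energy, face = "+x") {
  faces <- faceLabels(grid)
  onFace <- which(faces == face)
  adj <- adjacency(grid)
  deg <- lengths(adj)
  inA <- integer(nSites(grid)); inA[onFace] <- seq_along(onFace)
  iAll <- rep.int(onFace, deg[onFace])
  jAll <- unlist(adj[onFace], use.names = FALSE)
  p <- pmin(1, (deg[iAll] / deg[jAll]) *
              exp(-(energy[jAll] - energy[iAll]))) / deg[iAll]
  rs <- as.numeric(rowsum(p, inA[iAll]))  # total move prob per row
  keep <- inA[jAll] > 0L
  # self-loops cancel in M = I - P_AA once rows carry their total move
  # probability on the diagonal
  P <- sparseMatrix(i = inA[iAll[keep]], j = inA[jAll[keep]],
                    x = p[keep],
                    dims = c(length(onFace), length(onFace)))
  M <- Diagonal(length(onFace), rs) - P
  start <- which(onFace == nearestSite(
    grid, surfacePoint(.faceDir(face), grid@n, grid@sigmaC)))
  tau <- tryCatch(Matrix::solve(M, rep(1, length(onFace))),
                  error = function(e) NULL)
  # barriers of hundreds of k_BT make M numerically singular; the escape
  # rate is zero to machine precision there
  if (is.null(tau)) return(0)
  max(0, 1 / as.numeric(tau[start]))
}

.faceDir <- function(face) {
  ax <- match(substr(face, 2, 2), c("x", "y", "z"))
  v <- c(0, 0, 0)
  v[ax] <- if (substr(face, 1, 1) == "-") -1 else 1
  v
}

#' Scale a calibrated strand count to another size ratio
#'
#' The calibrated quantity is a strand density, so the per-sphere count
#' grows with the sphere surface area: `n(alpha) = round(nRef *
#' (alpha/alphaRef)^2)`.
#'
#' @param nRef calibrated count at `alphaRef`.
#' @param alpha target size ratio.
#' @param alphaRef reference size ratio (default 0.63, the smallest).
#' @return integer strand count (>= 1).
#' @export
scaleStrandCount <- function(nRef, alpha, alphaRef = 0.63) {
  max(1L, as.integer(round(nRef * (alpha / alphaRef)^2)))
}

#' Cube-to-sphere strand count ratio from the grafting densities
#'
#' Converts the experimental grafting densities (strands per square
#' micrometer on each body) into the ratio n_delta / n_gamma(alphaRef)
#' via the two surface areas.
#'
#' @param grid a \linkS4class{SuperballGrid} (supplies the superball area).
#' @param alphaRef size ratio whose sphere area anchors the ratio.
#' @param sphereDensity,cubeDensity grafting densities in strands/um^2.
#' @return numeric ratio n_delta per calibrated n_gamma.
#' @export
strandDensityRatio <- function(grid, alphaRef = 0.63, sphereDensity = 300,
                               cubeDensity = 2e4) {
  aCube <- superballArea(grid@n, grid@sigmaC)
  aSphere <- pi * (alphaRef * grid@sigmaC)^2
  (cubeDensity * aCube) / (sphereDensity * aSphere)
}

#' Calibrate the strand number from the mobility of the smallest spheres
#'
#' Chooses the number of sphere strands as the threshold above which the
#' motion of the smallest spheres (alpha = 0.63) would become constrained,
#' contradicting the observation that they diffuse across facets: the
#' returned n_gamma is the largest count whose facet crossing rate is
#' still at least `maxRate` per MC sweep (default 1e-6).  The cube strand
#' count is tied to n_gamma through the grafting-density ratio.  The
#' crossing rate is monotonically decreasing in n_gamma, so a bracketed
#' binary search is exact.
#'
#' @param grid a \linkS4class{SuperballGrid}.
#' @param alphaRef reference size ratio (paper: 0.63).
#' @param betaDG0 hybridization free energy (k_BT) at the working
#'   temperature.
#' @param rho0 reference concentration (1/sigma_c^3).
#' @param l linker length (sigma_c).
#' @param deltaPerGamma n_delta per n_gamma (default from
#'   \code{\link{strandDensityRatio}}).
#' @param maxRate crossing-rate threshold per sweep defining
#'   "unconstrained".
#' @param nMax upper bound for the search.
#' @param mc list with `nSamples` and `seed` for the configurational
#'   integrals.
#' @return list with `nGamma`, `nDelta`, the achieved `rate`, and the
#'   rate at `nGamma + 1` (`rateNext`).
#' @export
calibrateStrandNumber <- function(grid, alphaRef = 0.63, betaDG0,
                                  rho0 = rho0FromMolar(), l = 0.025,
                                  deltaPerGamma = NULL, maxRate = 1e-6,
                                  nMax = 400,
                                  mc = list(nSamples = 2e5, seed = 1)) {
  if (is.null(deltaPerGamma))
    deltaPerGamma <- strandDensityRatio(grid, alphaRef)
  geo <- .landscapeCnf(grid, alphaRef, l, rho0, mc$nSamples, mc$seed)
  bondRep <- bondStrength(betaDG0, geo$cnfRep)
  rateAt <- function(ng) {
    nd <- max(1L, as.integer(round(deltaPerGamma * ng)))
    betaF <- multivalentFreeEnergy(ng, nd, bondRep)[grid@orbit]
    crossingRate(grid, betaF)
  }
  if (rateAt(1L) < maxRate)
    stop("calibration unsatisfiable: even n_gamma = 1 is constrained ",
         "(rate ", format(rateAt(1L)), " < ", format(maxRate), ")")
  lo <- 1L; hi <- 2L
  while (hi <= nMax && rateAt(hi) >= maxRate) { lo <- hi; hi <- 2L * hi }
  if (hi > nMax)
    stop("calibration unsatisfiable: rate still above threshold at nMax = ",
         nMax)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (rateAt(mid) >= maxRate) lo <- mid else hi <- mid
  }
  list(nGamma = lo,
       nDelta = max(1L, as.integer(round(deltaPerGamma * lo))),
       rate = rateAt(lo), rateNext = rateAt(hi))
}
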
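#' @import methods
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.csv write.csv head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib FlexColloid, .registration = TRUE
NULL

#' DuplexThermo: hybridization thermodynamics of a DNA duplex
#'
#' Holds the nearest-neighbor enthalpy/entropy sums for a perfectly
#' complementary duplex together with the temperature, monovalent salt
#' concentration and the resulting standard free energy on both the
#' kcal/mol and the dimensionless (k_BT) scale.
#'
#' @slot seqA,seqB 5'->3' sequences of the two strands.
#' @slot dH enthalpy in kcal/mol (salt independent).
#' @slot dS entropy in cal/mol/K after the monovalent salt correction.
#' @slot temperature temperature in Kelvin.
#' @slot saltM monovalent salt concentration in mol/L.
#' @slot tailPenalty additive inert-tail correction in units of k_BT.
#' @slot dG0 standard hybridization free energy in kcal/mol
#'   (includes the tail correction).
#' @slot betaDG0 dG0 expressed in units of k_BT.
#' @export
setClass("DuplexThermo",
  representation(seqA = "character", seqB = "character",
                 dH = "numeric", dS = "numeric",
                 temperature = "numeric", saltM = "numeric",
                 tailPenalty = "numeric",
                 dG0 = "numeric", betaDG0 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0 K")
    if (object@saltM <= 0) msg <- c(msg, "saltM must be > 0")
    R <- 1.98720425864083e-3
    expected <- object@dG0 / (R * object@temperature)
    if (abs(expected - object@betaDG0) > 1e-8)
      msg <- c(msg, "betaDG0 inconsistent with dG0/(R*T)")
    if (length(msg)) msg else TRUE
  })

#' SuperballGrid: discretized superball surface
#'
#' A quasi-uniform point set on the implicit surface
#' |2x/sigma_c|^n + |2y/sigma_c|^n + |2z/sigma_c|^n = 1 with outward unit
#' normals, Gaussian curvature, face labels by dominant axis, a symmetric
#' nearest-neighbor move graph and the 48-fold octahedral orbit structure
#' used to share free-energy evaluations between symmetry-equivalent sites.
#'
#' @slot n superball roundness exponent (n = 2 sphere, n -> Inf cube).
#' @slot sigmaC edge length, the unit of length downstream.
#' @slot sites data.frame with columns x, y, z, nx, ny, nz, gamma, face.
#' @slot adjacency list of integer vectors, symmetric neighbor graph.
#' @slot orbit integer orbit id per site (sites in one orbit are related by
#'   an octahedral symmetry operation).
#' @slot orbitRep integer site index of one representative per orbit.
#' @slot targetSites requested number of sites.
#' @slot seed integer seed used for the construction.
#' @slot id character identity string for consistency checks.
#' @export
setClass("SuperballGrid",
  representation(n = "numeric", sigmaC = "numeric", sites = "data.frame",
                 adjacency = "list", orbit = "integer", orbitRep = "integer",
                 targetSites = "numeric", seed = "numeric", id = "character"),
  validity = function(object) {
    msg <- character()
    s <- object@sites
    need <- c("x", "y", "z", "nx", "ny", "nz", "gamma", "face")
    if (!all(need %in% names(s)))
      msg <- c(msg, "sites must have columns x,y,z,nx,ny,nz,gamma,face")
    if (length(object@adjacency) != nrow(s))
      msg <- c(msg, "adjacency length must equal the number of sites")
    if (nrow(s) > 0) {
      v <- implicitValue(as.matrix(s[, c("x", "y", "z")]),
                         object@n, object@sigmaC)
      if (max(abs(v)) > 1e-8)
        msg <- c(msg, "sites do not lie on the superball surface")
      if (any(s$gamma < -1e-8))
        msg <- c(msg, "Gaussian curvature must be non-negative")
      deg <- lengths(object@adjacency)
      if (any(deg < 3))
        msg <- c(msg, "each site needs at least 3 neighbors")
    }
    if (length(msg)) msg else TRUE
  })

#' ConfigSpaces: configurational volumes of mobile linkers
#'
#' Monte Carlo estimates of the configurational spaces available to an
#' unbound sphere strand (Omega_gamma), an unbound cube strand
#' (Omega_delta) and a hybridized pair (Omega_gammadelta) for a sphere
#' held at normal distance h = l + alpha*sigma_c/2 above a surface site.
#' Volumes are in units of sigma_c^3.
#'
#' @slot omegaGamma,omegaDelta,omegaGammaDelta volumes (sigma_c^3).
#' @slot nSamples Monte Carlo sample count used for omegaGammaDelta.
#' @slot mcStderr standard error of the omegaGammaDelta estimate.
#' @slot seed integer RNG seed.
#' @export
setClass("ConfigSpaces",
  representation(omegaGamma = "numeric", omegaDelta = "numeric",
                 omegaGammaDelta = "numeric", nSamples = "numeric",
                 mcStderr = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(c(object@omegaGamma, object@omegaDelta,
              object@omegaGammaDelta) < 0))
      msg <- c(msg, "volumes must be non-negative")
    if (object@omegaGammaDelta >
        min(object@omegaGamma, object@omegaDelta) + 4 * object@mcStderr)
      msg <- c(msg, "overlap volume exceeds the smaller shell volume")
    if (length(msg)) msg else TRUE
  })

#' Landscape: multivalent bond free energy over the grid
#'
#' Per-site multivalent bond free energy beta*F_bond and the barrier
#' beta*dF = beta*F_bond(site) - beta*F_bond(face center), both in k_BT,
#' for one sphere bound to the superball at a given size ratio and
#' temperature.
#'
#' @slot gridId identity string of the grid the landscape was computed on.
#' @slot alpha sphere-to-cube size ratio sigma_s/sigma_c.
#' @slot temperature temperature in Kelvin.
#' @slot betaFbond per-site bond free energy (k_BT, <= 0).
#' @slot betaDGcnf per-site configurational cost of a single bond (k_BT);
#'   kept so that temperature sweeps can re-use the geometry.
#' @slot betaDF per-site barrier relative to the face-center minimum (k_BT).
#' @slot params list with nGamma, nDelta, betaDG0, rho0, l, omegaGamma,
#'   omegaDelta, nSamples, seed.
#' @export
setClass("Landscape",
  representation(gridId = "character", alpha = "numeric",
                 temperature = "numeric", betaFbond = "numeric",
                 betaDGcnf = "numeric", betaDF = "numeric",
                 params = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@betaFbond) != length(object@betaDF))
      msg <- c(msg, "betaFbond and betaDF lengths differ")
    finite <- is.finite(object@betaDF)
    if (any(object@betaDF[finite] < -1e-6))
      msg <- c(msg, "betaDF must be >= 0 up to numerical tolerance")
    if (any(object@betaFbond[is.finite(object@betaFbond)] > 1e-9))
      msg <- c(msg, "betaFbond must be <= 0")
    if (length(msg)) msg else TRUE
  })

#' MCState: instantaneous state of the surface Monte Carlo sampler
#'
#' @slot siteIndices current site index of every sphere.
#' @slot step Monte Carlo sweep counter.
#' @slot rngSeed integer seed of the run.
#' @slot quasi2d TRUE when the top and bottom faces are excluded.
#' @slot alpha sphere-to-cube size ratio.
#' @slot gridId identity string of the grid.
#' @export
setClass("MCState",
  representation(siteIndices = "integer", step = "numeric",
                 rngSeed = "numeric", quasi2d = "logical",
                 alpha = "numeric", gridId = "character"))

#' SurfaceTrajectory: recorded contact points of bound spheres
#'
#' @slot steps MC sweep index of every record (strictly increasing).
#' @slot sites integer matrix (records x spheres) of site indices; may be
#'   NA when a trajectory was re-imported from coordinates only.
#' @slot coords numeric array (records x spheres x 3) of contact points.
#' @slot faces character matrix (records x spheres) of face labels.
#' @slot alpha size ratio; @slot gridId grid identity string.
#' @slot quasi2d logical flag; @slot seed integer run seed.
#' @slot acceptanceRate mean Metropolis acceptance rate of the run.
#' @export
setClass("SurfaceTrajectory",
  representation(steps = "numeric", sites = "matrix", coords = "array",
                 faces = "matrix", alpha = "numeric", gridId = "character",
                 quasi2d = "logical", seed = "numeric",
                 acceptanceRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@steps) != dim(object@coords)[1])
      msg <- c(msg, "steps and coords record counts differ")
    if (is.unsorted(object@steps, strictly = TRUE))
      msg <- c(msg, "steps must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "DuplexThermo", function(object) {
  cat("DuplexThermo:", object@seqA, "/", object@seqB, "\n")
  cat(sprintf("  T = %.2f K, [Na+] = %.3g M\n",
              object@temperature, object@saltM))
  cat(sprintf("  dH = %.2f kcal/mol, dS = %.2f cal/mol/K\n",
              object@dH, object@dS))
  cat(sprintf("  dG0 = %.4f kcal/mol  (beta*dG0 = %.4f k_BT)\n",
              object@dG0, object@betaDG0))
})

setMethod("show", "SuperballGrid", function(object) {
  cat(sprintf("SuperballGrid: %d sites, n = %g, sigma_c = %g\n",
              nrow(object@sites), object@n, object@sigmaC))
  cat(sprintf("  %d octahedral orbits, mean degree %.2f\n",
              length(object@orbitRep),
              mean(lengths(object@adjacency))))
})

setMethod("show", "ConfigSpaces", function(object) {
  cat("ConfigSpaces (sigma_c^3):\n")
  cat(sprintf("  Omega_gamma      = %.6g\n", object@omegaGamma))
  cat(sprintf("  Omega_delta      = %.6g\n", object@omegaDelta))
  cat(sprintf("  Omega_gammadelta = %.6g (stderr %.2g, %g samples)\n",
              object@omegaGammaDelta, object@mcStderr, object@nSamples))
})

setMethod("show", "Landscape", function(object) {
  fin <- is.finite(object@betaDF)
  cat(sprintf("Landscape: alpha = %.3g, T = %.2f K, %d sites\n",
              object@alpha, object@temperature, length(object@betaDF)))
  cat(sprintf("  n_gamma = %d, n_delta = %d, beta*dG0 = %.3f\n",
              object@params$nGamma, object@params$nDelta,
              object@params$betaDG0))
  cat(sprintf("  beta*dF range: [%.3g, %.3g] k_BT\n",
              min(object@betaDF[fin]), max(object@betaDF[fin])))
})

setMethod("show", "SurfaceTrajectory", function(object) {
  cat(sprintf(
    "SurfaceTrajectory: %d spheres, %d records, alpha = %.3g%s\n",
    ncol(object@sites), length(object@steps), object@alpha,
    if (object@quasi2d) " (quasi-2D)" else ""))
})
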
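# Metropolis Monte Carlo dynamics of bound spheres hopping on the grid.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Quasi-2D exclusion mask
#'
#' For large spheres the gravitational height confines the motion to a
#' plane, which the model mimics by excluding the top and bottom faces of
#' the cube.  The auto rule applies the mask for alpha >= 1.49.
#'
#' @param grid a \linkS4class{SuperballGrid}.
#' @param quasi2d logical, or `"auto"` to apply the alpha rule.
#' @param alpha size ratio (used by the auto rule).
#' @return logical vector, TRUE for excluded sites.
#' @export
quasi2dMask <- function(grid, quasi2d = "auto", alpha = NULL) {
  if (identical(quasi2d, "auto")) {
    if (is.null(alpha)) stop("alpha required for the auto quasi-2D rule")
    quasi2d <- alpha >= 1.49
  }
  if (quasi2d) faceLabels(grid) %in% c("+z", "-z")
  else rep(FALSE, nSites(grid))
}

#' Number of bound spheres observed per size ratio
#'
#' The coordination numbers of the most frequently assembled colloidal
#' molecules: AB_6 up to alpha = 1.20, AB_4 at 1.49, AB_3 at 1.98 and
#' AB_2 at the two largest size ratios.
#'
#' @param alpha size ratio.
#' @return integer sphere count.
#' @export
sphereCountForAlpha <- function(alpha) {
  tab <- c("0.63" = 6L, "0.93" = 6L, "1.2" = 6L, "1.49" = 4L,
           "1.98" = 3L, "3.19" = 2L, "4.44" = 2L)
  key <- as.character(alpha)
  if (!key %in% names(tab))
    stop("no recorded coordination number for alpha = ", alpha)
  unname(tab[key])
}

#' Initialize the sphere configuration on the grid
#'
#' Uniform random non-overlapping placement of the spheres on allowed
#' (non-excluded) sites; deterministic given the seed.  Hard-sphere
#' exclusion rejects configurations with center-center distance below
#' sigma_s.
#'
#' @param grid a \linkS4class{SuperballGrid}.
#' @param landscape a \linkS4class{Landscape} on the same grid.
#' @param nSpheres number of spheres to place (>= 0).
#' @param alpha size ratio (consistency-checked against the landscape).
#' @param quasi2d logical or `"auto"` (see \code{\link{quasi2dMask}}).
#' @param seed integer seed.
#' @param maxTries placement restarts before giving up.
#' @param distinctFaces require the spheres to start on distinct,
#'   mutually compatible faces: faces whose relaxed (face-center)
#'   sphere positions keep every pair at least sigma_s apart (default
#'   TRUE when nSpheres is at most the number of available faces).
#'   Assembled colloidal molecules carry their spheres on distinct
#'   facets near the face centers — at alpha = 4.44 this forces the two
#'   spheres onto opposite faces — whereas unrestricted random placement
#'   can start large spheres wedged against an edge in configurations
#'   the assembly process never produces.
#' @return an \linkS4class{MCState}.
#' @export
initState <- function(grid, landscape, nSpheres, alpha = alphaRatio(landscape),
                      quasi2d = "auto", seed = 1, maxTries = 2000,
                      distinctFaces = NULL) {
  if (landscape@gridId != grid@id)
    stop("landscape was computed on a different grid")
  if (abs(alpha - landscape@alpha) > 1e-12)
    stop("alpha does not match the landscape")
  mask <- quasi2dMask(grid, quasi2d, alpha)
  q2d <- any(mask)
  allowed <- which(!mask & is.finite(betaFbond(landscape)))
  if (nSpheres == 0)
    return(new("MCState", siteIndices = integer(0), step = 0,
               rngSeed = as.numeric(seed), quasi2d = q2d, alpha = alpha,
               gridId = grid@id))
  centers <- .sphereCenters(grid, alpha, landscape@params$l)
  sigmaS <- alpha * grid@sigmaC
  nFacesAvail <- length(unique(faceLabels(grid)[allowed]))
  if (is.null(distinctFaces)) distinctFaces <- nSpheres <= nFacesAvail
  if (distinctFaces && nSpheres > nFacesAvail)
    stop("cannot place ", nSpheres, " spheres on ", nFacesAvail,
         " distinct faces")
  fl <- faceLabels(grid)
  # face compatibility: can two spheres sit at the two face centers?
  faceNames <- sort(unique(fl))
  fcSites <- vapply(faceNames, function(f)
    nearestSite(grid, surfacePoint(.faceDir(f), grid@n, grid@sigmaC)),
    integer(1))
  fcCenters <- centers[fcSites, , drop = FALSE]
  compatible <- as.matrix(stats::dist(fcCenters)) >= sigmaS
  dimnames(compatible) <- list(faceNames, faceNames)
  .withSeed(seed, {
    for (try in seq_len(maxTries)) {
      picked <- integer(0)
      ok <- TRUE
      for (s in seq_len(nSpheres)) {
        cand <- allowed[sample.int(length(allowed), 1L)]
        if (distinctFaces && length(picked) &&
            !all(compatible[fl[cand], fl[picked]])) { ok <- FALSE; break }
        if (length(picked) &&
            any(sqrt(colSums((t(centers[picked, , drop = FALSE]) -
                                centers[cand, ])^2)) < sigmaS)) {
          ok <- FALSE
          break
        }
        picked <- c(picked, cand)
      }
      if (ok) break
    }
    if (!ok)
      stop("could not place ", nSpheres,
           " non-overlapping spheres after ", maxTries, " restarts")
    new("MCState", siteIndices = as.integer(picked), step = 0,
        rngSeed = as.numeric(seed), quasi2d = q2d, alpha = alpha,
        gridId = grid@id)
  })
}

#' Run surface Metropolis Monte Carlo
#'
#' One MC step is one attempted move per sphere.  A move from site i to a
#' uniformly chosen neighbor j is accepted with probability
#' `min(1, (k_i/k_j) * exp(-(beta F_j - beta F_i)))`, where k is the
#' neighbor count (the correction that keeps detailed balance on an
#' irregular graph); moves onto excluded sites or into hard-sphere
#' overlaps are rejected.  Contact points are recorded every
#' `recordEvery` sweeps, starting from the post-equilibration state.
#'
#' @param state an \linkS4class{MCState} from \code{\link{initState}}.
#' @param landscape the \linkS4class{Landscape} driving the dynamics.
#' @param grid the \linkS4class{SuperballGrid} shared by both.
#' @param nSweeps production sweeps.
#' @param recordEvery record interval in sweeps.
#' @param equilibration sweeps discarded before recording.
#' @param seed integer seed (defaults to the state's seed).
#' @return a \linkS4class{SurfaceTrajectory}.
#' @export
runSurfaceMC <- function(state, landscape, grid, nSweeps = 1e7,
                         recordEvery = 50, equilibration = 1e5,
                         seed = state@rngSeed) {
  if (state@gridId != grid@id || landscape@gridId != grid@id)
    stop("state, landscape and grid identities do not match")
  csr <- .csrAdjacency(grid)
  mask <- quasi2dMask(grid, state@quasi2d, state@alpha)
  centers <- .sphereCenters(grid, state@alpha, landscape@params$l)
  res <- .cppRunSurfaceMC(csr$idx, csr$ptr, betaFbond(landscape), centers,
                          mask, state@siteIndices - 1L,
                          state@alpha * grid@sigmaC, as.numeric(nSweeps),
                          as.integer(recordEvery),
                          as.integer(equilibration), as.numeric(seed))
  sites <- res$sites
  steps <- seq(0, nSweeps, by = recordEvery)[seq_len(nrow(sites))]
  pos <- siteCoords(grid)
  coords <- array(NA_real_, dim = c(nrow(sites), ncol(sites), 3))
  faces <- matrix("", nrow(sites), ncol(sites))
  fl <- faceLabels(grid)
  for (s in seq_len(ncol(sites))) {
    coords[, s, ] <- pos[sites[, s], , drop = FALSE]
    faces[, s] <- fl[sites[, s]]
  }
  new("SurfaceTrajectory", steps = steps, sites = sites, coords = coords,
      faces = faces, alpha = state@alpha, gridId = grid@id,
      quasi2d = state@quasi2d, seed = as.numeric(seed),
      acceptanceRate = res$acceptance_rate)
}

#' Run an ensemble of independent surface MC trajectories
#'
#' Convenience wrapper: one random initialization and one run per seed
#' `baseSeed + runIndex`.
#'
#' @inheritParams runSurfaceMC
#' @param nSpheres spheres per run.
#' @param nRuns number of independent runs.
#' @param baseSeed base seed; run r uses `baseSeed + r`.
#' @param quasi2d passed to \code{\link{initState}}.
#' @return list of \linkS4class{SurfaceTrajectory} objects.
#' @export
runEnsemble <- function(grid, landscape, nSpheres, nRuns = 20,
                        nSweeps = 1e7, recordEvery = 50,
                        equilibration = 1e5, baseSeed = 1,
                        quasi2d = "auto") {
  lapply(seq_len(nRuns), function(r) {
    st <- initState(grid, landscape, nSpheres, quasi2d = quasi2d,
                    seed = baseSeed + r)
    runSurfaceMC(st, landscape, grid, nSweeps, recordEvery,
                 equilibration, seed = baseSeed + r)
  })
}

#' Count facet changes per sphere
#'
#' Number of times each sphere's recorded face label changes along the
#' trajectory; zero means the sphere stayed on its facet.
#'
#' @param traj a \linkS4class{SurfaceTrajectory}.
#' @return integer vector, one count per sphere.
#' @export
countFaceCrossings <- function(traj) {
  f <- traj@faces
  if (nrow(f) == 0) stop("trajectory is empty")
  vapply(seq_len(ncol(f)), function(s) {
    sum(f[-1, s] != f[-nrow(f), s])
  }, integer(1))
}

#' Metropolis transition matrix on an arbitrary graph
#'
#' Dense transition matrix of the neighbor-corrected Metropolis chain used
#' by the sampler; intended for small graphs when verifying detailed
#' balance against the stationary distribution `pi ~ exp(-beta F)`.
#'
#' @param adj list of integer neighbor vectors (symmetric).
#' @param energy per-node beta*F.
#' @return a dense transition probability matrix.
#' @export
transitionMatrix <- function(adj, energy) {
  n <- length(adj)
  deg <- lengths(adj)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      P[i, j] <- min(1, (deg[i] / deg[j]) * exp(-(energy[j] - energy[i]))) /
        deg[i]
    }
    P[i, i] <- 1 - sum(P[i, -i])
  }
  P
}
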
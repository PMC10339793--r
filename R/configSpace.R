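# Configurational spaces of mobile linkers: shells of thickness l around
# each body, and their overlap for a sphere held above a surface site.

#' Shell volume around a sphere
#'
#' Closed form for the exterior shell of thickness l around a sphere of
#' the given radius: `(4*pi/3) * ((r+l)^3 - r^3)`.  This is the
#' configurational space Omega_gamma of a mobile linker anchored on the
#' sphere surface.
#'
#' @param radius sphere radius (> 0), in sigma_c.
#' @param l linker length (>= 0), in sigma_c.
#' @return volume in sigma_c^3.
#' @export
shellVolumeSphere <- function(radius, l) {
  if (radius <= 0) stop("radius must be positive")
  if (l < 0) stop("l must be non-negative")
  (4 * pi / 3) * ((radius + l)^3 - radius^3)
}

.omegaDeltaCache <- new.env(parent = emptyenv())

#' Monte Carlo shell volume around the superball
#'
#' Estimates the volume of the exterior layer of thickness l around the
#' superball (the configurational space Omega_delta of a cube-anchored
#' linker) by uniform sampling in the bounding box, with the
#' distance-to-surface test of \code{\link{distanceToSurface}}.
#'
#' @param grid a \linkS4class{SuperballGrid} (supplies n and sigma_c).
#' @param l linker length in sigma_c.
#' @param nSamples Monte Carlo samples (>= 1e4).
#' @param seed integer seed.
#' @param cache reuse a previous estimate for the same (n, sigma_c, l,
#'   nSamples, seed).
#' @return list with elements `volume`, `stderr`, `nSamples`, `seed`.
#' @export
shellVolumeSuperball <- function(grid, l = 0.025, nSamples = 1e6, seed = 1,
                                 cache = TRUE) {
  if (l == 0) return(list(volume = 0, stderr = 0,
                          nSamples = nSamples, seed = seed))
  if (nSamples < 1e4) stop("nSamples must be at least 1e4")
  key <- sprintf("n%g-s%g-l%g-N%g-seed%d", grid@n, grid@sigmaC, l,
                 nSamples, as.integer(seed))
  if (cache && !is.null(.omegaDeltaCache[[key]]))
    return(.omegaDeltaCache[[key]])
  est <- .cppShellVolumeSuperball(grid@n, grid@sigmaC, l,
                                  as.integer(nSamples), as.numeric(seed))
  out <- list(volume = unname(est["volume"]), stderr = unname(est["stderr"]),
              nSamples = nSamples, seed = seed)
  if (cache) .omegaDeltaCache[[key]] <- out
  out
}

#' Overlap volume of the sphere and superball shells
#'
#' Monte Carlo estimate of Omega_gammadelta, the configurational space of
#' a hybridized linker pair: the intersection of the sphere's exterior
#' shell with the superball's exterior shell, for a sphere centered at
#' `h = l + alpha*sigma_c/2` above each requested site.  Sampling is
#' uniform over the spherical-cap slice of the sphere shell that faces the
#' surface site (which provably contains the overlap), so the estimator is
#' unbiased with a far higher acceptance fraction than box sampling.
#'
#' @param grid a \linkS4class{SuperballGrid}.
#' @param sites integer vector of site indices (or an m x 3 matrix of
#'   surface positions paired with `normals`).
#' @param alpha sphere-to-cube size ratio.
#' @param l linker length (sigma_c).
#' @param nSamples samples per site.
#' @param seed integer seed (decorrelated per site).
#' @param normals optional m x 3 matrix of outward normals when `sites`
#'   is a coordinate matrix (a displaced anchor point can be passed this
#'   way to model a sphere lifted off the surface).
#' @return data.frame with columns `volume`, `stderr`, `nAccept`.
#' @export
overlapVolume <- function(grid, sites, alpha, l = 0.025, nSamples = 2e5,
                          seed = 1, normals = NULL) {
  if (alpha <= 0) stop("alpha must be positive")
  if (is.matrix(sites)) {
    pos <- sites
    if (is.null(normals)) stop("normals required with coordinate input")
  } else {
    pos <- siteCoords(grid)[sites, , drop = FALSE]
    normals <- siteNormals(grid)[sites, , drop = FALSE]
  }
  est <- .cppOverlapVolumes(pos, normals, alpha, l, grid@n, grid@sigmaC,
                            as.integer(nSamples), as.numeric(seed))
  data.frame(volume = est[, "volume"], stderr = est[, "stderr"],
             nAccept = est[, "n_accept"])
}

#' Configurational spaces for a sphere at one surface site
#'
#' Bundles Omega_gamma (closed form), Omega_delta (cached Monte Carlo) and
#' Omega_gammadelta (per-site Monte Carlo) into a
#' \linkS4class{ConfigSpaces} object.
#'
#' @inheritParams overlapVolume
#' @param site one site index.
#' @param nSamplesDelta samples for the superball shell volume.
#' @return a \linkS4class{ConfigSpaces}.
#' @export
configSpaces <- function(grid, site, alpha, l = 0.025, nSamples = 2e5,
                         nSamplesDelta = 1e6, seed = 1) {
  og <- shellVolumeSphere(alpha * grid@sigmaC / 2, l)
  od <- shellVolumeSuperball(grid, l, nSamplesDelta, seed)
  ogd <- overlapVolume(grid, site, alpha, l, nSamples, seed)
  new("ConfigSpaces", omegaGamma = og, omegaDelta = od$volume,
      omegaGammaDelta = ogd$volume[1], nSamples = as.numeric(nSamples),
      mcStderr = ogd$stderr[1], seed = as.numeric(seed))
}

#' Tabulate per-site configurational spaces
#'
#' @inheritParams overlapVolume
#' @param sites integer vector of site indices.
#' @return data.frame with one row per site (site, omegaGamma, omegaDelta,
#'   omegaGammaDelta, stderr, nSamples, seed), suitable for CSV export.
#' @export
configSpaceTable <- function(grid, sites, alpha, l = 0.025, nSamples = 2e5,
                             seed = 1) {
  og <- shellVolumeSphere(alpha * grid@sigmaC / 2, l)
  od <- shellVolumeSuperball(grid, l, seed = seed)
  ov <- overlapVolume(grid, sites, alpha, l, nSamples, seed)
  data.frame(site = sites, omegaGamma = og, omegaDelta = od$volume,
             omegaGammaDelta = ov$volume, stderr = ov$stderr,
             nSamples = nSamples, seed = seed)
}
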
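#' Accessors for FlexColloid objects
#'
#' Small accessor functions in place of direct slot access.
#'
#' @param x a \linkS4class{SuperballGrid}, \linkS4class{Landscape} or
#'   \linkS4class{SurfaceTrajectory}.
#' @return `nSites()` the number of surface sites; `siteCoords()` an
#'   n x 3 matrix of positions; `siteNormals()` an n x 3 matrix of outward
#'   unit normals; `siteCurvature()` the per-site Gaussian curvature;
#'   `faceLabels()` the per-site face label (one of `"+x" "-x" "+y" "-y"
#'   "+z" "-z"`); `adjacency()` the neighbor list; `betaFbond()` and
#'   `betaDeltaF()` the per-site free energy and barrier of a landscape;
#'   `contactPoints()` the (records x spheres x 3) coordinate array of a
#'   trajectory.
#' @name accessors
NULL

#' @rdname accessors
#' @export
nSites <- function(x) nrow(x@sites)

#' @rdname accessors
#' @export
siteCoords <- function(x) as.matrix(x@sites[, c("x", "y", "z")])

#' @rdname accessors
#' @export
siteNormals <- function(x) as.matrix(x@sites[, c("nx", "ny", "nz")])

#' @rdname accessors
#' @export
siteCurvature <- function(x) x@sites$gamma

#' @rdname accessors
#' @export
faceLabels <- function(x) {
  if (is(x, "SuperballGrid")) x@sites$face else x@faces
}

#' @rdname accessors
#' @export
adjacency <- function(x) x@adjacency

#' @rdname accessors
#' @export
gridId <- function(x) if (is(x, "SuperballGrid")) x@id else x@gridId

#' @rdname accessors
#' @export
betaFbond <- function(x) x@betaFbond

#' @rdname accessors
#' @export
betaDeltaF <- function(x) x@betaDF

#' @rdname accessors
#' @export
alphaRatio <- function(x) x@alpha

#' @rdname accessors
#' @export
contactPoints <- function(x) x@coords

#' @rdname accessors
#' @export
trajectorySteps <- function(x) x@steps

#' @rdname accessors
#' @export
trajectorySites <- function(x) x@sites
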
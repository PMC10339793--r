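# Trajectory observables: position autocorrelation, in-plane mean
# displacement, facet occupancy.

.asTrajList <- function(traj) {
  if (is(traj, "SurfaceTrajectory")) list(traj) else traj
}

#' Position autocorrelation of the contact points
#'
#' `C_r(t) = < r_i(t0) . r_i(t0+t) / |r_i(t0)|^2 >`, averaged over the
#' bound spheres, over time origins (all records by default, or only the
#' first when `origins = "first"`, matching a single-origin estimate) and
#' over runs when an ensemble is given.  Positions are the contact points
#' of the spheres on the superball surface, so full decay to zero requires
#' the spheres to redistribute over the facets; confinement to the initial
#' facet shows up as a non-decaying plateau.
#'
#' @param traj a \linkS4class{SurfaceTrajectory} or a list of them.
#' @param lags integer lags in records (default: ~60 log-spaced lags).
#' @param origins `"all"` or `"first"`.
#' @return data.frame with columns `lag` (MC sweeps), `c_r`, `n` (number
#'   of averaged pairs).
#' @export
positionAutocorrelation <- function(traj, lags = NULL, origins = "all") {
  trajs <- .asTrajList(traj)
  nRec <- vapply(trajs, function(x) length(x@steps), numeric(1))
  if (any(nRec < 2)) stop("trajectory needs at least 2 records")
  recStep <- trajs[[1]]@steps[2] - trajs[[1]]@steps[1]
  maxLag <- min(nRec) - 1
  if (is.null(lags)) {
    lags <- unique(c(0, round(exp(seq(0, log(maxLag), length.out = 60)))))
    lags <- lags[lags <= maxLag]
  }
  lags <- sort(unique(as.integer(lags)))
  num <- numeric(length(lags)); cnt <- numeric(length(lags))
  for (tr in trajs) {
    co <- tr@coords
    nr <- dim(co)[1]; ns <- dim(co)[2]
    for (s in seq_len(ns)) {
      r <- co[, s, ]                     # nr x 3
      r2 <- rowSums(r * r)
      for (k in seq_along(lags)) {
        lg <- lags[k]
        if (lg >= nr) next
        t0 <- if (origins == "first") 1L else seq_len(nr - lg)
        dots <- rowSums(r[t0, , drop = FALSE] *
                          r[t0 + lg, , drop = FALSE])
        num[k] <- num[k] + sum(dots / r2[t0])
        cnt[k] <- cnt[k] + length(t0)
      }
    }
  }
  data.frame(lag = lags * recStep, c_r = num / cnt, n = cnt)
}

#' Onset of the position-autocorrelation decay
#'
#' First lag (in MC sweeps) at which the ensemble C_r(t) falls below a
#' threshold; the default 0.9 is the conventional 10 percent-decay
#' criterion for locating when the spheres start to decorrelate from
#' their initial positions.
#'
#' @param cr data.frame from \code{\link{positionAutocorrelation}}.
#' @param threshold C_r level defining the decay onset.
#' @return lag in MC sweeps (NA when C_r never crosses the threshold).
#' @export
decayOnset <- function(cr, threshold = 0.9) {
  below <- which(cr$c_r < threshold & cr$lag > 0)
  if (!length(below)) return(NA_real_)
  cr$lag[below[1]]
}

# in-plane coordinates of contact points on a face: drop the dominant axis
.inPlane <- function(points, face) {
  ax <- match(substr(face, 2, 2), c("x", "y", "z"))
  points[, -ax, drop = FALSE]
}

#' Mean in-plane displacement of the spheres
#'
#' Root-mean-square excursion of a sphere's contact point about its mean,
#' projected onto the plane of the facet it occupies (the facet is treated
#' as flat).  Spheres that change facet contribute per contiguous
#' same-face segment; segments shorter than `minSegment` records are
#' ignored.  Averaged over spheres and runs by pooling squared
#' deviations.
#'
#' @param traj a \linkS4class{SurfaceTrajectory} or list of them.
#' @param minSegment minimum records per same-face segment.
#' @return Delta r in units of sigma_c.
#' @export
meanDisplacement <- function(traj, minSegment = 10) {
  trajs <- .asTrajList(traj)
  ss <- 0; nn <- 0
  for (tr in trajs) {
    co <- tr@coords; fc <- tr@faces
    for (s in seq_len(dim(co)[2])) {
      f <- fc[, s]
      seg <- cumsum(c(TRUE, f[-1] != f[-length(f)]))
      for (g in split(seq_along(f), seg)) {
        if (length(g) < minSegment) next
        xy <- .inPlane(co[g, s, , drop = TRUE], f[g[1]])
        dev <- sweep(xy, 2, colMeans(xy))
        ss <- ss + sum(dev^2)
        nn <- nn + nrow(xy)
      }
    }
  }
  if (nn == 0) return(NA_real_)
  sqrt(ss / nn)
}

#' Facet occupancy fractions
#'
#' Fraction of records spent on each of the six faces, per sphere.
#'
#' @param traj a \linkS4class{SurfaceTrajectory}.
#' @return 6 x nSpheres matrix of fractions (rows sum to 1 per column),
#'   with face labels as row names.
#' @export
facetOccupancy <- function(traj) {
  if (length(traj@steps) == 0) stop("trajectory is empty")
  levs <- c("+x", "-x", "+y", "-y", "+z", "-z")
  out <- vapply(seq_len(ncol(traj@faces)), function(s) {
    tabulate(match(traj@faces[, s], levs), nbins = 6) /
      nrow(traj@faces)
  }, numeric(6))
  rownames(out) <- levs
  out
}
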
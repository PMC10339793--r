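#' Superball implicit function
#'
#' Evaluates `f(p) = |2x/sigma_c|^n + |2y/sigma_c|^n + |2z/sigma_c|^n - 1`:
#' negative inside the superball, zero on its surface, positive outside.
#' The exponent n interpolates between a sphere (n = 2) and a sharp cube
#' (n -> Inf); sigma_c is the edge length.
#'
#' @param point numeric length-3 vector or an m x 3 matrix of points.
#' @param n roundness exponent (>= 2).
#' @param sigmaC edge length (> 0).
#' @return numeric vector of implicit values.
#' @examples
#' implicitValue(c(0.5, 0, 0), n = 6, sigmaC = 1)  # face center: 0
#' @export
implicitValue <- function(point, n = 6, sigmaC = 1) {
  if (sigmaC <= 0) stop("sigmaC must be positive")
  if (n < 2) stop("n must be >= 2")
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  rowSums(abs(2 * p / sigmaC)^n) - 1
}

# Radial projection of directions (rows) onto the superball surface.
.radialSurface <- function(dirs, n, sigmaC) {
  s <- rowSums(abs(2 * dirs / sigmaC)^n)^(-1 / n)
  dirs * s
}

#' Gaussian curvature of the superball surface
#'
#' Gaussian curvature from the gradient and Hessian of the implicit
#' function, `K = (g . adj(H) g) / |g|^4`.  For the superball the Hessian
#' is diagonal, so `K = (g1^2 H2 H3 + g2^2 H1 H3 + g3^2 H1 H2)/|g|^4`.
#' Non-negative everywhere on the (convex) surface; zero at the flat face
#' centers for n > 2 and `4/sigma_c^2` everywhere for n = 2.
#'
#' @param point length-3 vector or m x 3 matrix of on-surface points.
#' @inheritParams implicitValue
#' @param tol tolerance on |f(point)| for the on-surface check.
#' @return numeric vector of curvatures (1/sigma_c^2).
#' @export
gaussianCurvature <- function(point, n = 6, sigmaC = 1, tol = 1e-6) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  f <- implicitValue(p, n, sigmaC)
  if (any(abs(f) > tol))
    stop("point lies off the superball surface (|f| = ",
         format(max(abs(f))), ")")
  a <- abs(2 * p / sigmaC)
  g <- (2 * n / sigmaC) * a^(n - 1) * sign(p)
  h <- (4 * n * (n - 1) / sigmaC^2) * a^(n - 2)
  # a = 0 with n = 2 gives 0^0; the correct limit is 1
  if (n == 2) h[] <- 8 / sigmaC^2
  num <- g[, 1]^2 * h[, 2] * h[, 3] + g[, 2]^2 * h[, 1] * h[, 3] +
    g[, 3]^2 * h[, 1] * h[, 2]
  num / rowSums(g^2)^2
}

.surfaceNormals <- function(p, n, sigmaC) {
  a <- abs(2 * p / sigmaC)
  g <- (2 * n / sigmaC) * a^(n - 1) * sign(p)
  g / sqrt(rowSums(g^2))
}

.faceOf <- function(p) {
  ax <- max.col(abs(p), ties.method = "first")
  sg <- sign(p[cbind(seq_len(nrow(p)), ax)])
  paste0(ifelse(sg >= 0, "+", "-"), c("x", "y", "z")[ax])
}

# 48 octahedral symmetry operations applied to an m x 3 matrix: all axis
# permutations combined with all sign flips.
.octahedralImages <- function(dirs) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  out <- vector("list", 48L)
  op <- 1L
  for (i in seq_len(6)) {
    pd <- dirs[, perms[i, ], drop = FALSE]
    for (j in seq_len(8)) {
      out[[op]] <- sweep(pd, 2, signs[j, ], `*`)
      op <- op + 1L
    }
  }
  out
}

#' Build a discretized superball surface grid
#'
#' Quasi-uniform surface sites from a Fibonacci sphere restricted to the
#' octahedral fundamental domain (x >= y >= z >= 0), expanded by the 48
#' octahedral symmetry operations and projected radially onto the
#' superball.  The resulting grid is exactly symmetric, so downstream
#' free-energy evaluations are shared across each 48-site orbit.  Sites
#' are connected by a symmetrized k-nearest-neighbor move graph.
#'
#' @inheritParams implicitValue
#' @param targetSites requested number of sites (>= 500); the realized
#'   count is a multiple of the orbit sizes and matches to within a few
#'   percent.
#' @param seed integer seed (rotates the underlying Fibonacci lattice).
#' @param k neighbors per site before symmetrization; increased
#'   automatically if the graph comes out disconnected.
#' @return a \linkS4class{SuperballGrid}.
#' @examples
#' g <- buildSuperballGrid(n = 6, targetSites = 2000, seed = 1)
#' g
#' @export
buildSuperballGrid <- function(n = 6, sigmaC = 1, targetSites = 60000,
                               seed = 1, k = 6) {
  if (targetSites < 500)
    stop("targetSites must be at least 500 to triangulate the surface")
  if (sigmaC <= 0) stop("sigmaC must be positive")
  if (n < 2) stop("n must be >= 2")
  N <- as.integer(targetSites)
  i <- seq_len(N) - 1
  z <- 1 - (2 * i + 1) / N
  r <- sqrt(pmax(0, 1 - z^2))
  offset <- 2 * pi * ((seed * 0.6180339887498949) %% 1)
  phi <- i * pi * (3 - sqrt(5)) + offset
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  fund <- dirs[dirs[, 1] >= dirs[, 2] & dirs[, 2] >= dirs[, 3] &
                 dirs[, 3] >= 0, , drop = FALSE]
  m <- nrow(fund)
  images <- .octahedralImages(fund)
  allDirs <- do.call(rbind, images)
  orbit <- rep.int(seq_len(m), 48L)
  # drop duplicate images of boundary points
  key <- apply(round(allDirs, 9), 1, paste, collapse = ",")
  keep <- !duplicated(key)
  allDirs <- allDirs[keep, , drop = FALSE]
  orbit <- orbit[keep]

  pos <- .radialSurface(allDirs, n, sigmaC)
  nrm <- .surfaceNormals(pos, n, sigmaC)
  gam <- gaussianCurvature(pos, n, sigmaC, tol = 1e-8)
  face <- .faceOf(pos)
  orbitRep <- match(seq_len(m), orbit)  # identity image comes first

  repeat {
    nn <- .cppKnn(pos, as.integer(k))
    adj <- lapply(seq_len(nrow(pos)), function(ii) nn[ii, ])
    # symmetrize: union of i->j and j->i
    from <- rep.int(seq_len(nrow(pos)), k)
    to <- as.vector(nn)
    ed <- unique(rbind(cbind(from, to), cbind(to, from)))
    adj <- unname(split(ed[, 2], ed[, 1]))
    adj <- lapply(adj, function(v) sort(unique(as.integer(v))))
    ptr <- c(0L, cumsum(lengths(adj)))
    comp <- .cppComponents(as.integer(unlist(adj)) - 1L, as.integer(ptr))
    if (max(comp) == 1L || k >= 14) break
    k <- k + 2
  }
  if (max(comp) != 1L)
    stop("neighbor graph is disconnected even at k = ", k)

  sites <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
                      gamma = gam, face = face, stringsAsFactors = FALSE)
  id <- sprintf("superball-n%g-s%g-N%d-seed%d-k%d-v1",
                n, sigmaC, N, as.integer(seed), k)
  new("SuperballGrid", n = n, sigmaC = sigmaC, sites = sites,
      adjacency = adj, orbit = as.integer(orbit),
      orbitRep = as.integer(orbitRep), targetSites = as.numeric(N),
      seed = as.numeric(seed), id = id)
}

# CSR form of the adjacency list (0-based) for the compiled kernels.
.csrAdjacency <- function(grid) {
  adj <- grid@adjacency
  list(idx = as.integer(unlist(adj)) - 1L,
       ptr = as.integer(c(0L, cumsum(lengths(adj)))))
}

#' Sphere center above a surface site
#'
#' Places the sphere center at normal distance `h = l + alpha*sigma_c/2`
#' above the surface, the geometry at which the repulsive contributions of
#' inert strands can be neglected.
#'
#' @param grid a \linkS4class{SuperballGrid}.
#' @param site integer site index (vectorized).
#' @param alpha sphere-to-cube size ratio sigma_s/sigma_c (> 0).
#' @param l linker length in units of sigma_c (> 0 allowed to be 0 for the
#'   touching limit).
#' @return an m x 3 matrix of sphere centers.
#' @export
placeSphere <- function(grid, site, alpha, l = 0.025) {
  if (alpha <= 0) stop("alpha must be positive")
  if (l < 0) stop("l must be non-negative")
  h <- l * grid@sigmaC + alpha * grid@sigmaC / 2
  siteCoords(grid)[site, , drop = FALSE] +
    h * siteNormals(grid)[site, , drop = FALSE]
}

# all sphere centers for a given alpha (used by the MC kernel)
.sphereCenters <- function(grid, alpha, l = 0.025) {
  h <- l * grid@sigmaC + alpha * grid@sigmaC / 2
  siteCoords(grid) + h * siteNormals(grid)
}

#' Surface point in a given direction
#'
#' Radial projection of a direction onto the superball surface; used for
#' the canonical face-center (1,0,0), edge-midpoint (1,1,0) and corner
#' (1,1,1) reference points.
#'
#' @param dir length-3 direction (need not be normalized).
#' @inheritParams implicitValue
#' @return length-3 surface point.
#' @export
surfacePoint <- function(dir, n = 6, sigmaC = 1) {
  drop(.radialSurface(matrix(dir / sqrt(sum(dir^2)), ncol = 3), n, sigmaC))
}

#' Outward unit normal of the superball surface
#'
#' @param point length-3 vector or m x 3 matrix of on-surface points.
#' @inheritParams implicitValue
#' @return m x 3 matrix of unit normals.
#' @export
surfaceNormal <- function(point, n = 6, sigmaC = 1) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  .surfaceNormals(p, n, sigmaC)
}

#' Nearest grid site to a point
#'
#' @param grid a \linkS4class{SuperballGrid}.
#' @param point length-3 point (will be compared against site positions).
#' @return integer site index.
#' @export
nearestSite <- function(grid, point) {
  d2 <- colSums((t(siteCoords(grid)) - point)^2)
  which.min(d2)
}

#' Superball surface area
#'
#' Deterministic quadrature over directions of the star-shaped surface,
#' `A = sum t(u)^2 / (n_hat . u) dOmega` on a Fibonacci sphere.  Used to
#' convert the experimental strand densities into effective strand counts.
#'
#' @inheritParams implicitValue
#' @param nQuad number of quadrature directions.
#' @return surface area in sigma_c^2.
#' @export
superballArea <- function(n = 6, sigmaC = 1, nQuad = 20000) {
  i <- seq_len(nQuad) - 1
  z <- 1 - (2 * i + 1) / nQuad
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  u <- cbind(r * cos(phi), r * sin(phi), z)
  p <- .radialSurface(u, n, sigmaC)
  t2 <- rowSums(p^2)
  nh <- .surfaceNormals(p, n, sigmaC)
  cosang <- rowSums(nh * u)
  (4 * pi / nQuad) * sum(t2 / cosang)
}

#' Euclidean distance from exterior points to the superball surface
#'
#' Closed-form radial projection refined by tangential foot-point walking;
#' position tolerance `tol` (default l-scale / 100).
#'
#' @param points m x 3 matrix of exterior points.
#' @inheritParams implicitValue
#' @param tol tangential convergence tolerance.
#' @return numeric vector of distances.
#' @export
distanceToSurface <- function(points, n = 6, sigmaC = 1, tol = 2.5e-4) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  .cppDistanceToSuperball(p, n, sigmaC, tol)
}
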
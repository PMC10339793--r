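# Shared fixtures (built lazily, cached for the session) and independent
# oracles used across the test files.

.fx <- new.env(parent = emptyenv())

fxGrid <- function(which = c("toy", "small", "med", "paper", "sphere")) {
  which <- match.arg(which)
  key <- paste0("grid.", which)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- switch(which,
      toy = buildSuperballGrid(n = 6, targetSites = 500, seed = 1),
      small = buildSuperballGrid(n = 6, targetSites = 2000, seed = 1),
      med = buildSuperballGrid(n = 6, targetSites = 6000, seed = 1),
      paper = buildSuperballGrid(n = 6, targetSites = 60000, seed = 1),
      sphere = buildSuperballGrid(n = 2, targetSites = 2000, seed = 1))
  .fx[[key]]
}

fxThermo <- function(tempC = 24) {
  key <- sprintf("thermo.%g", tempC)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- duplexDG0("GTAGAAGTAGG", "CCTACTTCTAC",
                            temperature = 273.15 + tempC, saltM = 0.2)
  .fx[[key]]
}

.fxSamples <- function(which) if (which == "paper") 4e4 else 2e4

fxCalibration <- function(which = "med") {
  key <- paste0("cal.", which)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- calibrateStrandNumber(
      fxGrid(which), 0.63, fxThermo()@betaDG0,
      mc = list(nSamples = .fxSamples(which), seed = 1))
  .fx[[key]]
}

fxLandscape <- function(alpha, which = "med", tempC = 24) {
  key <- sprintf("land.%s.%g.%g", which, alpha, tempC)
  if (is.null(.fx[[key]])) {
    cal <- fxCalibration(which)
    p <- bondParams(fxThermo(tempC)@betaDG0,
                    nGamma = scaleStrandCount(cal$nGamma, alpha),
                    nDelta = cal$nDelta)
    .fx[[key]] <- computeLandscape(
      fxGrid(which), p, alpha, temperature = 273.15 + tempC,
      mc = list(nSamples = .fxSamples(which), seed = 1))
  }
  .fx[[key]]
}

# ---- independent oracles -------------------------------------------------

# published unified nearest-neighbor table, duplicated here on purpose as
# the oracle for the package's summation
oracleNN <- list(
  AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
  CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
  GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
  GG = c(-8.0, -19.9))

oracleThermoSums <- function(seq) {
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  b <- strsplit(seq, "")[[1]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(b) - 1)) {
    st <- paste0(b[i], b[i + 1])
    if (is.null(oracleNN[[st]]))
      st <- paste0(comp[b[i + 1]], comp[b[i]])
    dH <- dH + oracleNN[[st]][1]; dS <- dS + oracleNN[[st]][2]
  }
  for (e in c(b[1], b[length(b)])) {
    if (e %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  if (seq == paste(rev(comp[b]), collapse = "")) dS <- dS - 1.4
  c(dH = dH, dS = dS)
}

# brute-force partition function over bond matchings: each sphere strand
# is either unbound or bonded to a distinct cube strand with weight q
oracleMatchZ <- function(ng, nd, q) {
  rec <- function(s, used) {
    if (s > ng) return(1)
    tot <- rec(s + 1, used)
    for (cc in seq_len(nd)) if (!used[cc]) {
      used[cc] <- TRUE
      tot <- tot + q * rec(s + 1, used)
      used[cc] <- FALSE
    }
    tot
  }
  rec(1, rep(FALSE, nd))
}

# two spheres sharing the cube strand pool
oraclePairZ <- function(ng, nd, q1, q2) {
  rec <- function(s, used, q, nextQ) {
    if (s > ng) {
      if (is.null(nextQ)) return(1)
      return(rec(1, used, nextQ, NULL))
    }
    tot <- rec(s + 1, used, q, nextQ)
    for (cc in seq_len(nd)) if (!used[cc]) {
      used[cc] <- TRUE
      tot <- tot + q * rec(s + 1, used, q, nextQ)
      used[cc] <- FALSE
    }
    tot
  }
  rec(1, rep(FALSE, nd), q1, q2)
}

# volume of the lens-shaped intersection of two balls
oracleBallLens <- function(R, r, d) {
  if (d >= R + r) return(0)
  if (d <= abs(R - r)) return((4 / 3) * pi * min(R, r)^3)
  pi * (R + r - d)^2 *
    (d^2 + 2 * d * r - 3 * r^2 + 2 * d * R + 6 * r * R - 3 * R^2) / (12 * d)
}

# overlap of two spherical shells around centers at distance d:
# inclusion-exclusion over the four bounding balls
oracleShellOverlap <- function(R1, R2, r1, r2, d) {
  oracleBallLens(R1, R2, d) - oracleBallLens(R1, r2, d) -
    oracleBallLens(r1, R2, d) + oracleBallLens(r1, r2, d)
}

# independent distance-to-superball: staged directional minimization over
# radially projected surface points, vectorized over query points
oracleDistanceBatch <- function(pts, n = 6, sigma = 1) {
  m <- nrow(pts)
  best <- pts / sqrt(rowSums(pts^2))
  bd <- rep(Inf, m)
  span <- 0.7
  for (stage in 1:4) {
    # orthonormal basis per current best direction
    ref <- cbind(ifelse(abs(best[, 1]) < 0.9, 0, 1),
                 ifelse(abs(best[, 1]) < 0.9, 1, 0), 0)
    e1 <- cbind(best[, 2] * ref[, 3] - best[, 3] * ref[, 2],
                best[, 3] * ref[, 1] - best[, 1] * ref[, 3],
                best[, 1] * ref[, 2] - best[, 2] * ref[, 1])
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- cbind(best[, 2] * e1[, 3] - best[, 3] * e1[, 2],
                best[, 3] * e1[, 1] - best[, 1] * e1[, 3],
                best[, 1] * e1[, 2] - best[, 2] * e1[, 1])
    offs <- expand.grid(a = seq(-span, span, length.out = 15),
                        b = seq(-span, span, length.out = 15))
    newBest <- best
    for (k in seq_len(nrow(offs))) {
      d <- best + offs$a[k] * e1 + offs$b[k] * e2
      d <- d / sqrt(rowSums(d^2))
      s <- rowSums(abs(2 * d / sigma)^n)^(-1 / n)
      x <- d * s
      dist <- sqrt(rowSums((pts - x)^2))
      better <- dist < bd
      bd[better] <- dist[better]
      newBest[better, ] <- d[better, , drop = FALSE]
    }
    best <- newBest
    span <- span / 6
  }
  bd
}

# voxel-counting overlap volume: regular grid with spacing <= l/5 in the
# local frame of the site, averaged over randomized sub-voxel grid
# offsets (a thin lens otherwise suffers grid-alignment artifacts); the
# error estimate is the spread over the offset replicates
oracleVoxelOverlap <- function(grid, site, alpha, l = 0.025, sp = l / 5,
                               nOffsets = 6, seed = 99) {
  pos <- siteCoords(grid)[site, ]
  nh <- siteNormals(grid)[site, ]
  r <- alpha * grid@sigmaC / 2
  C <- pos + (r + l) * nh
  ref <- if (abs(nh[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nh) * nh; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nh[2] * e1[3] - nh[3] * e1[2], nh[3] * e1[1] - nh[1] * e1[3],
          nh[1] * e1[2] - nh[2] * e1[1])
  w <- 1.7 * sqrt(4 * (r + l) * l)
  lat <- seq(-w, w, by = sp)
  hgt <- seq(-0.5 * w, l + 2 * sp, by = sp)
  base <- expand.grid(a = lat, b = lat, h = hgt)
  set.seed(seed)
  vols <- vapply(seq_len(nOffsets), function(k) {
    off <- runif(3, 0, sp)
    a <- base$a + off[1]; b <- base$b + off[2]; h <- base$h + off[3]
    pts <- cbind(pos[1] + a * e1[1] + b * e2[1] + h * nh[1],
                 pos[2] + a * e1[2] + b * e2[2] + h * nh[2],
                 pos[3] + a * e1[3] + b * e2[3] + h * nh[3])
    rho <- sqrt(rowSums((pts - matrix(C, nrow(pts), 3, byrow = TRUE))^2))
    inSph <- rho >= r & rho <= r + l
    pts <- pts[inSph, , drop = FALSE]
    # exterior test plus exact distance bounds (radial chord is an upper
    # bound; tangent-plane offset is a lower bound for a convex body)
    S <- rowSums(abs(2 * pts / grid@sigmaC)^grid@n)
    fv <- S - 1
    q <- pts * S^(-1 / grid@n)
    ub <- sqrt(rowSums((pts - q)^2))
    aq <- abs(2 * q / grid@sigmaC)
    gq <- (2 * grid@n / grid@sigmaC) * aq^(grid@n - 1) * sign(q)
    nq <- gq / sqrt(rowSums(gq^2))
    lb <- rowSums((pts - q) * nq)
    dist <- rep(NA_real_, length(ub))
    dist[ub <= l] <- ub[ub <= l]
    dist[lb > l] <- Inf
    band <- is.na(dist)
    if (any(band))
      dist[band] <- oracleDistanceBatch(pts[band, , drop = FALSE],
                                        grid@n, grid@sigmaC)
    inside <- fv > 0 & dist <= l
    # the box must fully contain the overlap region
    onEdge <- abs(a[inSph]) > w - sp | abs(b[inSph]) > w - sp |
      h[inSph] < -0.5 * w + sp
    stopifnot(!any(inside & onEdge))
    sum(inside) * sp^3
  }, numeric(1))
  list(volume = mean(vols),
       stderr = stats::sd(vols) / sqrt(nOffsets))
}

# brute-force double-loop position autocorrelation over all time origins
oracleCr <- function(coords, lags) {
  nr <- dim(coords)[1]; ns <- dim(coords)[2]
  vapply(lags, function(lg) {
    num <- 0; cnt <- 0
    for (s in seq_len(ns)) for (t0 in seq_len(nr - lg)) {
      r0 <- coords[t0, s, ]; rt <- coords[t0 + lg, s, ]
      num <- num + sum(r0 * rt) / sum(r0^2)
      cnt <- cnt + 1
    }
    num / cnt
  }, numeric(1))
}
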
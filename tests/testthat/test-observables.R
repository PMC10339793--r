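test_that("autocorrelation is exactly 1 for a frozen trajectory", {
  tr <- makeFixture("toy-trajectory")
  tr@coords[] <- rep(tr@coords[1, 1, ], each = 100)
  cr <- positionAutocorrelation(tr)
  expect_equal(cr$c_r, rep(1, nrow(cr)), tolerance = 1e-12)
  expect_equal(cr$c_r[cr$lag == 0], 1)
})

test_that("the two-point alternating fixture matches its closed form", {
  tr <- makeFixture("toy-trajectory")
  p1 <- tr@coords[1, 1, ]; p2 <- tr@coords[2, 1, ]
  cr <- positionAutocorrelation(tr, lags = c(0, 1, 2, 3))
  mixed <- sum(p1 * p2)
  expect_equal(cr$c_r[1], 1)
  expect_equal(cr$c_r[3], 1, tolerance = 1e-12)
  # odd lags mix the two points, averaged over both origin parities
  expOdd <- function(n1, n2) (n1 * mixed / sum(p1^2) +
                                n2 * mixed / sum(p2^2)) / (n1 + n2)
  expect_equal(cr$c_r[2], expOdd(50, 49), tolerance = 1e-12)
  expect_equal(cr$c_r[4], expOdd(49, 48), tolerance = 1e-12)
})

test_that("independent uniform positions decorrelate to zero", {
  set.seed(31)
  nr <- 4000
  co <- array(rnorm(nr * 3), dim = c(nr, 1, 3))
  co <- co / sqrt(rowSums(co[, 1, ]^2))   # uniform directions
  tr <- new("SurfaceTrajectory", steps = seq(0, by = 50, length.out = nr),
            sites = matrix(NA_integer_, nr, 1), coords = co,
            faces = matrix("+x", nr, 1), alpha = 1, gridId = "toy",
            quasi2d = FALSE, seed = 1, acceptanceRate = NA_real_)
  cr <- positionAutocorrelation(tr, lags = c(0, 3, 17, 101))
  expect_equal(cr$c_r[1], 1)
  expect_lt(max(abs(cr$c_r[-1])), 3 * sqrt(3) / sqrt(nr - 101))
})

test_that("the streaming autocorrelation equals a brute-force double loop", {
  set.seed(17)
  nr <- 100
  co <- array(rnorm(nr * 2 * 3), dim = c(nr, 2, 3))
  tr <- new("SurfaceTrajectory", steps = seq(0, by = 10, length.out = nr),
            sites = matrix(NA_integer_, nr, 2), coords = co,
            faces = matrix("+x", nr, 2), alpha = 1, gridId = "toy",
            quasi2d = FALSE, seed = 1, acceptanceRate = NA_real_)
  lags <- c(0, 1, 5, 13, 60)
  cr <- positionAutocorrelation(tr, lags = lags)
  expect_equal(cr$c_r, oracleCr(co, lags), tolerance = 1e-12)
  expect_error(positionAutocorrelation(
    new("SurfaceTrajectory", steps = 0,
        sites = matrix(NA_integer_, 1, 1),
        coords = array(0, dim = c(1, 1, 3)),
        faces = matrix("+x", 1, 1), alpha = 1, gridId = "toy",
        quasi2d = FALSE, seed = 1, acceptanceRate = NA_real_)),
    "at least 2")
})

test_that("mean displacement has the documented closed forms", {
  mk <- function(pts, face = "+x") {
    nr <- nrow(pts)
    co <- array(NA_real_, dim = c(nr, 1, 3))
    co[, 1, ] <- pts
    new("SurfaceTrajectory", steps = seq(0, by = 50, length.out = nr),
        sites = matrix(NA_integer_, nr, 1), coords = co,
        faces = matrix(face, nr, 1), alpha = 1, gridId = "toy",
        quasi2d = FALSE, seed = 1, acceptanceRate = NA_real_)
  }
  # a single repeated point
  expect_equal(meanDisplacement(mk(matrix(rep(c(0.5, 0.1, 0), 20),
                                          ncol = 3, byrow = TRUE))), 0)
  # two points +-d/2 on a line in the face plane
  d <- 0.12
  pts <- matrix(rep(c(0.5, -d / 2, 0, 0.5, d / 2, 0), 10),
                ncol = 3, byrow = TRUE)
  expect_equal(meanDisplacement(mk(pts)), d / 2, tolerance = 1e-12)
})

test_that("mean displacement is invariant under rotation about the normal", {
  set.seed(23)
  nr <- 60
  y <- rnorm(nr, 0, 0.05); z <- rnorm(nr, 0, 0.02)
  pts <- cbind(0.5, y, z)
  th <- 0.7
  rot <- cbind(0.5, cos(th) * y - sin(th) * z, sin(th) * y + cos(th) * z)
  mk <- function(pts) {
    co <- array(NA_real_, dim = c(nr, 1, 3)); co[, 1, ] <- pts
    new("SurfaceTrajectory", steps = seq(0, by = 50, length.out = nr),
        sites = matrix(NA_integer_, nr, 1), coords = co,
        faces = matrix("+x", nr, 1), alpha = 1, gridId = "toy",
        quasi2d = FALSE, seed = 1, acceptanceRate = NA_real_)
  }
  expect_equal(meanDisplacement(mk(pts)), meanDisplacement(mk(rot)),
               tolerance = 1e-12)
})

test_that("facet occupancy fractions are well normalized", {
  tr <- makeFixture("toy-trajectory")
  occ <- facetOccupancy(tr)
  expect_equal(unname(colSums(occ)), 1)
  expect_equal(unname(occ["+x", 1]), 1)
  tr@faces[seq(1, 99, by = 2), 1] <- "-y"
  occ2 <- facetOccupancy(tr)
  expect_equal(unname(occ2["-y", 1]), 0.5)
  expect_equal(unname(occ2["+x", 1]), 0.5)
})

test_that("decay onset finds the first crossing of the threshold", {
  cr <- data.frame(lag = c(0, 100, 200, 400), c_r = c(1, 0.95, 0.85, 0.5))
  expect_equal(decayOnset(cr), 200)
  expect_equal(decayOnset(cr, threshold = 0.6), 400)
  expect_true(is.na(decayOnset(cr, threshold = 0.1)))
})
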
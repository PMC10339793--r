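test_that("initialization places spheres uniformly and without overlap", {
  g <- fxGrid("toy")
  L <- makeFixture("toy-landscape")
  L@betaFbond <- rep(-1, nSites(g)); L@betaDF <- rep(0, nSites(g))
  # empty state
  st0 <- initState(g, L, 0, alpha = 0.63, quasi2d = FALSE, seed = 1)
  expect_length(st0@siteIndices, 0)
  # single-sphere occupancy uniform across faces (chi-square over seeds)
  faces <- vapply(1:600, function(s)
    faceLabels(g)[initState(g, L, 1, quasi2d = FALSE,
                            seed = s)@siteIndices], character(1))
  counts <- table(faces)
  expected <- 600 * table(faceLabels(g)) / nSites(g)
  chi2 <- sum((counts - expected[names(counts)])^2 /
                expected[names(counts)])
  expect_lt(chi2, qchisq(0.999, df = 5))
  # determinism
  expect_identical(initState(g, L, 3, quasi2d = FALSE, seed = 7)@siteIndices,
                   initState(g, L, 3, quasi2d = FALSE, seed = 7)@siteIndices)
  # hard-sphere constraint respected at a large size ratio
  st <- initState(g, L, 2, alpha = 0.63, quasi2d = FALSE, seed = 3,
                  distinctFaces = FALSE)
  ctr <- placeSphere(g, st@siteIndices, 0.63)
  expect_gte(sqrt(sum((ctr[1, ] - ctr[2, ])^2)), 0.63)
})

test_that("two large spheres under quasi-2D start on opposite lateral faces", {
  g <- fxGrid("med")
  cal <- fxCalibration()
  L <- fxLandscape(4.44)
  for (s in 1:25) {
    st <- initState(g, L, 2, quasi2d = "auto", seed = s)
    f <- faceLabels(g)[st@siteIndices]
    expect_false(any(f %in% c("+z", "-z")))
    expect_setequal(unique(substr(f, 2, 2)), substr(f[1], 2, 2))
    expect_setequal(substr(f, 1, 1), c("+", "-"))
  }
  # overcrowding errors out
  expect_error(initState(g, L, 5, quasi2d = "auto", seed = 1,
                         distinctFaces = FALSE), "non-overlapping")
})

test_that("a flat landscape samples all sites uniformly", {
  g <- fxGrid("toy")
  L <- makeFixture("toy-landscape")
  L@betaFbond <- rep(0, nSites(g)); L@betaDF <- rep(0, nSites(g))
  st <- initState(g, L, 1, quasi2d = FALSE, seed = 2)
  tr <- runSurfaceMC(st, L, g, nSweeps = 4e5, recordEvery = 200,
                     equilibration = 5e3, seed = 2)
  occ <- facetOccupancy(tr)[, 1]
  expected <- table(faceLabels(g))[names(occ)] / nSites(g)
  expect_lt(max(abs(occ - expected)), 0.05)
})

test_that("a two-level system reproduces the Boltzmann ratio", {
  adjIdx <- c(1L, 0L); adjPtr <- c(0L, 1L, 2L)
  energy <- c(0, 1.5)
  centers <- rbind(c(0, 0, 0), c(1, 0, 0))
  res <- FlexColloid:::.cppRunSurfaceMC(
    adjIdx, adjPtr, energy, centers, c(FALSE, FALSE), 0L,
    0, 2e5, 5L, 1000L, 11)
  pB <- mean(res$sites[, 1] == 2L)
  expect_equal(pB, exp(-1.5) / (1 + exp(-1.5)), tolerance = 0.1)
})

test_that("the neighbor-count correction keeps a flat graph uniform", {
  # node 1 has two neighbors, nodes 2 and 3 have one; without the k_i/k_j
  # factor node 1 would be oversampled
  adjIdx <- c(1L, 2L, 0L, 0L); adjPtr <- c(0L, 2L, 3L, 4L)
  energy <- c(0, 0, 0)
  centers <- diag(3)
  res <- FlexColloid:::.cppRunSurfaceMC(
    adjIdx, adjPtr, energy, centers, rep(FALSE, 3), 0L,
    0, 3e5, 5L, 1000L, 5)
  occ <- tabulate(res$sites[, 1], 3) / nrow(res$sites)
  expect_equal(unname(occ), rep(1 / 3, 3), tolerance = 0.08)
})

test_that("the Metropolis chain satisfies detailed balance numerically", {
  set.seed(21)
  # ring of 10 with random chords -> irregular degrees
  adj <- lapply(1:10, function(i) sort(unique(c(
    ifelse(i == 1, 10, i - 1), ifelse(i == 10, 1, i + 1)))))
  for (k in 1:5) {
    ij <- sample(10, 2)
    adj[[ij[1]]] <- sort(unique(c(adj[[ij[1]]], ij[2])))
    adj[[ij[2]]] <- sort(unique(c(adj[[ij[2]]], ij[1])))
  }
  energy <- rnorm(10)
  P <- transitionMatrix(adj, energy)
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-12)
  pi0 <- exp(-energy) / sum(exp(-energy))
  flux <- pi0 * P
  expect_lt(max(abs(flux - t(flux))), 1e-14)
})

test_that("an infinite barrier ring confines the sphere to its face", {
  g <- fxGrid("toy")
  L <- makeFixture("toy-landscape")
  betaF <- ifelse(faceLabels(g) == "+x", -1, Inf)
  L@betaFbond <- betaF
  L@betaDF <- betaF - min(betaF)
  st <- initState(g, L, 1, quasi2d = FALSE, seed = 4)
  expect_identical(faceLabels(g)[st@siteIndices], "+x")
  tr <- runSurfaceMC(st, L, g, nSweeps = 5e4, recordEvery = 50,
                     equilibration = 0, seed = 4)
  expect_identical(sum(countFaceCrossings(tr)), 0L)
  expect_true(all(tr@faces == "+x"))
})

test_that("trajectories are well-formed and grid-consistent", {
  g <- fxGrid("toy")
  L <- makeFixture("toy-landscape")
  st <- initState(g, L, 2, quasi2d = FALSE, seed = 5)
  tr <- runSurfaceMC(st, L, g, nSweeps = 1e4, recordEvery = 50,
                     equilibration = 100, seed = 5)
  expect_true(all(diff(trajectorySteps(tr)) == 50))
  expect_equal(length(trajectorySteps(tr)), 1e4 / 50 + 1)
  co <- contactPoints(tr)
  pts <- rbind(co[, 1, ], co[, 2, ])
  expect_lt(max(abs(implicitValue(pts, g@n, g@sigmaC))), 1e-9)
  # mismatched grid identity is refused
  g2 <- fxGrid("small")
  expect_error(runSurfaceMC(st, L, g2, 100, 10), "identities")
  expect_error(initState(g2, L, 1), "different grid")
})

test_that("face-crossing counts follow the label changes", {
  tr <- makeFixture("toy-trajectory")
  expect_identical(countFaceCrossings(tr), 0L)
  tr@faces <- matrix(rep(c("+x", "+y"), length.out = 5), 5, 1)
  tr@steps <- tr@steps[1:5]
  tr@coords <- tr@coords[1:5, , , drop = FALSE]
  tr@sites <- tr@sites[1:5, , drop = FALSE]
  expect_identical(countFaceCrossings(tr), 4L)
})
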
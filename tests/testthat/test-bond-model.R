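test_that("configurational cost follows -ln(Ogd/(rho0*Og*Od))", {
  sp <- list(omegaGamma = 2, omegaDelta = 3, omegaGammaDelta = 6)
  expect_equal(configCost(sp, rho0 = 1), 0)               # identity case
  sp$omegaGammaDelta <- 3
  expect_equal(configCost(sp, rho0 = 1), log(2))          # halving costs ln 2
  sp$omegaGammaDelta <- 0
  expect_identical(configCost(sp, rho0 = 1), Inf)         # unbindable
  expect_error(configCost(list(omegaGamma = 0, omegaDelta = 1,
                               omegaGammaDelta = 1), 1), "positive")
})

test_that("bond strength adds hybridization and configurational terms", {
  expect_equal(bondStrength(-10, 3), -7)
  expect_identical(bondStrength(-10, Inf), Inf)
})

test_that("multivalent free energy matches closed forms and enumeration", {
  # single pair: -ln(1 + q)
  for (bdg in c(-3, 0, 2.5))
    expect_equal(multivalentFreeEnergy(1, 1, bdg),
                 -log(1 + exp(-bdg)), tolerance = 1e-12)
  # 2x2: -ln(1 + 4q + 2q^2)
  q <- exp(1.3)
  expect_equal(multivalentFreeEnergy(2, 2, -1.3),
               -log(1 + 4 * q + 2 * q^2), tolerance = 1e-12)
  # no binding
  expect_equal(multivalentFreeEnergy(3, 5, Inf), 0)
  expect_equal(multivalentFreeEnergy(0, 5, -1), 0)
  # brute-force matching enumeration for all counts up to 4
  for (ng in 1:4) for (nd in 1:4) for (q in c(0.2, 1, 4)) {
    expect_equal(multivalentFreeEnergy(ng, nd, -log(q)),
                 -log(oracleMatchZ(ng, nd, q)), tolerance = 1e-10)
  }
  expect_error(multivalentFreeEnergy(-1, 2, 0), "non-negative")
  # always attractive or neutral
  expect_true(all(multivalentFreeEnergy(30, 200, seq(-5, 10)) <= 0))
})

test_that("two spheres sharing the cube pool match brute-force enumeration", {
  for (ng in 1:3) for (nd in 2:4) {
    expect_equal(pairBondFreeEnergy(ng, nd, -log(0.7), -log(1.4)),
                 -log(oraclePairZ(ng, nd, 0.7, 1.4)), tolerance = 1e-10)
  }
  # with a huge shared pool the spheres decouple
  f1 <- multivalentFreeEnergy(3, 5000, 0.5)
  f2 <- multivalentFreeEnergy(3, 5000, -0.2)
  expect_equal(pairBondFreeEnergy(3, 5000, 0.5, -0.2), f1 + f2,
               tolerance = 1e-3)
})

test_that("the landscape is minimal at face centers and maximal at corners", {
  g <- fxGrid("med")
  L <- fxLandscape(0.63)
  expect_equal(min(betaDeltaF(L)), 0, tolerance = 1e-9)
  expect_true(all(betaFbond(L) <= 1e-9))
  spacing <- 2 * sqrt(superballArea(g@n) / nSites(g))
  # minimum within a grid spacing of a face center
  amin <- which.min(betaFbond(L))
  pos <- siteCoords(g)[amin, ]
  dir <- numeric(3)
  dir[which.max(abs(pos))] <- sign(pos[which.max(abs(pos))])
  expect_lt(sqrt(sum((pos - surfacePoint(dir))^2)), 2 * spacing)
  # maximum barrier at a corner (the curvature maximum)
  amax <- which.max(betaDeltaF(L))
  cpos <- siteCoords(g)[amax, ]
  expect_lt(sqrt(sum((cpos - surfacePoint(sign(cpos) * c(1, 1, 1)))^2)),
            2 * spacing)
})

test_that("the landscape carries exact 48-fold octahedral symmetry", {
  g <- fxGrid("med")
  L <- fxLandscape(0.63)
  spread <- tapply(betaFbond(L), g@orbit, function(v) diff(range(v)))
  expect_equal(max(spread), 0)
})

test_that("barriers are insensitive to n_delta above saturation", {
  g <- fxGrid("med")
  L <- fxLandscape(0.63)
  em <- nearestSite(g, surfacePoint(c(1, 1, 0)))
  cnf <- L@betaDGcnf
  bond <- bondStrength(L@params$betaDG0, cnf[c(em, which.min(betaFbond(L)))])
  ng <- L@params$nGamma
  b1 <- diff(multivalentFreeEnergy(ng, 20000, bond))
  b2 <- diff(multivalentFreeEnergy(ng, 40000, bond))
  expect_lt(abs(b2 - b1) / abs(b1), 0.01)
})

test_that("strand calibration sits exactly at the mobility threshold", {
  g <- fxGrid("med")
  cal <- fxCalibration()
  expect_gte(cal$rate, 1e-6)
  expect_lt(cal$rateNext, 1e-6)
  # deterministic: repeated call gives the same answer
  cal2 <- calibrateStrandNumber(g, 0.63, fxThermo()@betaDG0,
                                mc = list(nSamples = 2e4, seed = 1))
  expect_identical(cal$nGamma, cal2$nGamma)
  # unsatisfiable criterion errors out
  expect_error(calibrateStrandNumber(g, 0.63, fxThermo()@betaDG0,
                                     maxRate = 1, nMax = 4),
               "unsatisfiable")
})

test_that("the edge barrier grows monotonically with the strand number", {
  g <- fxGrid("med")
  L <- fxLandscape(0.63)
  em <- nearestSite(g, surfacePoint(c(1, 1, 0)))
  fc <- which.min(betaFbond(L))
  bond <- bondStrength(L@params$betaDG0, L@betaDGcnf[c(fc, em)])
  barrier <- vapply(1:50, function(ng) {
    f <- multivalentFreeEnergy(ng, 2000, bond)
    f[2] - f[1]
  }, numeric(1))
  expect_true(all(diff(barrier) > -1e-9))
})

test_that("barriers rise with size ratio and fall with temperature", {
  g <- fxGrid("med")
  cal <- fxCalibration()
  pts <- rbind(surfacePoint(c(1, 0, 0)), surfacePoint(c(1, 1, 0)))
  # edge-midpoint barrier monotone in alpha (evaluated at exact points)
  barriers <- vapply(c(0.63, 1.20, 1.98, 4.44), function(a) {
    p <- bondParams(fxThermo()@betaDG0,
                    nGamma = scaleStrandCount(cal$nGamma, a),
                    nDelta = cal$nDelta)
    fe <- pointFreeEnergy(g, pts, a, p, mc = list(nSamples = 4e4, seed = 2))
    fe$betaFbond[2] - fe$betaFbond[1]
  }, numeric(1))
  expect_true(all(diff(barriers) > 0))
  # ... and monotone decreasing in temperature at alpha = 0.93
  p93 <- bondParams(fxThermo()@betaDG0,
                    nGamma = scaleStrandCount(cal$nGamma, 0.93),
                    nDelta = cal$nDelta)
  sweep <- temperatureSweep(g, p93, 0.93, c(24, 36, 40),
                            mc = list(nSamples = 2e4, seed = 1))
  em <- nearestSite(g, surfacePoint(c(1, 1, 0)))
  edges <- vapply(sweep, function(L) betaDeltaF(L)[em], numeric(1))
  expect_true(all(diff(edges) < 0))
})

test_that("temperature sweeps share geometry and respect the pair limit", {
  g <- fxGrid("small")
  p <- bondParams(fxThermo()@betaDG0, nGamma = 5, nDelta = 50)
  sw <- temperatureSweep(g, p, 0.93, c(24, 24, 40),
                         mc = list(nSamples = 1e4, seed = 1))
  expect_equal(betaFbond(sw[[1]]), betaFbond(sw[[2]]))
  expect_identical(sw[[1]]@betaDGcnf, sw[[3]]@betaDGcnf)
  # single-pair closed form under a temperature change
  p1 <- bondParams(fxThermo()@betaDG0, nGamma = 1, nDelta = 1)
  sw1 <- temperatureSweep(g, p1, 0.93, c(24, 40),
                          mc = list(nSamples = 1e4, seed = 1))
  cnf <- sw1[[1]]@betaDGcnf
  for (k in 1:2) {
    bdg0 <- fxThermo(c(24, 40)[k])@betaDG0
    expect_equal(betaFbond(sw1[[k]]), -log(1 + exp(-(bdg0 + cnf))),
                 tolerance = 1e-10)
  }
})

test_that("landscape magnitudes span few k_BT (small alpha) to large (big alpha)", {
  L63 <- fxLandscape(0.63)
  L444 <- fxLandscape(4.44)
  expect_lt(max(betaDeltaF(L63)), 30)
  expect_gt(max(betaDeltaF(L444)), 100)
})
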
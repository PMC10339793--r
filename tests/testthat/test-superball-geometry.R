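test_that("implicit superball function has the right signs and landmarks", {
  expect_equal(implicitValue(c(0.5, 0, 0), n = 6, sigmaC = 1), 0)
  expect_equal(implicitValue(c(0, 0, 0), n = 6), -1)
  expect_equal(implicitValue(c(0, 0, 0), n = 2), -1)
  # sharp-cube limit: the (sigma/2, sigma/2, sigma/2) corner tends to f = 2
  expect_equal(implicitValue(c(0.5, 0.5, 0.5), n = 400), 2)
  expect_gt(implicitValue(c(0.6, 0, 0), n = 6), 0)
  expect_error(implicitValue(c(1, 0, 0), n = 6, sigmaC = -1), "positive")
})

test_that("grid construction hits the target size and stays on-surface", {
  g <- fxGrid("paper")
  expect_lt(abs(nSites(g) - 60000) / 60000, 0.05)
  gs <- fxGrid("small")
  expect_lt(max(abs(implicitValue(siteCoords(gs), gs@n, gs@sigmaC))), 1e-9)
  expect_equal(rowSums(siteNormals(gs)^2), rep(1, nSites(gs)),
               tolerance = 1e-12)
  expect_error(buildSuperballGrid(targetSites = 100), "at least 500")
})

test_that("the neighbor graph is symmetric, connected, with degree >= 3", {
  g <- fxGrid("small")
  adj <- adjacency(g)
  expect_true(all(lengths(adj) >= 3))
  # symmetry
  for (i in sample(nSites(g), 50))
    for (j in adj[[i]]) expect_true(i %in% adj[[j]])
  # connectivity by plain BFS
  seen <- logical(nSites(g)); seen[1] <- TRUE; front <- 1L
  while (length(front)) {
    nxt <- unique(unlist(adj[front]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    front <- nxt
  }
  expect_true(all(seen))
})

test_that("face labels partition the sites evenly by dominant axis", {
  g <- fxGrid("med")
  counts <- table(faceLabels(g))
  expect_setequal(names(counts), c("+x", "-x", "+y", "-y", "+z", "-z"))
  expect_lt(diff(range(counts)) / mean(counts), 0.03)
  pos <- siteCoords(g)
  ax <- max.col(abs(pos))
  lab <- paste0(ifelse(pos[cbind(seq_len(nrow(pos)), ax)] >= 0, "+", "-"),
                c("x", "y", "z")[ax])
  expect_identical(faceLabels(g), lab)
})

test_that("Gaussian curvature matches limits and a finite-difference oracle", {
  # sphere: K = 4/sigma^2 everywhere
  gs <- fxGrid("sphere")
  expect_equal(siteCurvature(gs), rep(4, nSites(gs)), tolerance = 1e-9)
  expect_equal(gaussianCurvature(c(0.5, 0, 0), n = 2, sigmaC = 1), 4,
               tolerance = 1e-12)
  # flat face center for n > 2
  expect_equal(gaussianCurvature(c(0.5, 0, 0), n = 6), 0)
  g <- fxGrid("med")
  fcSite <- nearestSite(g, surfacePoint(c(1, 0, 0)))
  expect_lt(siteCurvature(g)[fcSite], 1e-4)
  # grid argmax sits at a corner
  amax <- which.max(siteCurvature(g))
  corner <- surfacePoint(sign(siteCoords(g)[amax, ]) * c(1, 1, 1))
  spacing <- 2 * sqrt(superballArea(g@n) / nSites(g))
  expect_lt(sqrt(sum((siteCoords(g)[amax, ] - corner)^2)), 2 * spacing)
  # finite-difference oracle K = (g . adj(H) g)/|g|^4 on random sites
  set.seed(11)
  idx <- sample(nSites(g), 100)
  h <- 1e-5
  f <- function(p) sum(abs(2 * p)^6) - 1
  for (i in idx) {
    p <- siteCoords(g)[i, ]
    gr <- numeric(3); He <- matrix(0, 3, 3)
    for (a in 1:3) {
      ea <- replace(numeric(3), a, h)
      gr[a] <- (f(p + ea) - f(p - ea)) / (2 * h)
      for (b in 1:3) {
        eb <- replace(numeric(3), b, h)
        He[a, b] <- (f(p + ea + eb) - f(p + ea - eb) - f(p - ea + eb) +
                       f(p - ea - eb)) / (4 * h^2)
      }
    }
    Kfd <- (gr[1]^2 * (He[2, 2] * He[3, 3] - He[2, 3] * He[3, 2]) +
              gr[2]^2 * (He[1, 1] * He[3, 3] - He[1, 3] * He[3, 1]) +
              gr[3]^2 * (He[1, 1] * He[2, 2] - He[1, 2] * He[2, 1])) /
      sum(gr^2)^2
    expect_equal(siteCurvature(g)[i], Kfd, tolerance = 0.01)
  }
  expect_error(gaussianCurvature(c(0.6, 0, 0), n = 6), "off the")
})

test_that("octahedral symmetry images of every site exist on the grid", {
  g <- fxGrid("small")
  pos <- siteCoords(g)
  spacing <- 2 * sqrt(superballArea(g@n) / nSites(g))
  set.seed(3)
  perms <- rbind(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  for (i in sample(nSites(g), 10)) {
    for (k in seq_len(nrow(perms))) {
      img <- pos[i, perms[k, ]] * c(1, -1, 1)
      dmin <- sqrt(min(colSums((t(pos) - img)^2)))
      expect_lt(dmin, spacing)
    }
  }
})

test_that("sphere placement sits at h = l + alpha/2 along the normal", {
  g <- fxGrid("med")
  fc <- nearestSite(g, surfacePoint(c(1, 0, 0)))
  ctr <- placeSphere(g, fc, alpha = 0.63, l = 0.025)
  expect_equal(drop(ctr),
               siteCoords(g)[fc, ] + 0.34 * siteNormals(g)[fc, ],
               tolerance = 1e-12)
  # the paper arithmetic at the exact face center: 0.5 + 0.025 + 0.315
  expect_equal(sqrt(sum(placeSphere(g, fc, 0.63)^2)), 0.84,
               tolerance = 2e-3)
  # touching limit
  ctr0 <- placeSphere(g, fc, alpha = 0.63, l = 0)
  expect_equal(sqrt(sum((ctr0 - siteCoords(g)[fc, ])^2)), 0.315,
               tolerance = 1e-12)
  # mirror sites give mirror centers
  pos <- siteCoords(g)
  i <- which.max(pos[, 1])
  jm <- nearestSite(g, pos[i, ] * c(1, 1, -1))
  ci <- placeSphere(g, i, 1.2)
  cj <- placeSphere(g, jm, 1.2)
  expect_equal(drop(ci) * c(1, 1, -1), drop(cj), tolerance = 1e-9)
  expect_error(placeSphere(g, fc, alpha = -1), "positive")
})

test_that("distance to the superball surface is exact on normal rays", {
  expect_equal(distanceToSurface(c(0.6, 0, 0)), 0.1, tolerance = 1e-6)
  expect_equal(distanceToSurface(c(0, 0.75, 0)), 0.25, tolerance = 1e-6)
  # generic exterior points against the independent oracle
  set.seed(5)
  pts <- matrix(rnorm(30), ncol = 3)
  pts <- 0.8 * pts / sqrt(rowSums(pts^2))
  expect_equal(distanceToSurface(pts), oracleDistanceBatch(pts),
               tolerance = 1e-4)
})
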
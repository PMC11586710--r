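test_that("single-atom density has the super-Gaussian profile", {
  ctr <- c(1, -2, 0.5)
  expect_equal(gaussDensity(ctr, ctr, 2, 1, 2), 1)
  # at distance sigma*R the bracket is 1 for any exponent
  for (m in c(1, 2, 3, 8))
    expect_equal(gaussDensity(ctr + c(2 * 0.9, 0, 0), ctr, 2, 0.9, m),
                 exp(-1))
  expect_equal(gaussDensity(c(1, 0, 0), c(0, 0, 0), 2, 1, 2),
               exp(-0.0625))
  # strictly decreasing in distance
  r <- seq(0, 6, by = 0.1)
  g <- gaussDensity(cbind(r, 0, 0), c(0, 0, 0), 2, 1, 2)
  expect_true(all(diff(g) < 0))
})

test_that("total density is the probabilistic union of atom densities", {
  s1 <- makeBornIon(1, 2)
  pt <- c(1.3, 0.4, -0.2)
  expect_equal(totalDensity(s1, pt, 1, 2),
               gaussDensity(pt, c(0, 0, 0), 2, 1, 2))
  # two atoms with g_j = 0.5 each: g = 1 - 0.25
  s <- newSolute(c(-0.5, 0.5), c(0, 0), c(0, 0), c(0.5, -0.5), c(1, 1))
  d <- sqrt(log(2))  # g_j(d) = 0.5 for sigma = 1, m = 1, R = 1
  pt0 <- c(0, sqrt(d^2 - 0.25), 0)
  expect_equal(totalDensity(s, pt0, 1, 1, cutoff = FALSE), 0.75,
               tolerance = 1e-12)
  # union bound: never below the largest single-atom density
  set.seed(11)
  pts <- matrix(runif(60, -3, 3), ncol = 3)
  s2 <- makeTwoAtomSystem()
  gTot <- totalDensity(s2, pts, 1, 2)
  g1 <- gaussDensity(pts, c(-1.5, 0, 0), 1.5, 1, 2)
  g2 <- gaussDensity(pts, c(1.7, 0, 0), 1.7, 1, 2)
  expect_true(all(gTot >= pmax(g1, g2) - 1e-12))
  expect_true(all(gTot >= 0 & gTot <= 1))
})

test_that("surface function is the g-sigmoid with explicit limits", {
  for (eta in c(0.5, 1, 2, 4))
    expect_equal(surfaceFunction(0.5, eta), 0.5)
  expect_identical(surfaceFunction(1, 2), 1)
  expect_identical(surfaceFunction(0, 2), 0)
  expect_equal(surfaceFunction(0.25, 2), 0.1)
  # monotone increasing in g for random eta
  set.seed(5)
  for (eta in runif(5, 0.3, 6)) {
    g <- sort(runif(100))
    expect_true(all(diff(surfaceFunction(g, eta)) >= 0))
  }
})

test_that("dielectric components respect their bounds and limits", {
  s <- makeTwoAtomSystem()
  p <- pbParams()
  # at an atom center: eps_g = eps_ref, eps = eps_ref
  ctr <- c(-1.5, 0, 0)
  expect_equal(epsDensity(s, ctr, p), 1)
  expect_equal(dielectricValue(s, ctr, p, 80), 1)
  # far away: eps_g -> eps_gap, eps -> phase eps_out
  far <- c(60, 0, 0)
  expect_equal(epsDensity(s, far, p), 22)
  expect_equal(dielectricValue(s, far, p, 80), 80)
  expect_equal(dielectricValue(s, far, p, 1), 1)
  # interpolation: product 0.5 -> eps_g = 11.5 (single atom)
  s1 <- makeBornIon(1, 2)
  dHalf <- 2 * log(2)^(1 / 4)  # g_1 = 0.5 at this radius (m = 2)
  expect_equal(epsDensity(s1, c(dHalf, 0, 0), p), 1 + 21 * 0.5,
               tolerance = 1e-9)
  # convex-combination bound over random points
  set.seed(6)
  pts <- matrix(runif(300, -6, 6), ncol = 3)
  ev <- dielectricValue(s, pts, p, 80)
  expect_true(all(ev >= 1 - 1e-12 & ev <= 80 + 1e-12))
})

test_that("vacuum-phase dielectric shows the interior hump", {
  # with eps_gap = 22 > eps_out = 1, the vacuum dielectric rises above
  # 1 in the loosely packed interface region and returns to 1 both at
  # the center and far away
  s <- makeBornIon(1, 2)
  p <- pbParams()
  r <- seq(0, 10, by = 0.05)
  ev <- dielectricValue(s, cbind(r, 0, 0), p, 1)
  expect_equal(ev[1], 1)
  expect_equal(ev[length(ev)], 1, tolerance = 1e-9)
  expect_gt(max(ev), 1.5)
})

test_that("large m drives the Born-ion dielectric toward a step", {
  s <- makeBornIon(1, 2)
  r <- c(seq(0.1, 1.45, by = 0.05), seq(2.55, 6, by = 0.05))
  stepProfile <- ifelse(r < 2, 1, 80)
  dev <- sapply(c(2, 4, 8), function(m) {
    p <- pbParams(m = m, epsGap = 1, eta = 2)
    max(abs(dielectricValue(s, cbind(r, 0, 0), p, 80) - stepProfile))
  })
  expect_true(all(diff(dev) < 0))
})

test_that("analytic gradients match the finite-difference oracle", {
  set.seed(9)
  fixtures <- list(makeBornIon(1, 2), makeTwoAtomSystem(),
                   makeSyntheticPeptide(6, seed = 2))
  p <- pbParams()
  for (s in fixtures) {
    pts <- sampleShellPoints(s, 40)
    for (i in seq_len(nrow(pts))) {
      pt <- pts[i, ]
      # per-atom density gradient
      ctr <- atomCoords(s)[1, ]; R <- atomRadii(s)[1]
      an <- gradGaussDensity(pt, ctr, R, 1, 2)
      nu <- numGrad(function(x) gaussDensity(x, ctr, R, 1, 2), pt)
      if (sqrt(sum(nu^2)) > 1e-4)
        expect_lt(relVecErr(an, nu), 1e-6)
      # eps_g gradient
      an <- gradEpsDensity(s, pt, p, cutoff = FALSE)
      nu <- numGrad(function(x) epsDensity(s, x, p, cutoff = FALSE), pt)
      if (sqrt(sum(nu^2)) > 1e-2)
        expect_lt(relVecErr(an, nu), 1e-6)
      # surface gradient
      an <- gradSurface(s, pt, p, cutoff = FALSE)
      nu <- numGrad(function(x)
        surfaceFunction(totalDensity(s, x, p@sigma, p@m,
                                     cutoff = FALSE), p@eta), pt)
      if (sqrt(sum(nu^2)) > 1e-4)
        expect_lt(relVecErr(an, nu), 1e-6)
      # full dielectric gradient, both phases
      for (eo in c(80, 1)) {
        an <- gradDielectric(s, pt, p, eo, cutoff = FALSE)
        nu <- numGrad(function(x)
          dielectricValue(s, x, p, eo, cutoff = FALSE), pt)
        if (sqrt(sum(nu^2)) > 1e-2)
          expect_lt(relVecErr(an, nu), 1e-6)
      }
    }
  }
})

test_that("gradient limits: zero at atom centers and in the far field", {
  s <- makeTwoAtomSystem()
  p <- pbParams()
  expect_equal(gradGaussDensity(c(-1.5, 0, 0), c(-1.5, 0, 0), 1.5, 1, 2),
               matrix(0, 1, 3))
  expect_equal(gradDielectric(s, c(55, 3, -2), p, 80),
               matrix(0, 1, 3))
  expect_equal(gradSurface(s, c(55, 3, -2), p), matrix(0, 1, 3))
  # single-atom radial symmetry: gradient antiparallel to (r - r_j)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3))
  for (i in 1:3) {
    pt <- dirs[i, ] * 1.9
    gr <- gradGaussDensity(pt, c(0, 0, 0), 2, 1, 2)
    expect_lt(sum(gr * dirs[i, ]), 0)
  }
  # Born-ion water phase: dielectric rises outward through the interface
  s1 <- makeBornIon(1, 2)
  for (r in seq(0.8, 4, by = 0.4)) {
    gr <- gradDielectric(s1, c(r, 0, 0), p, 80)
    expect_gte(gr[1], 0)
  }
})

test_that("grid fields agree with point-wise evaluation", {
  s <- makeTwoAtomSystem()
  p <- pbParams()
  g <- buildGrid(s, scale = 1.5, paddingA = 6)
  fl <- dielectricFields(s, g, p, 80)
  d <- gridDims(g)
  set.seed(3)
  picks <- cbind(sample(d[1], 60, TRUE), sample(d[2], 60, TRUE),
                 sample(d[3], 60, TRUE))
  pts <- indexToWorld(g, picks - 1)
  expect_equal(fieldValues(fl$g)[picks],
               totalDensity(s, pts, p@sigma, p@m), tolerance = 1e-12)
  expect_equal(fieldValues(fl$eps)[picks],
               dielectricValue(s, pts, p, 80), tolerance = 1e-12)
  gv <- fieldValues(fl$gradEps)
  an <- gradDielectric(s, pts, p, 80)
  for (cc in 1:3)
    expect_equal(gv[cbind(picks, cc)], an[, cc], tolerance = 1e-10)
  # midpoint dielectric is the analytic value at the midpoint coordinate
  mid <- indexToWorld(g, picks - 1 + matrix(rep(c(0.5, 0, 0), each = 60),
                                            ncol = 3))
  expect_equal(fl$epsMidX[picks], dielectricValue(s, mid, p, 80),
               tolerance = 1e-12)
})

test_that("Born-ion surface field is spherically symmetric on axes", {
  s <- makeBornIon(1, 2)
  p <- pbParams()
  h <- 0.5
  g <- new("Grid3D", origin = c(-8, -8, -8), h = h,
           dims = c(33L, 33L, 33L))   # origin node lands on the ion
  fl <- dielectricFields(s, g, p, 80)
  S <- fieldValues(fl$S)
  ctr <- c(17, 17, 17)
  for (k in 1:4) {
    six <- c(S[ctr[1] + k, 17, 17], S[ctr[1] - k, 17, 17],
             S[17, ctr[2] + k, 17], S[17, ctr[2] - k, 17],
             S[17, 17, ctr[3] + k], S[17, 17, ctr[3] - k])
    expect_lt(max(six) - min(six), 1e-12)
  }
})
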
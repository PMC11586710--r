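test_that("physical constants reproduce the standard electrostatic units", {
  pc <- physicalConstants(300)
  expect_equal(pc$coulombKcal, 332.06, tolerance = 1e-4)
  expect_equal(pc$kTKcalMol, 0.59616, tolerance = 1e-4)
  # Coulomb prefactor is their ratio
  expect_equal(pc$coulombPrefactor, pc$coulombKcal / pc$kTKcalMol,
               tolerance = 1e-12)
})

test_that("Debye-Huckel parameter is linear in salt and zero without it", {
  expect_identical(debyeKappa2(0), 0)
  k1 <- debyeKappa2(0.1, 300)
  expect_equal(debyeKappa2(0.2, 300), 2 * k1, tolerance = 1e-12)
  # physiological salt in water: Debye length ~8 Angstrom
  lam <- sqrt(80 / debyeKappa2(0.145, 300))
  expect_gt(lam, 7); expect_lt(lam, 9)
  # frozen regression value for the constant expression
  expect_equal(debyeKappa2(0.145, 300), 1.222409, tolerance = 1e-5)
})

test_that("Green's potential follows Coulomb's law", {
  pc <- physicalConstants(300)
  s <- makeBornIon(1, 2)
  v1 <- greensPotential(s, c(1, 0, 0), pc, epsRef = 1)
  v2 <- greensPotential(s, c(2, 0, 0), pc, epsRef = 1)
  expect_equal(v1 / v2, 2, tolerance = 1e-12)
  # unit charge, unit distance, unit dielectric: the prefactor itself
  expect_equal(v1, pc$coulombPrefactor, tolerance = 1e-12)
  # net-zero pair at an equidistant point
  pair <- makeTwoAtomSystem()
  mid <- c(0.1, 0, 0)  # equidistant from (-1.5,0,0) and (1.7,0,0)
  expect_equal(greensPotential(pair, mid, pc), 0, tolerance = 1e-12)
  expect_error(greensPotential(s, c(0, 0, 0), pc), "center")
})

test_that("Green's gradient matches the numeric oracle", {
  pc <- physicalConstants(300)
  s <- makeTwoAtomSystem()
  set.seed(12)
  for (i in 1:10) {
    pt <- runif(3, -4, 4) + c(4, 0, 0) * sample(c(0, 1), 1)
    if (min(sqrt(colSums((t(atomCoords(s)) - pt)^2))) < 0.5) next
    an <- greensGradient(s, pt, pc)
    nu <- numGrad(function(x) greensPotential(s, x, pc), pt)
    expect_lt(relVecErr(an, nu), 1e-7)
  }
  # single positive charge: gradient points toward the charge
  b <- makeBornIon(1, 2)
  gr <- greensGradient(b, c(2, 0, 0), pc)
  expect_lt(gr[1], 0)
  # midpoint of +/- pair: gradient along the dipole (x) axis
  pm <- newSolute(c(-1, 1), c(0, 0), c(0, 0), c(0.5, -0.5), c(1, 1))
  gr <- greensGradient(pm, c(0, 2, 0), pc)
  expect_gt(abs(gr[1]), 1e-6)
  expect_equal(gr[2], 0, tolerance = 1e-12)
  expect_equal(gr[3], 0, tolerance = 1e-12)
})

test_that("charge summary splits signs and weights centers", {
  pm <- newSolute(c(1, -1), c(0, 0), c(0, 0), c(0.5, -0.5), c(1, 1))
  cs <- chargeSummary(pm)
  expect_equal(cs$qTotPlus, 0.5)
  expect_equal(cs$qTotMinus, -0.5)
  expect_equal(cs$centerPlus, c(1, 0, 0))
  expect_equal(cs$centerMinus, c(-1, 0, 0))
  expect_equal(cs$dipoleLength, 2)
  # weighted mean of two like charges
  two <- newSolute(c(0, 2), c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  cs2 <- chargeSummary(two)
  expect_equal(cs2$centerPlus, c(1, 0, 0))
  expect_false(cs2$dipolarAvailable)
  expect_true(is.na(cs2$dipoleLength))
})

test_that("boundary potentials: screening, symmetry, far-field agreement", {
  pc <- physicalConstants(300)
  pair <- makeTwoAtomSystem()
  # no salt: coulombic BC reduces to the unscreened sum
  pt <- c(20, 5, -3)
  bc0 <- boundaryPotential(pair, pt, "water", "coulombic", pc,
                           epsOut = 80, kappa2 = 0)
  man <- sum(atomCharges(pair) * pc$coulombPrefactor /
             (80 * sqrt(colSums((t(atomCoords(pair)) - pt)^2))))
  expect_equal(bc0, man, tolerance = 1e-12)
  # net-neutral pair, dipolar BC vanishes on the bisector plane
  cs <- chargeSummary(pair)
  xmid <- (cs$centerPlus[1] + cs$centerMinus[1]) / 2
  bcD <- boundaryPotential(pair, c(xmid, 25, 0), "water", "dipolar",
                           pc, epsOut = 80, kappa2 = 0)
  expect_equal(bcD, 0, tolerance = 1e-12)
  # dipolar ~ coulombic in the far field (5% at 30 A)
  far <- rbind(c(30, 4, 2), c(-28, -8, 5), c(3, 31, -4))
  bC <- boundaryPotential(pair, far, "water", "coulombic", pc, 80, 0)
  bD <- boundaryPotential(pair, far, "water", "dipolar", pc, 80, 0)
  expect_true(all(abs(bD - bC) <= 0.05 * abs(bC)))
  # dipolar BC unavailable for single-sign solutes
  expect_error(
    boundaryPotential(makeBornIon(1, 2), pt, "water", "dipolar", pc,
                      80, 0), "dipolar")
  # vacuum phase: unscreened, eps_out = 1 regardless of arguments
  bV <- boundaryPotential(pair, pt, "vacuum", "coulombic", pc,
                          epsOut = 80, kappa2 = 5)
  expect_equal(bV, man * 80, tolerance = 1e-12)
})

test_that("coulombic and dipolar BCs converge with distance", {
  pc <- physicalConstants(300)
  # a net-charged irregular solute: slower far-field decay of the
  # multipole error, still must converge
  s <- makeSyntheticPeptide(8, netCharge = 2, seed = 5)
  dists <- c(15, 30, 60)
  rel <- sapply(dists, function(d) {
    pt <- colMeans(atomCoords(s)) + c(d, 0, 0)
    bC <- boundaryPotential(s, pt, "water", "coulombic", pc, 80, 0)
    bD <- boundaryPotential(s, pt, "water", "dipolar", pc, 80, 0)
    abs(bD - bC) / abs(bC)
  })
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[3], 0.02)
})

test_that("regularized source fields are finite and symmetric", {
  p <- pbParams()
  pc <- physicalConstants(p@temperature, p@saltMolar)
  s <- makeBornIon(1, 2)
  h <- 0.5
  g <- new("Grid3D", origin = c(-8, -8, -8), h = h,
           dims = c(33L, 33L, 33L))   # node exactly on the ion center
  flW <- dielectricFields(s, g, p, 80)
  srcW <- rpbSourceWater(s, g, flW, pc, kappa2 = 0)
  expect_true(all(is.finite(fieldValues(srcW))))
  # spherical symmetry across the 6 axis neighbors at equal distance
  v <- fieldValues(srcW)
  for (k in c(2, 4, 6)) {
    six <- c(v[17 + k, 17, 17], v[17 - k, 17, 17], v[17, 17 + k, 17],
             v[17, 17 - k, 17], v[17, 17, 17 + k], v[17, 17, 17 - k])
    expect_lt(max(six) - min(six), 1e-9 * max(abs(six), 1e-30))
  }
  # node at the atom center carries the analytic limit 0
  expect_identical(v[17, 17, 17], 0)
  # far corner: essentially zero
  expect_lt(abs(v[1, 1, 1]), 1e-6)
  # vacuum source with homogeneous dielectric is identically zero
  pFlat <- pbParams(epsGap = 1)
  flV <- dielectricFields(s, g, pFlat, 1)
  srcV <- rpbSourceVacuum(s, g, flV, pc)
  expect_true(all(fieldValues(srcV) == 0))
  # default params: vacuum source nonzero in the interface region
  flV2 <- dielectricFields(s, g, p, 1)
  srcV2 <- rpbSourceVacuum(s, g, flV2, pc)
  expect_gt(max(abs(fieldValues(srcV2))), 0.1)
  expect_true(all(is.finite(fieldValues(srcV2))))
})

test_that("salt term enters the water source as -(1-S) kappa^2 G", {
  p <- pbParams(saltMolar = 0.145)
  pc <- physicalConstants(300, 0.145)
  s <- makeBornIon(1, 2)
  g <- new("Grid3D", origin = c(-8, -8, -8), h = 1,
           dims = c(17L, 17L, 17L))
  fl <- dielectricFields(s, g, p, 80)
  s0 <- rpbSourceWater(s, g, fl, pc, kappa2 = 0)
  s1 <- rpbSourceWater(s, g, fl, pc, kappa2 = pc$kappa2)
  gg <- suGaussRPB:::.gridGreens(s, g, pc, withGrad = FALSE)
  expected <- -(1 - fieldValues(fl$S)) * pc$kappa2 * gg$G
  diff <- fieldValues(s1) - fieldValues(s0)
  # away from the center node the difference is exactly the salt term
  mask <- !gg$near
  expect_equal(diff[mask], expected[mask], tolerance = 1e-12)
})
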
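# Shared oracles and samplers for the test suite.

# Central finite-difference gradient of a scalar function of a
# 3-vector: the master oracle for every analytic gradient. Truncation
# error O(h^2); round-off floor ~ |f| * 1e-11 / h, so comparisons are
# only meaningful where the true gradient clears that floor.
numGrad <- function(f, pt, h = 1e-5) {
  vapply(1:3, function(d) {
    e <- numeric(3); e[d] <- h
    (f(pt + e) - f(pt - e)) / (2 * h)
  }, numeric(1))
}

relVecErr <- function(a, b) {
  sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
}

# Random points in the shell around a solute's atoms where the
# density/dielectric interface lives (fractions of sigma*R_j from a
# randomly chosen atom): the region where gradients are appreciable
# and the FD oracle is valid.
sampleShellPoints <- function(solute, n, sigma = 1,
                              rangeFrac = c(0.25, 1.8)) {
  pos <- atomCoords(solute); rad <- atomRadii(solute)
  j <- sample.int(nrow(pos), n, replace = TRUE)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- stats::runif(n, rangeFrac[1], rangeFrac[2]) * sigma * rad[j]
  pos[j, , drop = FALSE] + u * r
}

# Small heterogeneous test system on a given grid: smooth dielectric
# from the Born fixture plus arbitrary rhs/boundary/screening fields,
# deterministic under set.seed by the caller.
randomHeteroSystem <- function(dims = c(16L, 14L, 15L), h = 0.5) {
  solute <- makeBornIon(1, 2)
  grid <- new("Grid3D", origin = -h * (dims - 1) / 2, h = h,
              dims = as.integer(dims))
  p <- pbParams()
  f <- dielectricFields(solute, grid, p, 80)
  n <- prod(dims)
  discretizeSystem(f$epsMidX, f$epsMidY, f$epsMidZ,
                   array(stats::runif(n, 0, 0.5), dim = dims),
                   array(stats::rnorm(n), dim = dims),
                   array(stats::rnorm(n), dim = dims), grid)
}
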
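# Super-Gaussian atom density, density-dependent surface function,
# smooth dielectric, and their analytic gradients. Point-wise
# evaluators (arbitrary coordinates) serve the finite-difference
# oracles; the lattice evaluator serves the solver.

.G_FLOOR <- 1e-14   # density clamp below/above which S snaps to 0/1

.asPoints <- function(point) {
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3L)
    point
  } else {
    stopifnot(length(point) == 3L)
    matrix(point, ncol = 3L)
  }
}

#' Density cutoff radius for one atom
#'
#' Distance at which the super-Gaussian exponent argument reaches 36,
#' i.e. g_j < 1e-15; beyond it g_j is treated as exactly zero when the
#' cutoff is enabled. Truncation error is far below solver tolerance.
#'
#' @param radius atom radius, Angstrom.
#' @param sigma,m super-Gaussian parameters.
#' @return cutoff distance, Angstrom.
#' @export
densityCutoff <- function(radius, sigma, m) {
  sigma * radius * 36^(1 / (2 * m))
}

#' Super-Gaussian density of a single atom
#'
#' g_j(r) = exp(-[ |r - r_j|^2 / (sigma^2 R_j^2) ]^m): one at the atom
#' center, exp(-1) at distance sigma*R_j, strictly decreasing outward.
#' m = 1 is the plain Gaussian; larger m flattens the top (hard sphere
#' as m -> Inf).
#'
#' @param point 3-vector or n x 3 matrix, Angstrom.
#' @param center atom center, 3-vector.
#' @param radius atom radius R_j, Angstrom.
#' @param sigma,m super-Gaussian parameters.
#' @return density values in [0, 1].
#' @examples
#' gaussDensity(c(0, 0, 0), c(0, 0, 0), 2, 1, 2)       # 1
#' gaussDensity(c(2, 0, 0), c(0, 0, 0), 2, 1, 2)       # exp(-1)
#' @export
gaussDensity <- function(point, center, radius, sigma, m) {
  p <- .asPoints(point)
  d2 <- (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 +
        (p[, 3] - center[3])^2
  exp(-(d2 / (sigma^2 * radius^2))^m)
}

#' Gradient of the single-atom density
#'
#' Analytic form: grad g_j = -(2m / (sigma^2 R^2)^m) g_j
#' (|r-r_j|^2)^(m-1) (r - r_j); zero at the atom center, antiparallel
#' to the outward direction elsewhere.
#'
#' @inheritParams gaussDensity
#' @return n x 3 matrix of gradient vectors, 1/Angstrom.
#' @export
gradGaussDensity <- function(point, center, radius, sigma, m) {
  p <- .asPoints(point)
  dx <- p[, 1] - center[1]; dy <- p[, 2] - center[2]
  dz <- p[, 3] - center[3]
  d2 <- dx * dx + dy * dy + dz * dz
  s2 <- sigma^2 * radius^2
  g <- exp(-(d2 / s2)^m)
  pref <- (2 * m / s2^m) * g * d2^(m - 1)
  cbind(-pref * dx, -pref * dy, -pref * dz)
}

# Per-atom density matrix at arbitrary points: n_points x n_atoms.
# cutoff=TRUE zeroes densities beyond densityCutoff().
.densityMatrix <- function(solute, pts, sigma, m, cutoff = TRUE) {
  pos <- atomCoords(solute); rad <- atomRadii(solute)
  n <- nrow(pts); nm <- nrow(pos)
  G <- matrix(0, n, nm)
  for (j in seq_len(nm)) {
    dx <- pts[, 1] - pos[j, 1]; dy <- pts[, 2] - pos[j, 2]
    dz <- pts[, 3] - pos[j, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    if (cutoff) {
      rc2 <- densityCutoff(rad[j], sigma, m)^2
      inr <- d2 <= rc2
      gj <- numeric(n)
      if (any(inr))
        gj[inr] <- exp(-(d2[inr] / (sigma^2 * rad[j]^2))^m)
      G[, j] <- gj
    } else {
      G[, j] <- exp(-(d2 / (sigma^2 * rad[j]^2))^m)
    }
  }
  G
}

#' Total super-Gaussian density of a solute
#'
#' g(r) = 1 - prod_j (1 - g_j(r)): the probabilistic union of the
#' per-atom densities. Equals 1 wherever any g_j = 1 and never falls
#' below the largest single-atom density.
#'
#' @param solute a [Solute-class]
#' @param point 3-vector or n x 3 matrix, Angstrom.
#' @param sigma,m super-Gaussian parameters.
#' @param cutoff apply the per-atom distance cutoff (disable for
#'   oracle comparisons).
#' @return density values in [0, 1].
#' @export
totalDensity <- function(solute, point, sigma, m, cutoff = TRUE) {
  pts <- .asPoints(point)
  G <- .densityMatrix(solute, pts, sigma, m, cutoff)
  1 - apply(1 - G, 1, prod)
}

#' Density-dependent surface function
#'
#' S(g) = 1 / (1 + (1/g - 1)^eta): a sigmoid in the density, exactly
#' 0.5 at g = 0.5 for any eta, 1 inside the solute and 0 in bulk
#' solvent. The limits g -> 0 and g -> 1 are handled explicitly: g is
#' clamped at 1e-14 from both ends and S snaps to 0/1 there (the
#' raw formula is singular at g = 0).
#'
#' @param g density values in [0, 1].
#' @param eta steepness exponent (> 0).
#' @return S values in [0, 1].
#' @examples
#' surfaceFunction(0.5, 2)    # 0.5
#' surfaceFunction(0.25, 2)   # 0.1
#' @export
surfaceFunction <- function(g, eta) {
  s <- numeric(length(g))
  lo <- g <= .G_FLOOR
  hi <- g >= 1 - .G_FLOOR
  mid <- !lo & !hi
  s[hi] <- 1
  s[mid] <- 1 / (1 + (1 / g[mid] - 1)^eta)
  s
}

# dS/dg = eta (1/g - 1)^(eta-1) S^2 / g^2; zero on the clamped plateaus.
.dSurfacedG <- function(g, eta) {
  d <- numeric(length(g))
  mid <- g > .G_FLOOR & g < 1 - .G_FLOOR
  gm <- g[mid]
  t <- 1 / gm - 1
  S <- 1 / (1 + t^eta)
  d[mid] <- eta * t^(eta - 1) * S * S / (gm * gm)
  d
}

#' Density-dependent component of the dielectric
#'
#' eps_g(r) = eps_ref + (eps_gap - eps_ref) prod_j (1 - g_j(r)):
#' eps_ref at atom centers (dense packing), rising to eps_gap where
#' the solute density vanishes. Always within
#' [min(eps_ref, eps_gap), max(eps_ref, eps_gap)].
#'
#' @param solute a [Solute-class]
#' @param point 3-vector or n x 3 matrix.
#' @param params a [PBParams-class]
#' @param cutoff apply the per-atom distance cutoff.
#' @return dielectric values.
#' @export
epsDensity <- function(solute, point, params, cutoff = TRUE) {
  pts <- .asPoints(point)
  G <- .densityMatrix(solute, pts, params@sigma, params@m, cutoff)
  P <- apply(1 - G, 1, prod)
  params@epsRef + (params@epsGap - params@epsRef) * P
}

#' Smooth spatial dielectric
#'
#' eps(r) = S(r) eps_g(r) + (1 - S(r)) eps_out: the surface function
#' blends the packing-dependent solute dielectric into the phase
#' dielectric (80 in water, 1 in vacuum). A convex combination, hence
#' bounded by the extreme of its three inputs.
#'
#' @inheritParams epsDensity
#' @param phaseEpsOut dielectric of the surrounding phase (80 water,
#'   1 vacuum).
#' @return dielectric values.
#' @export
dielectricValue <- function(solute, point, params, phaseEpsOut,
                            cutoff = TRUE) {
  pts <- .asPoints(point)
  G <- .densityMatrix(solute, pts, params@sigma, params@m, cutoff)
  P <- apply(1 - G, 1, prod)
  g <- 1 - P
  S <- surfaceFunction(g, params@eta)
  eg <- params@epsRef + (params@epsGap - params@epsRef) * P
  S * eg + (1 - S) * phaseEpsOut
}

# Shared point-wise machinery: total density g, product P, and the
# accumulator A = sum_j prod_{k!=j}(1-g_k) * pref_j * (r - r_j) with
# pref_j = (2m/(sigma^2 R^2)^m) g_j (d^2)^(m-1) >= 0, from which
#   grad g      = -A
#   grad eps_g  = (eps_gap - eps_ref) * A
# Near an atom center 1 - g_j underflows; those contributions are
# set to zero (the term itself vanishes like r^(2m-1) there).
.densityGradParts <- function(solute, pts, sigma, m, cutoff = TRUE) {
  pos <- atomCoords(solute); rad <- atomRadii(solute)
  n <- nrow(pts); nm <- nrow(pos)
  G <- .densityMatrix(solute, pts, sigma, m, cutoff)
  P <- apply(1 - G, 1, prod)
  A <- matrix(0, n, 3)
  for (j in seq_len(nm)) {
    gj <- G[, j]
    act <- gj > 0
    if (!any(act)) next
    one_m <- 1 - gj[act]
    ratio <- ifelse(one_m < 1e-12, 0, P[act] / one_m)
    dx <- pts[act, 1] - pos[j, 1]; dy <- pts[act, 2] - pos[j, 2]
    dz <- pts[act, 3] - pos[j, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    s2 <- sigma^2 * rad[j]^2
    pref <- (2 * m / s2^m) * gj[act] * d2^(m - 1) * ratio
    A[act, 1] <- A[act, 1] + pref * dx
    A[act, 2] <- A[act, 2] + pref * dy
    A[act, 3] <- A[act, 3] + pref * dz
  }
  list(g = 1 - P, P = P, A = A)
}

#' Gradient of the density-dependent dielectric component
#'
#' Analytic product-rule form
#' grad eps_g = -(eps_gap - eps_ref) sum_j grad g_j prod_{k!=j}(1-g_k),
#' with the overall sign fixed so that eps_g increases away from the
#' solute (validated against a numeric-differentiation oracle).
#'
#' @inheritParams epsDensity
#' @return n x 3 gradient matrix.
#' @export
gradEpsDensity <- function(solute, point, params, cutoff = TRUE) {
  pts <- .asPoints(point)
  parts <- .densityGradParts(solute, pts, params@sigma, params@m, cutoff)
  (params@epsGap - params@epsRef) * parts$A
}

#' Gradient of the surface function
#'
#' grad S = dS/dg * grad g by the chain rule, with grad g assembled
#' from the analytic per-atom gradients. Exactly zero on the clamped
#' density plateaus (deep solute interior and bulk solvent).
#'
#' @inheritParams epsDensity
#' @return n x 3 gradient matrix.
#' @export
gradSurface <- function(solute, point, params, cutoff = TRUE) {
  pts <- .asPoints(point)
  parts <- .densityGradParts(solute, pts, params@sigma, params@m, cutoff)
  dS <- .dSurfacedG(pmin(pmax(parts$g, 0), 1), params@eta)
  -dS * parts$A
}

#' Gradient of the smooth dielectric
#'
#' grad eps = S grad eps_g + grad S (eps_g - eps_out): zero far from
#' the solute and at atom centers, largest through the solute-solvent
#' interface.
#'
#' @inheritParams dielectricValue
#' @return n x 3 gradient matrix.
#' @export
gradDielectric <- function(solute, point, params, phaseEpsOut,
                           cutoff = TRUE) {
  pts <- .asPoints(point)
  parts <- .densityGradParts(solute, pts, params@sigma, params@m, cutoff)
  g <- pmin(pmax(parts$g, 0), 1)
  S <- surfaceFunction(g, params@eta)
  dS <- .dSurfacedG(g, params@eta)
  eg <- params@epsRef + (params@epsGap - params@epsRef) * parts$P
  dEg <- (params@epsGap - params@epsRef)
  # grad eps_g = dEg * A ; grad S = -dS * A
  coef <- S * dEg - dS * (eg - phaseEpsOut)
  coef * parts$A
}

# Lattice evaluation of P = prod(1 - g_j) (pass 1) and the gradient
# accumulator A (pass 2), using per-atom cutoff sub-boxes. origin/h/
# dims define the lattice (need not be a solute-fitted grid, so the
# same code serves node and midpoint lattices).
.latticeDensity <- function(solute, origin, h, dims, sigma, m,
                            withGrad = FALSE) {
  pos <- atomCoords(solute); rad <- atomRadii(solute)
  xs <- origin[1] + h * (seq_len(dims[1]) - 1)
  ys <- origin[2] + h * (seq_len(dims[2]) - 1)
  zs <- origin[3] + h * (seq_len(dims[3]) - 1)
  P <- array(1, dim = dims)
  boxes <- vector("list", nrow(pos))
  for (j in seq_len(nrow(pos))) {
    rc <- densityCutoff(rad[j], sigma, m)
    ix <- which(abs(xs - pos[j, 1]) <= rc)
    iy <- which(abs(ys - pos[j, 2]) <= rc)
    iz <- which(abs(zs - pos[j, 3]) <= rc)
    boxes[[j]] <- list(ix = ix, iy = iy, iz = iz)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((xs[ix] - pos[j, 1])^2, (ys[iy] - pos[j, 2])^2,
                      "+"), (zs[iz] - pos[j, 3])^2, "+")
    gj <- exp(-(d2 / (sigma^2 * rad[j]^2))^m)
    P[ix, iy, iz] <- P[ix, iy, iz] * (1 - gj)
  }
  out <- list(P = P, g = 1 - P)
  if (withGrad) {
    Ax <- array(0, dim = dims); Ay <- array(0, dim = dims)
    Az <- array(0, dim = dims)
    for (j in seq_len(nrow(pos))) {
      b <- boxes[[j]]
      if (!length(b$ix) || !length(b$iy) || !length(b$iz)) next
      dxv <- xs[b$ix] - pos[j, 1]; dyv <- ys[b$iy] - pos[j, 2]
      dzv <- zs[b$iz] - pos[j, 3]
      d2 <- outer(outer(dxv^2, dyv^2, "+"), dzv^2, "+")
      s2 <- sigma^2 * rad[j]^2
      gj <- exp(-(d2 / s2)^m)
      one_m <- 1 - gj
      ratio <- P[b$ix, b$iy, b$iz] / one_m
      ratio[one_m < 1e-12] <- 0
      pref <- (2 * m / s2^m) * gj * d2^(m - 1) * ratio
      nx <- length(dxv); ny <- length(dyv); nz <- length(dzv)
      Ax[b$ix, b$iy, b$iz] <- Ax[b$ix, b$iy, b$iz] +
        pref * array(dxv, dim = c(nx, ny, nz))
      Ay[b$ix, b$iy, b$iz] <- Ay[b$ix, b$iy, b$iz] +
        pref * array(rep(dyv, each = nx), dim = c(nx, ny, nz))
      Az[b$ix, b$iy, b$iz] <- Az[b$ix, b$iy, b$iz] +
        pref * array(rep(dzv, each = nx * ny), dim = c(nx, ny, nz))
    }
    out$Ax <- Ax; out$Ay <- Ay; out$Az <- Az
  }
  out
}

# eps on an arbitrary lattice (used for midpoint dielectric): the
# model is analytic, so midpoint values are evaluated at the midpoint
# coordinates, never averaged from nodes.
.latticeEps <- function(solute, origin, h, dims, params, phaseEpsOut) {
  ld <- .latticeDensity(solute, origin, h, dims, params@sigma,
                        params@m)
  S <- array(surfaceFunction(as.numeric(ld$g), params@eta), dim = dims)
  eg <- params@epsRef + (params@epsGap - params@epsRef) * ld$P
  S * eg + (1 - S) * phaseEpsOut
}

#' Dielectric model fields on a grid
#'
#' Evaluates the total density g, surface function S, smooth
#' dielectric eps and its analytic gradient at every node, plus eps at
#' the six stencil midpoints (analytically, at the midpoint
#' coordinates). All fields come from the closed-form model -- nothing
#' is obtained by differencing.
#'
#' @param solute a [Solute-class]
#' @param grid a [Grid3D-class]
#' @param params a [PBParams-class]
#' @param phaseEpsOut phase dielectric (80 water, 1 vacuum).
#' @return named list: \code{g}, \code{S}, \code{eps}
#'   ([ScalarField-class]), \code{gradEps} ([VectorField-class]), and
#'   \code{epsMidX}, \code{epsMidY}, \code{epsMidZ} (arrays of eps at
#'   the +x/+y/+z midpoints; the last slab along the shifted axis is
#'   padding).
#' @export
dielectricFields <- function(solute, grid, params, phaseEpsOut) {
  stopifnot(is(solute, "Solute"), is(grid, "Grid3D"))
  d <- grid@dims; h <- grid@h; o <- grid@origin
  ld <- .latticeDensity(solute, o, h, d, params@sigma, params@m,
                        withGrad = TRUE)
  g <- ld$g
  S <- array(surfaceFunction(as.numeric(g), params@eta), dim = d)
  eg <- params@epsRef + (params@epsGap - params@epsRef) * ld$P
  eps <- S * eg + (1 - S) * phaseEpsOut
  dS <- array(.dSurfacedG(pmin(pmax(as.numeric(g), 0), 1),
                          params@eta), dim = d)
  coef <- S * (params@epsGap - params@epsRef) -
    dS * (eg - phaseEpsOut)
  gradEps <- array(0, dim = c(d, 3L))
  gradEps[, , , 1] <- coef * ld$Ax
  gradEps[, , , 2] <- coef * ld$Ay
  gradEps[, , , 3] <- coef * ld$Az
  list(
    g = new("ScalarField", grid = grid, values = g),
    S = new("ScalarField", grid = grid, values = S),
    eps = new("ScalarField", grid = grid, values = eps),
    gradEps = new("VectorField", grid = grid, values = gradEps),
    epsMidX = .latticeEps(solute, o + c(h / 2, 0, 0), h, d, params,
                          phaseEpsOut),
    epsMidY = .latticeEps(solute, o + c(0, h / 2, 0), h, d, params,
                          phaseEpsOut),
    epsMidZ = .latticeEps(solute, o + c(0, 0, h / 2), h, d, params,
                          phaseEpsOut))
}
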
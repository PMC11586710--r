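# 7-point finite-difference discretization, SOR iteration, sparse
# direct-solve oracle, and drivers for the regularized and direct
# (Gaussian) PB solves.

#' Discretize the variable-coefficient PB operator
#'
#' Assembles the 7-point flux-form stencil of
#' \eqn{-\nabla\cdot(\epsilon\nabla\phi) + (1-S)\kappa^2\phi = f}:
#' for each interior node,
#' \eqn{\sum_{nb} \epsilon_{mid}(\phi_c - \phi_{nb})/h^2 +
#' \mathrm{screen}\,\phi_c = f}, boundary nodes pinned to Dirichlet
#' values. With constant eps and zero screening this is the standard
#' 7-point Laplacian; the assembled matrix is symmetric for any eps
#' field.
#'
#' @param epsMidX,epsMidY,epsMidZ arrays of dielectric at the
#'   +x/+y/+z midpoints (node dims; last slab along the shifted axis
#'   unused).
#' @param screening array of (1-S) kappa^2 per node, 1/Angstrom^2.
#' @param rhs source array per node.
#' @param boundary array of Dirichlet values (only boundary faces
#'   read).
#' @param grid a [Grid3D-class]
#' @return a [LinearSystemSpec-class]
#' @export
discretizeSystem <- function(epsMidX, epsMidY, epsMidZ, screening,
                             rhs, boundary, grid) {
  asArr <- function(x) if (is(x, "ScalarField")) x@values else x
  sys <- new("LinearSystemSpec", grid = grid, epsX = asArr(epsMidX),
             epsY = asArr(epsMidY), epsZ = asArr(epsMidZ),
             screening = asArr(screening), rhs = asArr(rhs),
             boundary = asArr(boundary))
  validObject(sys)
  sys
}

#' Solve a discretized system by successive over-relaxation
#'
#' Lexicographic Gauss-Seidel sweeps with over-relaxation factor
#' omega. Convergence is declared when the diagonally scaled residual
#' (the Gauss-Seidel displacement, kT/e) drops below \code{tol} in
#' max-norm; if the residual grows over 50 consecutive sweeps the
#' solve stops with \code{converged = FALSE} (no exception). Sweeps
#' are deterministic: repeated calls are bitwise identical.
#'
#' @param system a [LinearSystemSpec-class]
#' @param omega relaxation factor in (0, 2).
#' @param tol residual tolerance, kT/e.
#' @param maxiter maximum sweeps.
#' @param initial optional initial-guess array (interior values;
#'   boundary is always reset to the Dirichlet data). Default zero.
#' @return list with \code{phi} ([ScalarField-class]) and
#'   \code{diagnostics} ([SolveDiagnostics-class]).
#' @export
sorSolve <- function(system, omega = 1.9, tol = 1e-6,
                     maxiter = 30000, initial = NULL) {
  stopifnot(is(system, "LinearSystemSpec"), omega > 0, omega < 2)
  g <- system@grid
  d <- as.integer(g@dims)
  h2 <- g@h^2
  bnd <- .boundaryMask(d)
  # default initial guess: the boundary mean, so a constant-boundary
  # homogeneous system is already solved at sweep one
  phi0 <- if (is.null(initial))
    array(mean(system@boundary[bnd]), dim = d)
  else initial
  stopifnot(identical(dim(phi0), d))
  phi0[bnd] <- system@boundary[bnd]
  res <- .cpp_sor(as.numeric(system@epsX), as.numeric(system@epsY),
                  as.numeric(system@epsZ),
                  as.numeric(system@screening) * h2,
                  as.numeric(system@rhs) * h2, as.numeric(phi0), d,
                  omega, tol, as.integer(maxiter))
  phi <- array(res$phi, dim = d)
  list(phi = new("ScalarField", grid = g, values = phi),
       diagnostics = new("SolveDiagnostics",
                         iterations = res$iterations,
                         finalResidual = res$residual,
                         converged = res$converged))
}

# logical array marking boundary nodes
.boundaryMask <- function(d) {
  m <- array(FALSE, dim = d)
  m[c(1, d[1]), , ] <- TRUE
  m[, c(1, d[2]), ] <- TRUE
  m[, , c(1, d[3])] <- TRUE
  m
}

#' Direct sparse solve of a discretized system
#'
#' Assembles the interior equations as one sparse matrix and solves by
#' sparse LU (Matrix package): an SOR-independent reference solution.
#' Guarded to small systems (<= 25000 total nodes), its role being
#' verification, not production.
#'
#' @param system a [LinearSystemSpec-class]
#' @return a [ScalarField-class] (boundary nodes carry the Dirichlet
#'   values).
#' @export
directSolve <- function(system) {
  stopifnot(is(system, "LinearSystemSpec"))
  g <- system@grid
  d <- as.integer(g@dims)
  if (prod(as.numeric(d)) > 25000)
    stop("directSolve is a verification oracle; total nodes must be <= 25000")
  h2 <- g@h^2
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  nxi <- nx - 2L; nyi <- ny - 2L; nzi <- nz - 2L
  nInt <- nxi * nyi * nzi
  # interior node (ii,jj,kk) [1-based] <-> global (ii+1, jj+1, kk+1)
  ii <- rep(seq_len(nxi), times = nyi * nzi)
  jj <- rep(rep(seq_len(nyi), each = nxi), times = nzi)
  kk <- rep(seq_len(nzi), each = nxi * nyi)
  gi <- ii + 1L; gj <- jj + 1L; gk <- kk + 1L
  lin <- function(i, j, k) i + nx * (j - 1L + ny * (k - 1L))
  id <- seq_len(nInt)
  gidx <- lin(gi, gj, gk)
  exm <- system@epsX[lin(gi - 1L, gj, gk)]
  exp_ <- system@epsX[gidx]
  eym <- system@epsY[lin(gi, gj - 1L, gk)]
  eyp <- system@epsY[gidx]
  ezm <- system@epsZ[lin(gi, gj, gk - 1L)]
  ezp <- system@epsZ[gidx]
  diag <- exm + exp_ + eym + eyp + ezm + ezp +
    system@screening[gidx] * h2
  b <- system@rhs[gidx] * h2
  rows <- id; cols <- id; vals <- diag
  addNb <- function(coef, di, dj, dk, interiorFlag) {
    tgt <- interiorFlag
    # neighbor inside: off-diagonal entry; on boundary: move to rhs
    nbId <- id + di + dj * nxi + dk * nxi * nyi
    rows <<- c(rows, id[tgt]); cols <<- c(cols, nbId[tgt])
    vals <<- c(vals, -coef[tgt])
    out <- !tgt
    if (any(out)) {
      bIdx <- lin(gi[out] + di, gj[out] + dj, gk[out] + dk)
      b[out] <<- b[out] + coef[out] * system@boundary[bIdx]
    }
    invisible(NULL)
  }
  addNb(exm, -1L, 0L, 0L, ii > 1L)
  addNb(exp_, +1L, 0L, 0L, ii < nxi)
  addNb(eym, 0L, -1L, 0L, jj > 1L)
  addNb(eyp, 0L, +1L, 0L, jj < nyi)
  addNb(ezm, 0L, 0L, -1L, kk > 1L)
  addNb(ezp, 0L, 0L, +1L, kk < nzi)
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(nInt, nInt))
  x <- as.numeric(Matrix::solve(A, b))
  phi <- array(0, dim = d)
  bnd <- .boundaryMask(d)
  phi[bnd] <- system@boundary[bnd]
  phi[gidx] <- x
  new("ScalarField", grid = g, values = phi)
}

# Dirichlet boundary array for a phase; subtractG = TRUE gives the
# regularized condition phi_b - G.
.boundaryArray <- function(solute, grid, phase, params, constants,
                           subtractG = FALSE) {
  d <- as.integer(grid@dims)
  bnd <- which(.boundaryMask(d))
  ijk <- arrayInd(bnd, d) - 1L   # 0-based
  pts <- indexToWorld(grid, ijk)
  v <- boundaryPotential(solute, pts, phase = phase,
                         bcType = params@bcType, constants = constants,
                         epsOut = params@epsOut,
                         kappa2 = constants$kappa2)
  if (subtractG)
    v <- v - greensPotential(solute, pts, constants,
                             epsRef = params@epsRef)
  arr <- array(0, dim = d)
  arr[bnd] <- v
  arr
}

#' Solve the regularized PB equation for one phase
#'
#' End-to-end driver: builds the phase dielectric fields, the
#' regularized source (grad eps . grad G minus the salt term in
#' water), the screening coefficient ((1-S) kappa^2 in water, 0 in
#' vacuum) and the boundary condition phi_b - G, then runs SOR. The
#' result is the reaction-field potential phi_RF on the grid --
#' bounded everywhere, including at atom centers.
#'
#' @param solute a [Solute-class]
#' @param params a [PBParams-class]
#' @param phase "water" or "vacuum".
#' @param grid optional prebuilt [Grid3D-class]; default
#'   \code{buildGrid(solute, params@scale, params@paddingA)}. Water
#'   and vacuum phases of one energy evaluation must share the grid.
#' @return list: \code{phi} ([ScalarField-class]),
#'   \code{diagnostics} ([SolveDiagnostics-class]), \code{grid}.
#' @export
solveRPB <- function(solute, params, phase = c("water", "vacuum"),
                     grid = NULL) {
  phase <- match.arg(phase)
  validObject(params)
  if (is.null(grid))
    grid <- buildGrid(solute, params@scale, params@paddingA)
  constants <- physicalConstants(params@temperature, params@saltMolar)
  phaseEps <- if (phase == "water") params@epsOut else 1
  fields <- dielectricFields(solute, grid, params, phaseEps)
  if (phase == "water") {
    src <- rpbSourceWater(solute, grid, fields, constants,
                          kappa2 = constants$kappa2,
                          epsRef = params@epsRef)
    screening <- (1 - fields$S@values) * constants$kappa2
  } else {
    src <- rpbSourceVacuum(solute, grid, fields, constants,
                           epsRef = params@epsRef)
    screening <- array(0, dim = as.integer(grid@dims))
  }
  bArr <- .boundaryArray(solute, grid, phase, params, constants,
                         subtractG = TRUE)
  sys <- discretizeSystem(fields$epsMidX, fields$epsMidY,
                          fields$epsMidZ, screening, src@values, bArr,
                          grid)
  sol <- sorSolve(sys, omega = params@sorOmega, tol = params@sorTol,
                  maxiter = params@sorMaxiter)
  list(phi = sol$phi, diagnostics = sol$diagnostics, grid = grid)
}

# Trilinear (cloud-in-cell) charge assignment: each q_j spread onto
# its 8 enclosing nodes; total grid charge equals sum(q) exactly.
# Returned as the PB source rhs 4*pi*C*q_node/h^3.
.singularSource <- function(solute, grid, constants) {
  d <- as.integer(grid@dims)
  rhs <- array(0, dim = d)
  pos <- atomCoords(solute); q <- atomCharges(solute)
  C <- constants$coulombPrefactor
  fidx <- worldToIndex(grid, pos)   # 0-based fractional
  if (any(fidx < 0) || any(sweep(fidx, 2, d - 1L) > 0))
    stop("atom outside the grid")
  i0 <- pmin(floor(fidx), matrix(rep(d - 2L, each = nrow(fidx)),
                                 ncol = 3))
  fr <- fidx - i0
  for (jat in seq_along(q)) {
    wx <- c(1 - fr[jat, 1], fr[jat, 1])
    wy <- c(1 - fr[jat, 2], fr[jat, 2])
    wz <- c(1 - fr[jat, 3], fr[jat, 3])
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      w <- wx[a + 1] * wy[b + 1] * wz[cc + 1]
      if (w == 0) next
      rhs[i0[jat, 1] + a + 1L, i0[jat, 2] + b + 1L,
          i0[jat, 3] + cc + 1L] <-
        rhs[i0[jat, 1] + a + 1L, i0[jat, 2] + b + 1L,
            i0[jat, 3] + cc + 1L] + w * q[jat]
    }
  }
  rhs * (4 * pi * C / grid@h^3)
}

#' Solve the direct (Gaussian) PB equation for one phase
#'
#' The unregularized route: the full potential phi is solved with the
#' singular charge density mapped onto the grid by trilinear
#' (cloud-in-cell) assignment and the plain phi_b boundary condition.
#' Carries the grid self-energy, which cancels only approximately in
#' the water - vacuum difference; kept as the cross-validation
#' baseline for the regularized path.
#'
#' @inheritParams solveRPB
#' @return list: \code{phi}, \code{diagnostics}, \code{grid}.
#' @export
solveGaussPB <- function(solute, params, phase = c("water", "vacuum"),
                         grid = NULL) {
  phase <- match.arg(phase)
  validObject(params)
  if (is.null(grid))
    grid <- buildGrid(solute, params@scale, params@paddingA)
  constants <- physicalConstants(params@temperature, params@saltMolar)
  phaseEps <- if (phase == "water") params@epsOut else 1
  fields <- dielectricFields(solute, grid, params, phaseEps)
  screening <- if (phase == "water")
    (1 - fields$S@values) * constants$kappa2
  else array(0, dim = as.integer(grid@dims))
  rhs <- .singularSource(solute, grid, constants)
  bArr <- .boundaryArray(solute, grid, phase, params, constants,
                         subtractG = FALSE)
  sys <- discretizeSystem(fields$epsMidX, fields$epsMidY,
                          fields$epsMidZ, screening, rhs, bArr, grid)
  sol <- sorSolve(sys, omega = params@sorOmega, tol = params@sorTol,
                  maxiter = params@sorMaxiter)
  list(phi = sol$phi, diagnostics = sol$diagnostics, grid = grid)
}
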
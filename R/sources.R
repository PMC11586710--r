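# Analytic Coulomb (Green's function) potential, boundary conditions
# and the regularized right-hand-side source fields.

#' Green's function potential of the solute charges
#'
#' G(r) = C sum_j q_j / (eps_ref |r - r_j|) in kT/e, the solution of
#' the homogeneous-dielectric Poisson equation -eps_ref Lap(phi_C) =
#' rho. This is the singular Coulomb component removed analytically by
#' the regularization; the reference dielectric (not the solvent
#' dielectric) sits in the denominator, consistent with the defining
#' Poisson equation.
#'
#' @param solute a [Solute-class]
#' @param point 3-vector or n x 3 matrix, Angstrom.
#' @param constants list from [physicalConstants()].
#' @param epsRef reference dielectric of the decomposition.
#' @return potential in kT/e.
#' @export
greensPotential <- function(solute, point, constants, epsRef = 1) {
  pts <- .asPoints(point)
  pos <- atomCoords(solute); q <- atomCharges(solute)
  C <- constants$coulombPrefactor
  G <- numeric(nrow(pts))
  for (j in seq_along(q)) {
    r <- sqrt((pts[, 1] - pos[j, 1])^2 + (pts[, 2] - pos[j, 2])^2 +
              (pts[, 3] - pos[j, 3])^2)
    if (any(r < 1e-9))
      stop("greensPotential evaluated at (or within 1e-9 A of) an atom center")
    G <- G + C * q[j] / (epsRef * r)
  }
  G
}

#' Gradient of the Green's function potential
#'
#' grad G = -C sum_j q_j (r - r_j) / (eps_ref |r - r_j|^3): for a
#' positive charge the gradient points toward the charge (the
#' potential decreases outward).
#'
#' @inheritParams greensPotential
#' @return n x 3 matrix, kT/e per Angstrom.
#' @export
greensGradient <- function(solute, point, constants, epsRef = 1) {
  pts <- .asPoints(point)
  pos <- atomCoords(solute); q <- atomCharges(solute)
  C <- constants$coulombPrefactor
  out <- matrix(0, nrow(pts), 3)
  for (j in seq_along(q)) {
    dx <- pts[, 1] - pos[j, 1]; dy <- pts[, 2] - pos[j, 2]
    dz <- pts[, 3] - pos[j, 3]
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    if (any(r < 1e-9))
      stop("greensGradient evaluated at (or within 1e-9 A of) an atom center")
    f <- -C * q[j] / (epsRef * r^3)
    out[, 1] <- out[, 1] + f * dx
    out[, 2] <- out[, 2] + f * dy
    out[, 3] <- out[, 3] + f * dz
  }
  out
}

# G and grad G on every node of a grid. Nodes within `singTol` of an
# atom center are flagged (col `near`): the regularized source is set
# to zero there, where the analytic limit of the full product is zero.
.gridGreens <- function(solute, grid, constants, epsRef = 1,
                        withGrad = TRUE, singTol = 1e-9) {
  d <- grid@dims
  ax <- gridAxes(grid)
  pos <- atomCoords(solute); q <- atomCharges(solute)
  C <- constants$coulombPrefactor
  G <- array(0, dim = d)
  if (withGrad) {
    Gx <- array(0, dim = d); Gy <- array(0, dim = d)
    Gz <- array(0, dim = d)
  }
  near <- array(FALSE, dim = d)
  for (j in seq_along(q)) {
    dx <- ax$x - pos[j, 1]; dy <- ax$y - pos[j, 2]
    dz <- ax$z - pos[j, 3]
    r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    sing <- r2 < singTol^2
    near <- near | sing
    r2[sing] <- 1   # placeholder; flagged entries overwritten by caller
    r <- sqrt(r2)
    G <- G + C * q[j] / (epsRef * r)
    if (withGrad) {
      f <- -C * q[j] / (epsRef * r^3)
      nx <- length(dx); ny <- length(dy); nz <- length(dz)
      Gx <- Gx + f * array(dx, dim = d)
      Gy <- Gy + f * array(rep(dy, each = nx), dim = d)
      Gz <- Gz + f * array(rep(dz, each = nx * ny), dim = d)
    }
  }
  out <- list(G = G, near = near)
  if (withGrad) { out$Gx <- Gx; out$Gy <- Gy; out$Gz <- Gz }
  out
}

#' Charge summary of a solute
#'
#' Total positive and negative partial charges and their
#' charge-weighted geometric centers; the two centers form the dipole
#' used by the dipolar boundary condition, and their separation is the
#' dipole length dL.
#'
#' @param solute a [Solute-class]
#' @return named list: \code{qTotPlus}, \code{qTotMinus},
#'   \code{centerPlus}, \code{centerMinus} (NA 3-vector when the sign
#'   class is empty), \code{dipoleLength} (NA when either class is
#'   empty), \code{dipolarAvailable}.
#' @examples
#' chargeSummary(makeTwoAtomSystem())
#' @export
chargeSummary <- function(solute) {
  q <- atomCharges(solute); pos <- atomCoords(solute)
  ip <- q > 0; im <- q < 0
  qp <- sum(q[ip]); qm <- sum(q[im])
  cp <- if (any(ip)) colSums(pos[ip, , drop = FALSE] * q[ip]) / qp
        else rep(NA_real_, 3)
  cm <- if (any(im)) colSums(pos[im, , drop = FALSE] * q[im]) / qm
        else rep(NA_real_, 3)
  dl <- if (any(ip) && any(im)) sqrt(sum((cp - cm)^2)) else NA_real_
  list(qTotPlus = qp, qTotMinus = qm, centerPlus = cp,
       centerMinus = cm, dipoleLength = dl,
       dipolarAvailable = any(ip) && any(im))
}

#' Dirichlet boundary potential
#'
#' Far-field potential on the box boundary. Coulombic: the screened
#' per-charge sum \eqn{C \sum_j q_j e^{-|r-r_j|\tilde\kappa} /
#' (\epsilon_{out}|r-r_j|)} with screening
#' \eqn{\tilde\kappa = \sqrt{\kappa^2/\epsilon_{out}}} (the standard
#' Debye-Huckel length). Dipolar: the same expression collapsed onto
#' the two net-charge centers -- cheaper for large solutes and
#' equivalent in the far field. Vacuum phase: eps_out = 1 and no
#' screening.
#'
#' @param solute a [Solute-class]
#' @param point boundary point(s), 3-vector or n x 3 matrix.
#' @param phase "water" or "vacuum".
#' @param bcType "coulombic" or "dipolar".
#' @param constants list from [physicalConstants()].
#' @param epsOut solvent dielectric of the water phase.
#' @param kappa2 Debye-Huckel kappa^2, 1/Angstrom^2.
#' @return potential in kT/e.
#' @export
boundaryPotential <- function(solute, point, phase = c("water", "vacuum"),
                              bcType = "coulombic", constants,
                              epsOut = 80, kappa2 = 0) {
  phase <- match.arg(phase)
  pts <- .asPoints(point)
  C <- constants$coulombPrefactor
  if (phase == "vacuum") { epsOut <- 1; kappa2 <- 0 }
  kapEff <- sqrt(kappa2 / epsOut)
  screenedSum <- function(centers, charges) {
    v <- numeric(nrow(pts))
    for (j in seq_along(charges)) {
      r <- sqrt((pts[, 1] - centers[j, 1])^2 +
                (pts[, 2] - centers[j, 2])^2 +
                (pts[, 3] - centers[j, 3])^2)
      v <- v + C * charges[j] * exp(-r * kapEff) / (epsOut * r)
    }
    v
  }
  if (bcType == "coulombic") {
    screenedSum(atomCoords(solute), atomCharges(solute))
  } else if (bcType == "dipolar") {
    cs <- chargeSummary(solute)
    if (!cs$dipolarAvailable)
      stop("dipolar boundary condition needs both positive and negative ",
           "partial charges; use bcType = 'coulombic'")
    screenedSum(rbind(cs$centerPlus, cs$centerMinus),
                c(cs$qTotPlus, cs$qTotMinus))
  } else stop("unknown bcType: ", bcType)
}

# Shared regularized-source builder. f = gradEps . gradG - (1-S) kappa2 G
# per node; kappa2 = 0 gives the vacuum form. Finite everywhere: near
# atom centers gradEps -> 0 and (1-S) -> 0 faster than G, gradG blow up
# (for m >= 2); nodes numerically on a center are set to 0, the
# analytic limit.
.rpbSource <- function(solute, grid, fields, constants, kappa2,
                       epsRef = 1) {
  gg <- .gridGreens(solute, grid, constants, epsRef = epsRef,
                    withGrad = TRUE)
  gE <- fields$gradEps@values
  f <- gE[, , , 1] * gg$Gx + gE[, , , 2] * gg$Gy +
       gE[, , , 3] * gg$Gz
  if (kappa2 > 0)
    f <- f - (1 - fields$S@values) * kappa2 * gg$G
  f[gg$near] <- 0
  new("ScalarField", grid = grid, values = f)
}

#' Regularized source field, water phase
#'
#' Right-hand side of the regularized linearized PB equation in the
#' solvent phase: f = grad eps . grad G - (1 - S) kappa^2 G at every
#' node. Both factors of each term vanish where the other is singular,
#' so the field is finite everywhere including at atom centers -- the
#' central promise of the regularization.
#'
#' @param solute a [Solute-class]
#' @param grid a [Grid3D-class]
#' @param fields water-phase output of [dielectricFields()].
#' @param constants list from [physicalConstants()].
#' @param kappa2 Debye-Huckel kappa^2, 1/Angstrom^2.
#' @param epsRef reference dielectric of the Green's-function
#'   decomposition.
#' @return a [ScalarField-class]
#' @export
rpbSourceWater <- function(solute, grid, fields, constants,
                           kappa2 = constants$kappa2, epsRef = 1) {
  .rpbSource(solute, grid, fields, constants, kappa2, epsRef)
}

#' Regularized source field, vacuum phase
#'
#' f = grad eps_v . grad G with the vacuum-phase dielectric gradient
#' and no salt term. Identically zero when eps_gap = eps_ref = 1 (a
#' homogeneous medium has no reaction field).
#'
#' @param solute a [Solute-class]
#' @param grid a [Grid3D-class]
#' @param fields vacuum-phase output of [dielectricFields()].
#' @param constants list from [physicalConstants()].
#' @param epsRef reference dielectric of the Green's-function
#'   decomposition.
#' @return a [ScalarField-class]
#' @export
rpbSourceVacuum <- function(solute, grid, fields, constants,
                            epsRef = 1) {
  .rpbSource(solute, grid, fields, constants, kappa2 = 0,
             epsRef = epsRef)
}
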
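#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib suGaussRPB, .registration = TRUE
NULL

#' Solute: an ordered collection of atoms
#'
#' An atomic solute as read from a PQR file or built by a fixture
#' generator. Atoms carry a short name, a Cartesian position (Angstrom),
#' a partial charge (units of the elementary charge e) and a radius
#' (Angstrom). Atom order is preserved throughout.
#'
#' @slot atoms data.frame with columns \code{name}, \code{x}, \code{y},
#'   \code{z}, \code{charge}, \code{radius}; one row per atom.
#' @slot id free-text label for the solute.
#'
#' @seealso [readPQR()], [makeBornIon()], [makeTwoAtomSystem()]
#' @exportClass Solute
setClass("Solute",
  slots = c(atoms = "data.frame", id = "character"))

setValidity("Solute", function(object) {
  a <- object@atoms
  need <- c("name", "x", "y", "z", "charge", "radius")
  if (!all(need %in% names(a)))
    return(sprintf("atoms must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(a) < 1L) return("a Solute must contain at least one atom")
  pos <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(pos))) return("atom positions must be finite")
  if (!all(is.finite(a$charge))) return("atom charges must be finite")
  if (!all(is.finite(a$radius)) || any(a$radius <= 0))
    return("atom radii must be positive and finite")
  TRUE
})

#' PBParams: model and solver parameters
#'
#' All parameters of the super-Gaussian dielectric model, the
#' Poisson-Boltzmann equation and the finite-difference solver. The
#' defaults are the optimal parameter set for polar solvation of
#' proteins: sigma = 1.0, m = 2, eps_ref = 1, eps_gap = 22,
#' eps_out = 80, eta = 4/m, zero salt, scale 2.5 grids/Angstrom and a
#' 15 Angstrom box padding.
#'
#' @slot sigma super-Gaussian variance parameter (dimensionless).
#' @slot m super-Gaussian exponent (integer >= 1; m = 1 is the plain
#'   Gaussian, m >= 2 super-Gaussian, m -> Inf a hard sphere).
#' @slot epsRef reference (minimum) dielectric inside the solute.
#' @slot epsGap limiting dielectric of the density-dependent component
#'   in loosely packed solute regions.
#' @slot epsOut solvent dielectric (80 for water).
#' @slot eta steepness exponent of the density-dependent surface function.
#' @slot saltMolar ionic strength I, mol/L.
#' @slot temperature absolute temperature, K.
#' @slot scale grid resolution, grids per Angstrom (spacing h = 1/scale).
#' @slot paddingA minimum distance from any atom center to every box
#'   face, Angstrom.
#' @slot bcType Dirichlet boundary condition type: "coulombic"
#'   (screened per-charge sum) or "dipolar" (two net-charge centers).
#' @slot sorOmega SOR over-relaxation factor in (0, 2).
#' @slot sorTol convergence tolerance on the diagonally scaled residual
#'   (kT/e, max-norm).
#' @slot sorMaxiter maximum number of SOR sweeps.
#'
#' @seealso [pbParams()], [defaultParams()]
#' @exportClass PBParams
setClass("PBParams",
  slots = c(sigma = "numeric", m = "numeric", epsRef = "numeric",
            epsGap = "numeric", epsOut = "numeric", eta = "numeric",
            saltMolar = "numeric", temperature = "numeric",
            scale = "numeric", paddingA = "numeric", bcType = "character",
            sorOmega = "numeric", sorTol = "numeric",
            sorMaxiter = "numeric"))

setValidity("PBParams", function(object) {
  if (object@sigma <= 0) return("sigma must be > 0")
  if (object@m < 1 || object@m != round(object@m))
    return("m must be an integer >= 1")
  if (object@epsRef < 1) return("epsRef must be >= 1")
  if (object@epsGap < object@epsRef) return("epsGap must be >= epsRef")
  if (object@epsOut < 1) return("epsOut must be >= 1")
  if (object@eta <= 0) return("eta must be > 0")
  if (object@saltMolar < 0) return("saltMolar must be >= 0")
  if (object@temperature <= 0) return("temperature must be > 0")
  if (object@scale <= 0) return("scale must be > 0")
  if (object@paddingA < 0) return("paddingA must be >= 0")
  if (!object@bcType %in% c("coulombic", "dipolar"))
    return("bcType must be 'coulombic' or 'dipolar'")
  if (object@sorOmega <= 0 || object@sorOmega >= 2)
    return("sorOmega must lie in (0, 2)")
  if (object@sorTol <= 0) return("sorTol must be > 0")
  if (object@sorMaxiter < 1) return("sorMaxiter must be >= 1")
  TRUE
})

#' Grid3D: a uniform cubic lattice
#'
#' Node-centered uniform lattice with equal spacing h in x, y and z.
#' Node (0,0,0) (0-based indexing) sits at \code{origin}; node
#' (i,j,k) at \code{origin + h*(i,j,k)}.
#'
#' @slot origin world coordinate (Angstrom) of node (0,0,0).
#' @slot h grid spacing, Angstrom (= 1/scale).
#' @slot dims integer node counts (Nx, Ny, Nz), each >= 5.
#'
#' @seealso [buildGrid()], [worldToIndex()], [indexToWorld()]
#' @exportClass Grid3D
setClass("Grid3D",
  slots = c(origin = "numeric", h = "numeric", dims = "integer"))

setValidity("Grid3D", function(object) {
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    return("origin must be a finite 3-vector")
  if (length(object@h) != 1L || object@h <= 0) return("h must be > 0")
  if (length(object@dims) != 3L || any(object@dims < 5L))
    return("dims must be three node counts, each >= 5")
  TRUE
})

#' ScalarField: one value per grid node
#'
#' @slot grid the [Grid3D-class] the values live on.
#' @slot values numeric array of dimension \code{dims(grid)}.
#' @exportClass ScalarField
setClass("ScalarField", slots = c(grid = "Grid3D", values = "array"))

setValidity("ScalarField", function(object) {
  if (!identical(dim(object@values), as.integer(object@grid@dims)))
    return("values array dimension must equal grid dims")
  TRUE
})

#' VectorField: one 3-vector per grid node
#'
#' @slot grid the [Grid3D-class] the values live on.
#' @slot values numeric array of dimension \code{c(dims(grid), 3)};
#'   the last index is the Cartesian component.
#' @exportClass VectorField
setClass("VectorField", slots = c(grid = "Grid3D", values = "array"))

setValidity("VectorField", function(object) {
  if (!identical(dim(object@values), c(as.integer(object@grid@dims), 3L)))
    return("values array dimension must equal c(grid dims, 3)")
  TRUE
})

#' SolveDiagnostics: iteration record of a linear solve
#'
#' @slot iterations number of SOR sweeps performed.
#' @slot finalResidual diagonally scaled linear residual (max-norm,
#'   kT/e) at exit.
#' @slot converged whether the residual dropped below the tolerance.
#' @exportClass SolveDiagnostics
setClass("SolveDiagnostics",
  slots = c(iterations = "numeric", finalResidual = "numeric",
            converged = "logical"))

#' LinearSystemSpec: a discretized variable-coefficient system
#'
#' The 7-point finite-difference discretization of
#' \eqn{-\nabla\cdot(\epsilon\nabla\phi) + (1-S)\kappa^2\phi = f}
#' with Dirichlet boundaries. Midpoint dielectric arrays store
#' \eqn{\epsilon} halfway between a node and its +x/+y/+z neighbor.
#'
#' @slot grid the [Grid3D-class].
#' @slot epsX,epsY,epsZ arrays of dielectric values at the
#'   (i+1/2,j,k), (i,j+1/2,k), (i,j,k+1/2) midpoints (full node dims;
#'   the last slab along the shifted axis is unused).
#' @slot screening array of \eqn{(1-S)\kappa^2} per node, 1/Angstrom^2.
#' @slot rhs source per node (kT/e / Angstrom^2 scale).
#' @slot boundary array of Dirichlet values; only boundary-face entries
#'   are used.
#' @exportClass LinearSystemSpec
setClass("LinearSystemSpec",
  slots = c(grid = "Grid3D", epsX = "array", epsY = "array",
            epsZ = "array", screening = "array", rhs = "array",
            boundary = "array"))

setValidity("LinearSystemSpec", function(object) {
  d <- as.integer(object@grid@dims)
  for (nm in c("epsX", "epsY", "epsZ", "screening", "rhs", "boundary"))
    if (!identical(dim(slot(object, nm)), d))
      return(sprintf("%s must have the grid's dimensions", nm))
  if (any(object@epsX <= 0) || any(object@epsY <= 0) ||
      any(object@epsZ <= 0))
    return("midpoint dielectric must be positive everywhere")
  if (any(object@screening < 0)) return("screening must be >= 0")
  if (!all(is.finite(object@rhs))) return("rhs must be finite")
  TRUE
})

#' SolvationResult: polar solvation free energy of one solute
#'
#' Reaction-field (or direct) energies in the water and vacuum phases
#' and their difference, the polar solvation free energy, in kcal/mol.
#'
#' @slot energyWater water-phase energy term, kcal/mol.
#' @slot energyVacuum vacuum-phase energy term, kcal/mol.
#' @slot dGPolar polar solvation free energy
#'   \code{energyWater - energyVacuum}, kcal/mol.
#' @slot method "rpb" (regularized) or "gauss" (direct).
#' @slot params the [PBParams-class] used.
#' @slot diagnostics named list with per-phase [SolveDiagnostics-class]
#'   (\code{water}, \code{vacuum}).
#' @exportClass SolvationResult
setClass("SolvationResult",
  slots = c(energyWater = "numeric", energyVacuum = "numeric",
            dGPolar = "numeric", method = "character",
            params = "PBParams", diagnostics = "list"))

setValidity("SolvationResult", function(object) {
  if (!object@method %in% c("rpb", "gauss"))
    return("method must be 'rpb' or 'gauss'")
  if (abs(object@dGPolar - (object@energyWater - object@energyVacuum)) >
      1e-9 * max(1, abs(object@dGPolar)))
    return("dGPolar must equal energyWater - energyVacuum")
  TRUE
})

#' ConvergenceScan: energies across grid scales
#'
#' One polar solvation energy per grid scale, normalized as
#' \code{100 * dG(scale) / dG(scale = 4)} so the finest scale reads
#' exactly 100.
#'
#' @slot scales grid scales scanned, grids/Angstrom.
#' @slot energies dG_polar at each scale, kcal/mol.
#' @slot normalized 100 * energies / energies[scale == 4].
#' @slot results list of per-scale [SolvationResult-class] objects.
#' @exportClass ConvergenceScan
setClass("ConvergenceScan",
  slots = c(scales = "numeric", energies = "numeric",
            normalized = "numeric", results = "list"))

setValidity("ConvergenceScan", function(object) {
  n <- length(object@scales)
  if (length(object@energies) != n || length(object@normalized) != n)
    return("scales, energies and normalized must have equal length")
  i4 <- which(abs(object@scales - 4) < 1e-9)
  if (length(i4) == 1L && abs(object@normalized[i4] - 100) > 1e-9)
    return("normalized value at scale 4 must be exactly 100")
  TRUE
})
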
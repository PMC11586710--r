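#' @describeIn nAtoms atom count of a Solute
#' @export
setMethod("nAtoms", "Solute", function(x) nrow(x@atoms))

#' @describeIn atomCoords coordinates of a Solute
#' @export
setMethod("atomCoords", "Solute", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})

#' @describeIn atomCharges charges of a Solute
#' @export
setMethod("atomCharges", "Solute", function(x) x@atoms$charge)

#' @describeIn atomRadii radii of a Solute
#' @export
setMethod("atomRadii", "Solute", function(x) x@atoms$radius)

#' @describeIn gridOf grid of a ScalarField
#' @export
setMethod("gridOf", "ScalarField", function(x) x@grid)

#' @describeIn gridOf grid of a VectorField
#' @export
setMethod("gridOf", "VectorField", function(x) x@grid)

#' @describeIn fieldValues values of a ScalarField
#' @export
setMethod("fieldValues", "ScalarField", function(x) x@values)

#' @describeIn fieldValues values of a VectorField
#' @export
setMethod("fieldValues", "VectorField", function(x) x@values)

#' @describeIn gridDims node counts
#' @export
setMethod("gridDims", "Grid3D", function(x) x@dims)

#' @describeIn gridSpacing spacing h
#' @export
setMethod("gridSpacing", "Grid3D", function(x) x@h)

#' @describeIn gridOrigin origin coordinate
#' @export
setMethod("gridOrigin", "Grid3D", function(x) x@origin)

#' @describeIn dGPolar polar solvation energy of a SolvationResult
#' @export
setMethod("dGPolar", "SolvationResult", function(x) x@dGPolar)

setMethod("show", "Solute", function(object) {
  q <- sum(object@atoms$charge)
  cat(sprintf("Solute '%s': %d atom%s, net charge %+.3f e\n",
              object@id, nrow(object@atoms),
              if (nrow(object@atoms) == 1L) "" else "s", q))
})

setMethod("show", "PBParams", function(object) {
  cat("PBParams (super-Gaussian dielectric / PB solver)\n")
  cat(sprintf("  sigma=%g  m=%d  eta=%g\n", object@sigma,
              as.integer(object@m), object@eta))
  cat(sprintf("  epsRef=%g  epsGap=%g  epsOut=%g\n", object@epsRef,
              object@epsGap, object@epsOut))
  cat(sprintf("  salt=%g mol/L  T=%g K\n", object@saltMolar,
              object@temperature))
  cat(sprintf("  scale=%g grids/A (h=%g A)  padding=%g A  bc=%s\n",
              object@scale, 1 / object@scale, object@paddingA,
              object@bcType))
  cat(sprintf("  SOR: omega=%g tol=%g maxiter=%d\n", object@sorOmega,
              object@sorTol, as.integer(object@sorMaxiter)))
})

setMethod("show", "Grid3D", function(object) {
  d <- object@dims
  cat(sprintf(
    "Grid3D: %d x %d x %d nodes (%s total), h=%g A\n  origin (%g, %g, %g) A\n",
    d[1], d[2], d[3], format(prod(as.numeric(d)), big.mark = ","),
    object@h, object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "ScalarField", function(object) {
  v <- range(object@values)
  cat(sprintf("ScalarField on %d x %d x %d grid, range [%.6g, %.6g]\n",
              object@grid@dims[1], object@grid@dims[2],
              object@grid@dims[3], v[1], v[2]))
})

setMethod("show", "VectorField", function(object) {
  n <- sqrt(rowSums(matrix(object@values, ncol = 3L)^2))
  cat(sprintf("VectorField on %d x %d x %d grid, |v| max %.6g\n",
              object@grid@dims[1], object@grid@dims[2],
              object@grid@dims[3], max(n)))
})

setMethod("show", "SolveDiagnostics", function(object) {
  cat(sprintf("SolveDiagnostics: %d sweeps, residual %.3e, %s\n",
              as.integer(object@iterations), object@finalResidual,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "SolvationResult", function(object) {
  cat(sprintf("SolvationResult [%s]\n", object@method))
  cat(sprintf("  E(water)  = %12.4f kcal/mol\n", object@energyWater))
  cat(sprintf("  E(vacuum) = %12.4f kcal/mol\n", object@energyVacuum))
  cat(sprintf("  dG_polar  = %12.4f kcal/mol\n", object@dGPolar))
  for (ph in names(object@diagnostics)) {
    d <- object@diagnostics[[ph]]
    cat(sprintf("  %s: %d sweeps, residual %.2e, %s\n", ph,
                as.integer(d@iterations), d@finalResidual,
                if (d@converged) "converged" else "NOT converged"))
  }
})

setMethod("show", "ConvergenceScan", function(object) {
  cat("ConvergenceScan (normalized to scale 4.0)\n")
  for (i in seq_along(object@scales))
    cat(sprintf("  scale %4.1f: dG = %12.4f kcal/mol  (%7.2f%%)\n",
                object@scales[i], object@energies[i],
                object@normalized[i]))
})
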
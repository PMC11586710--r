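#' Number of atoms in a solute
#' @param x a [Solute-class]
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom coordinates
#' @param x a [Solute-class]
#' @return numeric n x 3 matrix of positions, Angstrom
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' Atom partial charges
#' @param x a [Solute-class]
#' @return numeric vector, units of e
#' @export
setGeneric("atomCharges", function(x) standardGeneric("atomCharges"))

#' Atom radii
#' @param x a [Solute-class]
#' @return numeric vector, Angstrom
#' @export
setGeneric("atomRadii", function(x) standardGeneric("atomRadii"))

#' Grid accessor
#' @param x a ScalarField or VectorField
#' @return the underlying [Grid3D-class]
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))

#' Field values accessor
#' @param x a ScalarField or VectorField
#' @return the values array
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' Grid dimensions
#' @param x a [Grid3D-class]
#' @return integer 3-vector of node counts
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' Grid spacing
#' @param x a [Grid3D-class]
#' @return spacing h in Angstrom
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' Grid origin
#' @param x a [Grid3D-class]
#' @return world coordinate of node (0,0,0)
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' Polar solvation free energy accessor
#' @param x a [SolvationResult-class]
#' @return dG_polar in kcal/mol
#' @export
setGeneric("dGPolar", function(x) standardGeneric("dGPolar"))
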
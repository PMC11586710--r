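#' Build the computational lattice around a solute
#'
#' Axis-aligned bounding box of the atom centers, expanded by
#' \code{paddingA} on every side, then snapped outward to whole grid
#' cells of spacing h = 1/scale (the extra slack from snapping is split
#' symmetrically). The padding guarantee -- every atom center at least
#' \code{paddingA} from every box face -- is what lets the Dirichlet
#' boundary be approximated by the screened Coulomb / dipolar far
#' field.
#'
#' @param solute a [Solute-class]
#' @param scale grids per Angstrom.
#' @param paddingA minimum atom-center-to-face distance, Angstrom.
#' @return a [Grid3D-class]
#' @examples
#' buildGrid(makeBornIon(1, 2), scale = 2, paddingA = 15)
#' @export
buildGrid <- function(solute, scale, paddingA) {
  stopifnot(is(solute, "Solute"), scale > 0, paddingA >= 0)
  validObject(solute)
  h <- 1 / scale
  pos <- atomCoords(solute)
  lo <- apply(pos, 2, min) - paddingA
  hi <- apply(pos, 2, max) + paddingA
  span <- hi - lo
  ncell <- pmax(4L, as.integer(ceiling(span / h - 1e-12)))
  dims <- ncell + 1L
  slack <- ncell * h - span
  origin <- lo - slack / 2
  g <- new("Grid3D", origin = origin, h = h, dims = dims)
  validObject(g)
  g
}

#' World coordinates to fractional grid index
#'
#' 0-based fractional index \code{(point - origin)/h} per component;
#' exact inverse of [indexToWorld()].
#'
#' @param grid a [Grid3D-class]
#' @param point numeric 3-vector or n x 3 matrix, Angstrom.
#' @return fractional index, same shape as \code{point}.
#' @export
worldToIndex <- function(grid, point) {
  if (is.matrix(point))
    sweep(point, 2, grid@origin) / grid@h
  else
    (point - grid@origin) / grid@h
}

#' Fractional grid index to world coordinates
#'
#' @param grid a [Grid3D-class]
#' @param index 0-based fractional index 3-vector or n x 3 matrix.
#' @return world coordinates, Angstrom.
#' @export
indexToWorld <- function(grid, index) {
  if (is.matrix(index))
    sweep(index * grid@h, 2, grid@origin, "+")
  else
    grid@origin + index * grid@h
}

#' Node coordinate vectors of a grid
#'
#' @param grid a [Grid3D-class]
#' @return list with components x, y, z: world coordinates of the node
#'   planes along each axis.
#' @keywords internal
gridAxes <- function(grid) {
  list(x = grid@origin[1] + grid@h * (seq_len(grid@dims[1]) - 1),
       y = grid@origin[2] + grid@h * (seq_len(grid@dims[2]) - 1),
       z = grid@origin[3] + grid@h * (seq_len(grid@dims[3]) - 1))
}

#' Export a scalar field as an OpenDX volumetric map
#'
#' Plain-text OpenDX "regularpositions / regularconnections" format as
#' written by DelPhi/APBS-family tools, readable by PyMOL, VMD and
#' Chimera. Values are written in z-fastest order per the DX
#' convention.
#'
#' @param field a [ScalarField-class]
#' @param path output path (conventionally .dx).
#' @param comment header comment line.
#' @return invisibly, the path.
#' @export
writeDX <- function(field, path, comment = "scalar field") {
  stopifnot(is(field, "ScalarField"))
  g <- field@grid
  d <- g@dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("#", comment),
    sprintf("object 1 class gridpositions counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e",
            g@origin[1], g@origin[2], g@origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", g@h),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", g@h),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", g@h),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(
      "object 3 class array type double rank 0 items %d data follows",
      prod(as.numeric(d)))), con)
  # DX wants x slowest, z fastest: permute the column-major array
  v <- aperm(field@values, c(3, 2, 1))
  vals <- as.numeric(v)
  npad <- (3 - length(vals) %% 3) %% 3
  if (npad > 0) vals <- c(vals, rep(NA_real_, npad))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  rows <- apply(m, 1, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  writeLines(rows, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
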
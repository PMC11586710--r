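#' Construct a Solute from atom vectors
#'
#' @param x,y,z positions, Angstrom.
#' @param charge partial charges, e.
#' @param radius radii, Angstrom (> 0).
#' @param name per-atom labels (recycled).
#' @param id solute label.
#' @return a [Solute-class]
#' @export
newSolute <- function(x, y, z, charge, radius, name = "X",
                      id = "solute") {
  atoms <- data.frame(name = rep_len(as.character(name), length(x)),
                      x = as.numeric(x), y = as.numeric(y),
                      z = as.numeric(z), charge = as.numeric(charge),
                      radius = as.numeric(radius),
                      stringsAsFactors = FALSE)
  new("Solute", atoms = atoms, id = id)
}

#' Read a PQR structure file
#'
#' Whitespace-tokenized PQR dialect: every ATOM/HETATM record ends in
#' the fields x y z charge radius; preceding columns (serial, atom and
#' residue names, optional chain id, residue number) vary in the wild
#' and are tolerated by counting tokens from the end. Atom order is
#' preserved.
#'
#' @param path path to a PQR file.
#' @param id solute label; defaults to the file name.
#' @return a [Solute-class]
#' @examples
#' f <- tempfile(fileext = ".pqr")
#' writePQR(makeBornIon(1, 2), f)
#' readPQR(f)
#' @export
readPQR <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PQR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("no ATOM/HETATM records in ", path)
  n <- length(idx)
  nm <- character(n); xs <- ys <- zs <- qs <- rs <- numeric(n)
  for (i in seq_len(n)) {
    ln <- idx[i]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 8L)
      stop(sprintf("malformed PQR record at line %d: fewer than 8 fields",
                   ln))
    tail5 <- suppressWarnings(as.numeric(tok[(length(tok) - 4):length(tok)]))
    if (any(is.na(tail5)))
      stop(sprintf(
        "malformed PQR record at line %d: trailing x y z q r not numeric",
        ln))
    if (tail5[5] <= 0)
      stop(sprintf("invalid PQR record at line %d: radius must be positive",
                   ln))
    nm[i] <- tok[3]
    xs[i] <- tail5[1]; ys[i] <- tail5[2]; zs[i] <- tail5[3]
    qs[i] <- tail5[4]; rs[i] <- tail5[5]
  }
  if (is.null(id)) id <- basename(path)
  newSolute(xs, ys, zs, qs, rs, name = nm, id = id)
}

#' Write a Solute as a PQR file
#'
#' Fixed-format ATOM records with x, y, z, charge to 3 decimals and
#' radius to 3 decimals; round-trips through [readPQR()] to 1e-3.
#'
#' @param solute a [Solute-class]
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePQR <- function(solute, path) {
  stopifnot(is(solute, "Solute"))
  validObject(solute)
  a <- solute@atoms
  recs <- sprintf(
    "ATOM  %5d %-4s %-3s %5d    %8.3f%8.3f%8.3f %7.3f %6.3f",
    seq_len(nrow(a)), substr(a$name, 1, 4), "UNK", 1L,
    a$x, a$y, a$z, a$charge, a$radius)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(recs, "END"), con)
  invisible(path)
}

#' Born ion fixture
#'
#' A single spherical ion at the origin: the one geometry with a
#' closed-form solvation energy in the sharp-dielectric limit,
#' dG = -(C/2) q^2 (1/eps_in - 1/eps_out) / R.
#'
#' @param q partial charge, e.
#' @param R radius, Angstrom (> 0).
#' @return a [Solute-class] with one atom.
#' @examples
#' makeBornIon(1, 2)
#' @export
makeBornIon <- function(q = 1, R = 2) {
  if (R <= 0) stop("Born ion radius must be positive")
  newSolute(0, 0, 0, q, R, name = "ION", id = sprintf("born_q%g_R%g", q, R))
}

#' Two-atom fixture
#'
#' Two atoms with radii 1.5 and 1.7 Angstrom at (-1.5, 0, 0) and
#' (1.7, 0, 0): the canonical illustration of overlapping
#' super-Gaussian densities and the smooth two-center dielectric.
#' Charges are +0.5/-0.5 e by convention (the geometry alone defines
#' the fixture; charges matter only for potential and energy tests).
#'
#' @return a [Solute-class] with two atoms.
#' @export
makeTwoAtomSystem <- function() {
  newSolute(x = c(-1.5, 1.7), y = c(0, 0), z = c(0, 0),
            charge = c(0.5, -0.5), radius = c(1.5, 1.7),
            name = c("A1", "A2"), id = "two_atom")
}

#' Synthetic peptide-like fixture
#'
#' A deterministic pseudo-random chain of atoms emulating the size,
#' packing and partial-charge pattern of a short peptide: backbone
#' beads ~3.8 Angstrom apart with small perpendicular jitter, radii in
#' [1.2, 1.9] Angstrom and alternating partial charges that sum to a
#' chosen net charge. Purely synthetic -- no force field is consulted;
#' the fixture exists so multi-atom solver behavior can be exercised
#' without external structure files.
#'
#' @param nAtomsChain number of atoms in the chain.
#' @param netCharge net charge, e, distributed on top of the
#'   zero-sum alternating pattern.
#' @param seed integer seed; identical calls return identical solutes.
#' @return a [Solute-class]
#' @examples
#' makeSyntheticPeptide(8)
#' @export
makeSyntheticPeptide <- function(nAtomsChain = 10, netCharge = 0,
                                 seed = 42L) {
  stopifnot(nAtomsChain >= 1)
  # draw from a private RNG stream: the caller's .Random.seed must
  # survive fixture generation untouched
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed))
      assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  rs <- list(jit = matrix(stats::runif(3 * nAtomsChain, -0.9, 0.9),
                          ncol = 3),
             rad = stats::runif(nAtomsChain, 1.2, 1.9),
             qj = stats::runif(nAtomsChain, 0.25, 0.55))
  t <- seq_len(nAtomsChain) - 1
  pos <- cbind(3.8 * t * 0.55, 3.8 * t * 0.35, 3.8 * t * 0.25) + rs$jit
  q <- rs$qj * rep_len(c(1, -1), nAtomsChain)
  q <- q - mean(q) + netCharge / nAtomsChain
  newSolute(pos[, 1], pos[, 2], pos[, 3], q, rs$rad,
            name = sprintf("C%d", t + 1),
            id = sprintf("synthetic_peptide_n%d", nAtomsChain))
}

#' Model parameters, with the optimal defaults
#'
#' Constructor for [PBParams-class]. Defaults are the optimal parameter
#' set for protein polar solvation: sigma = 1, m = 2, eps_ref = 1,
#' eps_gap = 22, eps_out = 80, eta = 4/m, zero salt, 300 K, scale 2.5
#' grids/Angstrom, 15 Angstrom padding, Coulombic boundary condition.
#'
#' @param sigma super-Gaussian variance parameter.
#' @param m super-Gaussian exponent (integer >= 1).
#' @param epsRef reference dielectric at atom centers.
#' @param epsGap limiting solute dielectric in loosely packed regions.
#' @param epsOut solvent dielectric.
#' @param eta surface-function steepness; default 4/m.
#' @param saltMolar ionic strength, mol/L.
#' @param temperature K.
#' @param scale grids per Angstrom.
#' @param paddingA minimum atom-to-boundary distance, Angstrom.
#' @param bcType "coulombic" or "dipolar".
#' @param sorOmega SOR relaxation factor.
#' @param sorTol SOR residual tolerance (kT/e).
#' @param sorMaxiter maximum SOR sweeps.
#' @return a validated [PBParams-class]
#' @examples
#' pbParams()
#' pbParams(scale = 4, paddingA = 10)
#' @export
pbParams <- function(sigma = 1.0, m = 2L, epsRef = 1, epsGap = 22,
                     epsOut = 80, eta = 4 / m, saltMolar = 0,
                     temperature = 300, scale = 2.5, paddingA = 15,
                     bcType = "coulombic", sorOmega = 1.9,
                     sorTol = 1e-6, sorMaxiter = 30000L) {
  new("PBParams", sigma = sigma, m = as.numeric(m), epsRef = epsRef,
      epsGap = epsGap, epsOut = epsOut, eta = eta,
      saltMolar = saltMolar, temperature = temperature, scale = scale,
      paddingA = paddingA, bcType = bcType, sorOmega = sorOmega,
      sorTol = sorTol, sorMaxiter = as.numeric(sorMaxiter))
}

#' @rdname pbParams
#' @export
defaultParams <- function() pbParams()

#' Read parameters from a key=value config file
#'
#' Flat text config, one \code{key = value} pair per line, keys named
#' after the [pbParams()] arguments; '#' starts a comment. Unknown keys
#' are an error.
#'
#' @param path config file path.
#' @return a [PBParams-class]
#' @export
readParams <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(pbParams)))
      stop("unknown parameter key: ", key)
    args[[key]] <- if (key == "bcType") val else as.numeric(val)
  }
  do.call(pbParams, args)
}
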
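#' @useDynLib scqedhf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize rnorm runif setNames
#' @importFrom utils head tail
NULL

BOHR_PER_ANGSTROM <- 1 / 0.52917721092
HARTREE_PER_EV <- 1 / 27.211386

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"
)

atomic_number <- function(symbol) {
  z <- match(symbol, .element_symbols)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(symbol[is.na(z)], collapse = ", "))
  }
  z
}

#' Construct a molecular system
#'
#' Defines the molecule the cavity QED mean-field calculation is run on:
#' element symbols, nuclear positions, total charge and the Gaussian basis
#' set used to expand the orbitals. Positions are stored internally in bohr;
#' all other quantities in the package are in atomic units as well.
#'
#' @param atoms character vector of element symbols.
#' @param coords numeric matrix (n_atoms x 3) of positions.
#' @param charge integer total charge.
#' @param basis basis-set name resolvable by [load_basis()] (e.g. "sto-3g",
#'   "6-31g", "cc-pvdz", "aug-cc-pvdz").
#' @param unit `"angstrom"` (default) or `"bohr"` for `coords`.
#' @return an object of class `"molecule"` with fields `atoms`, `coords`
#'   (bohr), `charge`, `n_electrons` and `basis_name`.
#' @export
molecule <- function(atoms, coords, charge = 0L, basis = "sto-3g",
                     unit = c("angstrom", "bohr")) {
  unit <- match.arg(unit)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) != length(atoms)) {
    stop("coords must be a length(atoms) x 3 matrix")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (unit == "angstrom") coords <- coords * BOHR_PER_ANGSTROM
  z <- atomic_number(atoms)
  n_el <- sum(z) - as.integer(charge)
  if (n_el <= 0) stop("no electrons left for charge ", charge)
  if (n_el %% 2L != 0L) {
    stop("odd electron count (", n_el,
         "): only closed-shell restricted references are supported")
  }
  structure(
    list(atoms = atoms, coords = unname(coords), charge = as.integer(charge),
         n_electrons = as.integer(n_el), basis_name = tolower(basis)),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("Molecule:", length(x$atoms), "atoms, charge", x$charge,
      ", ", x$n_electrons, "electrons, basis", x$basis_name, "\n")
  ang <- x$coords / BOHR_PER_ANGSTROM
  for (i in seq_along(x$atoms)) {
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$atoms[i],
                ang[i, 1], ang[i, 2], ang[i, 3]))
  }
  invisible(x)
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ dialect: atom count line, comment line, then one
#' `element x y z` line per atom with coordinates in Angstrom.
#'
#' @param path path to the XYZ file.
#' @param charge total charge (XYZ carries no charge field).
#' @param basis basis-set name attached to the returned molecule.
#' @return a [molecule()] object (coordinates converted to bohr).
#' @export
read_xyz <- function(path, charge = 0L, basis = "sto-3g") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(length(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop("malformed XYZ: header declares ", n, " atoms but only ",
         length(body), " atom lines found")
  }
  body <- body[seq_len(n)]
  toks <- strsplit(trimws(body), "\\s+")
  if (any(vapply(toks, length, 1L) < 4L)) {
    stop("malformed XYZ: atom lines must be 'element x y z'")
  }
  atoms <- vapply(toks, `[`, "", 1L)
  coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (anyNA(coords)) stop("malformed XYZ: non-numeric coordinate")
  molecule(atoms, coords, charge = charge, basis = basis, unit = "angstrom")
}

#' Write a molecule to an XYZ file
#'
#' @param mol a [molecule()] object.
#' @param path output path.
#' @param comment comment line content.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, comment = "") {
  ang <- mol$coords / BOHR_PER_ANGSTROM
  lines <- c(as.character(length(mol$atoms)), comment,
             sprintf("%-2s %17.12f %17.12f %17.12f", mol$atoms,
                     ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Built-in benchmark geometries
#'
#' Standard equilibrium geometries for the small closed-shell systems used
#' throughout the package tests and examples: H2, H2O, NH3, CH2O and NH4+
#' (total charge +1). These are repository-standard geometries, not fitted
#' to any particular potential-energy surface point.
#'
#' @param name one of `"h2"`, `"h2o"`, `"nh3"`, `"ch2o"`, `"nh4+"`.
#' @param basis basis-set name attached to the molecule.
#' @return a [molecule()] object.
#' @export
fixture_molecule <- function(name = c("h2", "h2o", "nh3", "ch2o", "nh4+"),
                             basis = "sto-3g") {
  name <- match.arg(tolower(name), c("h2", "h2o", "nh3", "ch2o", "nh4+"))
  file <- c("h2" = "h2.xyz", "h2o" = "h2o.xyz", "nh3" = "nh3.xyz",
            "ch2o" = "ch2o.xyz", "nh4+" = "nh4.xyz")[[name]]
  charge <- if (name == "nh4+") 1L else 0L
  path <- system.file("extdata", "geometries", file, package = "scqedhf")
  if (!nzchar(path)) stop("geometry fixture not found: ", name)
  read_xyz(path, charge = charge, basis = basis)
}

nuclear_repulsion <- function(mol) {
  z <- atomic_number(mol$atoms)
  e <- 0
  n <- length(z)
  if (n < 2) return(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
      e <- e + z[i] * z[j] / r
    }
  }
  e
}

nuclear_dipole <- function(mol) {
  z <- atomic_number(mol$atoms)
  colSums(mol$coords * z)
}
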
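# Basis-set handling: parse the plain-text basis files shipped under
# extdata/basis, build contracted shells with primitive + contraction
# normalization, and provide the Cartesian -> real-spherical transformation.

.dfact <- function(n) {
  # (2n-1)!! style double factorial with (-1)!! = 1
  if (n <= 0) return(1)
  prod(seq(n, 1, by = -2))
}

#' Load a basis set definition
#'
#' Parses one of the plain-text basis files shipped with the package
#' (`sto-3g`, `6-31g`, `cc-pvdz`, `aug-cc-pvdz`; H/C/N/O). Pople `SP`
#' entries are split into separate s and p shells sharing exponents.
#'
#' @param name basis-set name (case-insensitive).
#' @return named list per element; each element is a list of shells with
#'   fields `l`, `alpha`, `coef` (raw contraction coefficients).
#' @export
load_basis <- function(name) {
  file <- system.file("extdata", "basis",
                      paste0(tolower(name), ".txt"), package = "scqedhf")
  if (!nzchar(file)) stop("unknown basis set: ", name)
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  out <- list()
  i <- 1
  lmap <- c(S = 0L, P = 1L, D = 2L, F = 3L)
  while (i <= length(lines)) {
    tk <- strsplit(lines[i], "\\s+")[[1]]
    if (tolower(tk[1]) != "element") stop("basis parse error near: ", lines[i])
    el <- tk[2]
    i <- i + 1
    shells <- list()
    while (tolower(lines[i]) != "end") {
      hd <- strsplit(lines[i], "\\s+")[[1]]
      type <- toupper(hd[1])
      np <- as.integer(hd[2])
      rows <- do.call(rbind, lapply(lines[i + seq_len(np)], function(l) {
        as.numeric(strsplit(l, "\\s+")[[1]])
      }))
      i <- i + np + 1
      if (type == "SP") {
        shells[[length(shells) + 1]] <-
          list(l = 0L, alpha = rows[, 1], coef = rows[, 2])
        shells[[length(shells) + 1]] <-
          list(l = 1L, alpha = rows[, 1], coef = rows[, 3])
      } else {
        shells[[length(shells) + 1]] <-
          list(l = lmap[[type]], alpha = rows[, 1], coef = rows[, 2])
      }
    }
    i <- i + 1
    out[[el]] <- shells
  }
  out
}

# Normalize a shell: scale primitive coefficients by the (l,0,0) primitive
# norm, then normalize the contracted (l,0,0) function to unit self-overlap.
.normalize_shell <- function(shell) {
  l <- shell$l
  a <- shell$alpha
  c0 <- shell$coef
  nprim <- (2 * a / pi)^0.75 * (4 * a)^(l / 2) / sqrt(.dfact(2 * l - 1))
  cc <- c0 * nprim
  p <- outer(a, a, "+")
  s_ll <- .dfact(2 * l - 1) / (2 * p)^l * (pi / p)^1.5
  norm2 <- sum(outer(cc, cc) * s_ll)
  shell$coef_norm <- cc / sqrt(norm2)
  shell
}

# Build the full shell list for a molecule (centers in bohr).
build_shells <- function(mol, basis_def = NULL) {
  if (is.null(basis_def)) basis_def <- load_basis(mol$basis_name)
  shells <- list()
  for (i in seq_along(mol$atoms)) {
    el <- mol$atoms[i]
    if (is.null(basis_def[[el]])) {
      stop("basis ", mol$basis_name, " has no entry for element ", el)
    }
    for (sh in basis_def[[el]]) {
      sh <- .normalize_shell(sh)
      shells[[length(shells) + 1]] <- list(
        l = sh$l, center = mol$coords[i, ], alpha = sh$alpha,
        coef = sh$coef_norm, atom = i)
    }
  }
  shells
}

# Real-spherical transformation matrix for one shell (ncart x nsph), in the
# shell-normalized Cartesian convention ((l,0,0)-normalized primitives).
# Cartesian order: lx descending then ly descending; spherical order m=-l..l.
.c2s_block <- function(l) {
  if (l == 0) return(matrix(1, 1, 1))
  if (l == 1) return(diag(3))  # order x, y, z
  if (l == 2) {
    # cart: xx, xy, xz, yy, yz, zz ; sph: m = -2, -1, 0, 1, 2
    s3 <- sqrt(3)
    m <- matrix(0, 6, 5)
    m[2, 1] <- s3                 # xy
    m[5, 2] <- s3                 # yz
    m[1, 3] <- -0.5; m[4, 3] <- -0.5; m[6, 3] <- 1  # (2zz - xx - yy)/2
    m[3, 4] <- s3                 # xz
    m[1, 5] <- s3 / 2; m[4, 5] <- -s3 / 2           # (xx - yy) sqrt(3)/2
    return(m)
  }
  stop("spherical transformation implemented up to l = 2")
}

# Block-diagonal cartesian -> spherical matrix for a shell list.
c2s_matrix <- function(shells, spherical = TRUE) {
  ncart <- sum(vapply(shells, function(s) (s$l + 1) * (s$l + 2) / 2, 1))
  if (!spherical) return(diag(ncart))
  blocks <- lapply(shells, function(s) {
    if (s$l <= 1) diag((s$l + 1) * (s$l + 2) / 2) else .c2s_block(s$l)
  })
  nsph <- sum(vapply(blocks, ncol, 1L))
  m <- matrix(0, ncart, nsph)
  ri <- ci <- 0
  for (b in blocks) {
    m[ri + seq_len(nrow(b)), ci + seq_len(ncol(b))] <- b
    ri <- ri + nrow(b)
    ci <- ci + ncol(b)
  }
  m
}

n_basis_functions <- function(shells, spherical = TRUE) {
  if (spherical) {
    sum(vapply(shells, function(s) 2 * s$l + 1, 1))
  } else {
    sum(vapply(shells, function(s) (s$l + 1) * (s$l + 2) / 2, 1))
  }
}
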
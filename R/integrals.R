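# AO integral layer: one fixed contract between the molecule definition and
# the rest of the package. Everything downstream consumes the returned list
# and never talks to the integral engine directly, so the engine could be
# swapped without touching any physics code.

#' Compute all AO integrals for a molecule
#'
#' Returns overlap, core Hamiltonian (kinetic + nuclear attraction),
#' electron-repulsion tensor in chemists' notation, the three electronic
#' dipole component matrices, the nuclear dipole vector and the nuclear
#' repulsion energy, all in atomic units over (spherical) contracted
#' Gaussians.
#'
#' The electronic dipole matrices follow the physics sign convention
#' `d^e_pq = -<p| r |q>` (electron charge -1), so the total molecular dipole
#' expectation is `tr(D d^e) + d_nuc`.
#'
#' @param mol a [molecule()] object.
#' @return list with `S`, `hcore`, `eri` (4-d array), `dip` (list of 3
#'   matrices), `d_nuc`, `e_nuc`, `nbf`, and the shell list used.
#' @export
ao_integrals <- function(mol) {
  shells <- build_shells(mol)
  coords <- mol$coords
  charges <- atomic_number(mol$atoms)
  one <- .cpp_one_electron(shells, coords, as.numeric(charges))
  Tm <- c2s_matrix(shells)
  S <- crossprod(Tm, one$S %*% Tm)
  H <- crossprod(Tm, (one$T + one$V) %*% Tm)
  dip <- lapply(list(one$dx, one$dy, one$dz), function(m) {
    -crossprod(Tm, m %*% Tm)  # electronic dipole: charge -1
  })
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-9) {
    stop("AO overlap is near-singular (min eigenvalue ", format(min(ev)),
         "); basis too linearly dependent for this geometry")
  }
  g_cart <- .cpp_eri(shells)
  g <- .transform_eri_basis(g_cart, Tm)
  S <- (S + t(S)) / 2
  H <- (H + t(H)) / 2
  list(S = S, hcore = H, eri = g,
       dip = lapply(dip, function(m) (m + t(m)) / 2),
       d_nuc = nuclear_dipole(mol), e_nuc = nuclear_repulsion(mol),
       nbf = ncol(Tm), shells = shells)
}

# Transform a 4-index tensor g[pqrs] by the same matrix on every index:
# g'[ijkl] = sum_pqrs C[p,i]C[q,j]C[r,k]C[s,l] g[pqrs].
# Implemented as four quarter transforms through BLAS matrix products.
.transform_eri_basis <- function(g, C) {
  n <- nrow(C)
  m <- ncol(C)
  x <- g
  for (k in 1:4) {
    dim(x) <- c(n, length(x) / n)  # leading index is the next untransformed
    x <- t(crossprod(C, x))        # transform it, rotate to the back
  }
  dim(x) <- rep(m, 4)
  x
}
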
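# Plain restricted Hartree-Fock in the AO basis (Roothaan-Hall + DIIS).
# Used as the lambda = 0 reference/oracle and to seed the cavity
# calculations with converged field-free orbitals. Deliberately independent
# of the dipole-basis SC-QED-HF code paths.

#' Restricted Hartree-Fock
#'
#' Textbook closed-shell SCF: Roothaan-Hall diagonalization with DIIS
#' acceleration on the AO Fock matrix (commutator FDS - SDF error vector).
#'
#' @param mol a [molecule()] object.
#' @param ints optional precomputed [ao_integrals()].
#' @param conv convergence threshold on the DIIS error and energy change.
#' @param max_iter iteration cap.
#' @return list with `energy`, `C` (AO MO coefficients), `orbital_energies`,
#'   `D` (AO density), `converged`, `iterations`.
#' @export
rhf <- function(mol, ints = NULL, conv = 1e-10, max_iter = 200) {
  if (is.null(ints)) ints <- ao_integrals(mol)
  n <- ints$nbf
  nocc <- mol$n_electrons %/% 2L
  S <- ints$S
  H <- ints$hcore
  X <- .inv_sqrt(S)
  gm <- matrix(ints$eri, n * n, n * n)
  gk <- aperm(ints$eri, c(1L, 4L, 3L, 2L))
  dim(gk) <- c(n * n, n * n)
  D <- matrix(0, n, n)
  E_old <- 0
  buf <- diis_buffer(8L)
  converged <- FALSE
  C <- NULL
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    F <- H + matrix(gm %*% as.vector(D), n, n) -
      0.5 * matrix(gk %*% as.vector(D), n, n)
    err <- F %*% D %*% S - S %*% D %*% F
    err <- crossprod(X, err %*% X)
    buf <- diis_push(buf, as.vector(F), as.vector(err))
    F <- matrix(diis_extrapolate(buf), n, n)
    Fp <- crossprod(X, F %*% X)
    es <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(es$values)
    C <- X %*% es$vectors[, ord, drop = FALSE]
    eps <- es$values[ord]
    D <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    Fc <- H + matrix(gm %*% as.vector(D), n, n) -
      0.5 * matrix(gk %*% as.vector(D), n, n)
    E <- 0.5 * sum(D * (H + Fc)) + ints$e_nuc
    if (abs(E - E_old) < conv && max(abs(err)) < max(1e-9, conv)) {
      converged <- TRUE
      E_old <- E
      break
    }
    E_old <- E
  }
  list(energy = E_old, C = C, orbital_energies = eps, D = D,
       converged = converged, iterations = it)
}
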
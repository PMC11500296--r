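# Photon-Fock-space exact-diagonalization oracle.
#
# For tiny electronic spaces (at most 4 spin orbitals, e.g. H2 in a minimal
# basis) the full polaritonic Hamiltonian — electronic Hamiltonian, photon
# number operator, bilinear coupling and dipole self-energy — is built
# explicitly in the (second-quantized fermion Fock space) x (photon number)
# product basis and diagonalized. Completely independent of the mean-field
# code paths: operators are assembled from their definitions via
# Jordan-Wigner matrices, not from any SC-QED-HF machinery.

# Jordan-Wigner annihilation operators for nso spin orbitals (2^nso dim)
.jw_ops <- function(nso) {
  a1 <- matrix(c(0, 0, 1, 0), 2, 2)  # annihilator: a |1> = |0>
  Z <- diag(c(1, -1))
  I2 <- diag(2)
  lapply(seq_len(nso), function(p) {
    m <- matrix(1, 1, 1)
    for (q in seq_len(nso)) {
      m <- kronecker(m, if (q < p) Z else if (q == p) a1 else I2)
    }
    m
  })
}

# number operator eigenvalues on the fermion Fock space diagonal
.jw_occupations <- function(nso) {
  occ <- matrix(0L, 2^nso, nso)
  for (i in seq_len(2^nso)) {
    bits <- as.integer(intToBits(i - 1L))[seq_len(nso)]
    occ[i, ] <- bits
  }
  occ
}

#' Exact polariton ground state (tiny systems)
#'
#' Lowest eigenvalue of the full length-gauge single-mode Pauli-Fierz
#' Hamiltonian (electronic Hamiltonian + omega b'b + bilinear coupling +
#' dipole self-energy + nuclear terms) in the explicit (determinant) x
#' (photon number) basis, converged with respect to the photon cutoff. Only
#' systems with at most 4 spin orbitals are accepted: the oracle exists to
#' validate the Hamiltonian terms and the variational bound, not to scale.
#'
#' @param mol a [molecule()] (at most 2 spatial basis functions).
#' @param cav a [cavity()].
#' @param n_max photon number cutoff.
#' @param ints optional precomputed [ao_integrals()].
#' @return list with `energy` (ground-state energy, hartree), `n_max`.
#' @export
exact_polariton_ground_state <- function(mol, cav, n_max = 10, ints = NULL) {
  if (is.null(ints)) ints <- ao_integrals(mol)
  nspat <- ints$nbf
  nso <- 2L * nspat
  if (nso > 4L) {
    stop("Fock-space oracle is restricted to at most 4 spin orbitals (got ",
         nso, "); it validates physics on tiny systems only")
  }
  nel <- mol$n_electrons
  # orthonormal spatial basis (symmetric orthogonalization)
  X <- .inv_sqrt(ints$S)
  hs <- crossprod(X, ints$hcore %*% X)
  gs <- .transform_eri_basis(ints$eri, X)
  ds <- crossprod(X, dip_projected(ints, cav$polarization) %*% X)
  c_nuc <- sum(ints$d_nuc * cav$polarization)

  ops <- .jw_ops(nso)           # spin orbitals ordered (1a, 1b, 2a, 2b, ...)
  so_spat <- rep(seq_len(nspat), each = 2L)
  dim_f <- 2^nso
  Hel <- matrix(0, dim_f, dim_f)
  Dop <- matrix(0, dim_f, dim_f)
  # one-electron part and dipole operator
  for (p in seq_len(nso)) {
    for (q in seq_len(nso)) {
      if (p %% 2L != q %% 2L) next  # same spin only
      cpq <- crossprod(ops[[p]], ops[[q]])  # a_p^dagger a_q
      Hel <- Hel + hs[so_spat[p], so_spat[q]] * cpq
      Dop <- Dop + ds[so_spat[p], so_spat[q]] * cpq
    }
  }
  # two-electron part: 1/2 sum g_pqrs (E_pq E_rs - delta_qr E_ps)
  for (p in seq_len(nso)) {
    for (q in seq_len(nso)) {
      if (p %% 2L != q %% 2L) next
      cpq <- crossprod(ops[[p]], ops[[q]])
      for (r in seq_len(nso)) {
        for (s in seq_len(nso)) {
          if (r %% 2L != s %% 2L) next
          gval <- gs[so_spat[p], so_spat[q], so_spat[r], so_spat[s]]
          if (gval == 0) next
          crs <- crossprod(ops[[r]], ops[[s]])
          term <- cpq %*% crs
          if (q == r) term <- term - crossprod(ops[[p]], ops[[s]])
          Hel <- Hel + 0.5 * gval * term
        }
      }
    }
  }
  # restrict to the n-electron sector
  occ <- .jw_occupations(nso)
  sel <- which(rowSums(occ) == nel)
  Hel <- Hel[sel, sel, drop = FALSE]
  Dtot <- Dop[sel, sel, drop = FALSE] + diag(c_nuc, length(sel))

  nph <- n_max + 1L
  bmat <- matrix(0, nph, nph)
  for (i in seq_len(n_max)) bmat[i, i + 1L] <- sqrt(i)
  nb <- crossprod(bmat)                     # b' b
  xph <- bmat + t(bmat)                     # b + b'
  Iel <- diag(length(sel))
  Iph <- diag(nph)
  H <- kronecker(Iph, Hel) +
    cav$omega * kronecker(nb, Iel) +
    sqrt(cav$omega / 2) * cav$lambda * kronecker(xph, Dtot) +
    0.5 * cav$lambda^2 * kronecker(Iph, Dtot %*% Dtot) +
    ints$e_nuc * diag(length(sel) * nph)
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(energy = min(ev), n_max = n_max)
}

#' Cutoff-converged polariton ground state
#'
#' Increases the photon number cutoff until the ground-state energy changes
#' by less than `tol` between successive increments.
#'
#' @inheritParams exact_polariton_ground_state
#' @param tol convergence tolerance on the ground-state energy.
#' @param start,step initial cutoff and increment.
#' @return list with `energy`, `n_max` (the converged cutoff).
#' @export
exact_polariton_converged <- function(mol, cav, tol = 1e-10, start = 4L,
                                      step = 2L, ints = NULL) {
  if (is.null(ints)) ints <- ao_integrals(mol)
  n_max <- start
  e_old <- exact_polariton_ground_state(mol, cav, n_max, ints)$energy
  repeat {
    n_max <- n_max + step
    e_new <- exact_polariton_ground_state(mol, cav, n_max, ints)$energy
    if (abs(e_new - e_old) < tol || n_max > 40L) break
    e_old <- e_new
  }
  list(energy = e_new, n_max = n_max)
}
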
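# SC-QED-HF core: dipole basis, eta-dressed integrals, energy, Fock matrix
# and the kappa / eta gradients.
#
# Working representation. All electronic quantities live in the "dipole
# basis": the orthonormal orbital basis that diagonalizes the projected
# electronic dipole (d.eps). Because that basis diagonalizes a fixed AO-space
# operator, it does not depend on the current MOs; the orbital state is an
# orthogonal matrix W whose columns are the MOs expressed in the dipole
# basis (first nocc columns occupied), and the closed-shell density there is
# D = 2 W_occ W_occ^T.
#
# Energy functional (closed shell, spin-summed), with s = lambda^2/(4 omega),
# u_pq = eta_p - eta_q, Delta_pqrs = u_pq + u_rs, delta_p = d_pp - eta_p and
# c = d_nuc . eps:
#   E = sum_pq  h_pq exp(-s u_pq^2) D_pq
#     + 1/2 sum_pqrs g_pqrs exp(-s Delta^2) (D_pq D_rs - 1/2 D_ps D_rq)
#     + lambda^2/2 < (d.eps - sum_p eta_p E_pp)^2 >_HF  + E_nuc
# The last term (photon displacement mismatch / dipole self-energy) expands
# into effective one- and two-electron integrals diagonal in the dipole
# basis, so the whole functional is an ordinary restricted HF energy with
# eta-dependent effective integrals h_eff(eta), g_eff(eta). The photonic
# Hilbert space never appears explicitly: all photon expectation values are
# the analytic Gaussian factors above.

#' Build the dipole basis
#'
#' Finds the orthogonal transformation `V` from a given orthonormal MO basis
#' to the basis diagonalizing the MO representation of the projected dipole
#' operator (d.eps), together with the eigenvalues (diagonal dipole values),
#' sorted ascending. The eigenvector sign is fixed deterministically (the
#' largest-magnitude component of each column is made positive); exact
#' degeneracies are resolved by the secondary ordering that `eigen` induces
#' plus the sign fix, which is deterministic for a fixed input.
#'
#' @param mo_coeff AO-basis MO coefficient matrix (columns orthonormal
#'   w.r.t. `S`).
#' @param ao_ints result of [ao_integrals()].
#' @param cav a [cavity()] object (supplies the polarization).
#' @return list with `V` (orthogonal), `d_diag` (ascending eigenvalues),
#'   `mo_coeff`.
#' @export
build_dipole_basis <- function(mo_coeff, ao_ints, cav) {
  S <- ao_ints$S
  ortho_err <- max(abs(crossprod(mo_coeff, S %*% mo_coeff) -
                         diag(ncol(mo_coeff))))
  if (ortho_err > 1e-8) {
    stop("mo_coeff is not orthonormal w.r.t. the AO overlap (error ",
         format(ortho_err), ")")
  }
  dmat <- dip_projected(ao_ints, cav$polarization)
  dmo <- crossprod(mo_coeff, dmat %*% mo_coeff)
  dmo <- (dmo + t(dmo)) / 2
  es <- eigen(dmo, symmetric = TRUE)
  ord <- order(es$values)
  V <- es$vectors[, ord, drop = FALSE]
  V <- .fix_sign(V)
  list(V = V, d_diag = es$values[ord], mo_coeff = mo_coeff)
}

# projected electronic dipole matrix in the AO basis
dip_projected <- function(ao_ints, eps) {
  eps[1] * ao_ints$dip[[1]] + eps[2] * ao_ints$dip[[2]] +
    eps[3] * ao_ints$dip[[3]]
}

.fix_sign <- function(V) {
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Assemble the fixed data for an SC-QED-HF calculation
#'
#' Computes AO integrals, constructs the dipole basis over the orthonormalized
#' AO space and transforms the one- and two-electron integrals into it. All
#' downstream optimization works on this object plus a state (W, eta).
#'
#' @param mol a [molecule()] object.
#' @param cav a [cavity()] object.
#' @param max_nbf guard for the in-memory N^4 two-electron tensors; systems
#'   with more basis functions abort with a pointer to the (not implemented)
#'   Cholesky batching hook.
#' @return object of class `"scqed_system"`.
#' @export
scqed_system <- function(mol, cav, max_nbf = 200) {
  ints <- ao_integrals(mol)
  n <- ints$nbf
  if (n > max_nbf) {
    stop("system has ", n, " basis functions; the dense in-memory ",
         "two-electron path is limited to ", max_nbf,
         ". Batching of Cholesky-decomposed integrals is a known extension ",
         "hook, not implemented here.")
  }
  # dipole basis as eigenbasis of the generalized problem  d C = S C diag
  X <- .inv_sqrt(ints$S)
  dmat <- dip_projected(ints, cav$polarization)
  M <- crossprod(X, dmat %*% X)
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)
  ord <- order(es$values)
  Ct <- .fix_sign(X %*% es$vectors[, ord, drop = FALSE])
  d_diag <- es$values[ord]
  h <- crossprod(Ct, ints$hcore %*% Ct)
  h <- (h + t(h)) / 2
  g <- .transform_eri_basis(ints$eri, Ct)
  structure(list(
    mol = mol, cavity = cav, n = n, nocc = mol$n_electrons %/% 2L,
    e_nuc = ints$e_nuc, c_nuc = sum(ints$d_nuc * cav$polarization),
    Ct = Ct, d_diag = d_diag, h = h, g = g,
    s_exp = cav$lambda^2 / (4 * cav$omega),
    ao = ints[c("S", "hcore", "dip", "d_nuc")]), class = "scqed_system")
}

.inv_sqrt <- function(S) {
  es <- eigen(S, symmetric = TRUE)
  es$vectors %*% (t(es$vectors) / sqrt(es$values))
}

#' Dress the integrals with the coherent-state Gaussian factors
#'
#' Scales the dipole-basis one- and two-electron integrals by the
#' omega-dependent Gaussian factors exp(-lambda^2 (eta_p - eta_q)^2 / (4
#' omega)) and exp(-lambda^2 (eta_p - eta_q + eta_r - eta_s)^2 / (4 omega)),
#' and folds the dipole self-energy terms into effective integrals, so the
#' energy is an ordinary RHF functional of the density in the dipole basis.
#'
#' @param sys a [scqed_system()].
#' @param eta numeric vector of orbital-specific coherent-state parameters,
#'   one per (spatial) dipole-basis orbital.
#' @return object of class `"scqed_dressing"`: `G1` (one-electron factor
#'   matrix), `h_eff`, `gm` and `gk` (N^2 x N^2 views of the effective
#'   two-electron tensor for Coulomb and exchange builds), `eta`, `delta`.
#' @export
dress_integrals <- function(sys, eta) {
  n <- sys$n
  if (length(eta) != n) stop("eta must have one entry per orbital")
  if (sys$cavity$omega <= 0) stop("cavity frequency must be positive")
  s <- sys$s_exp
  lam2 <- sys$cavity$lambda^2
  u <- outer(eta, eta, "-")
  G1 <- exp(-s * u^2)
  delta <- sys$d_diag - eta
  h_eff <- sys$h * G1
  diag(h_eff) <- diag(h_eff) + 0.5 * lam2 * delta^2 + lam2 * sys$c_nuc * delta
  if (lam2 == 0) {
    geff <- sys$g
  } else {
    a <- as.vector(u)
    Delta <- outer(a, a, "+")
    G2 <- exp(-s * Delta * Delta)
    geff <- matrix(as.vector(sys$g) * as.vector(G2), n * n, n * n)
    rm(G2, Delta)
    # dipole self-energy two-electron part: (pp|rr) += lambda^2 delta_p delta_r
    dd <- seq(1L, n * n, by = n + 1L)
    geff[dd, dd] <- geff[dd, dd] + lam2 * outer(delta, delta)
  }
  dim(geff) <- rep(n, 4)
  gk <- aperm(geff, c(1L, 4L, 3L, 2L))  # [p,q,r,s] -> (ps|rq) view
  dim(geff) <- c(n * n, n * n)
  dim(gk) <- c(n * n, n * n)
  structure(list(eta = eta, G1 = G1, u = u, h_eff = h_eff,
                 gm = geff, gk = gk, delta = delta),
            class = "scqed_dressing")
}

# closed-shell density in the dipole basis from the orbital state
density_from_W <- function(sys, W) {
  occ <- W[, seq_len(sys$nocc), drop = FALSE]
  2 * tcrossprod(occ)
}

# Coulomb and exchange builds with the effective (dressed) integrals
jk_build <- function(dress, D) {
  n <- nrow(D)
  J <- matrix(dress$gm %*% as.vector(D), n, n)
  K <- matrix(dress$gk %*% as.vector(D), n, n)
  list(J = (J + t(J)) / 2, K = (K + t(K)) / 2)
}

#' SC-QED-HF energy
#'
#' Total energy of the normalized strong-coupling ansatz at the given
#' orbital state and eta parameters: dressed one- and two-electron terms,
#' dipole self-energy (including the nuclear-dipole cross terms that make
#' the functional origin invariant once eta relaxes), and nuclear repulsion.
#'
#' @param sys a [scqed_system()].
#' @param W orthogonal orbital matrix in the dipole basis (columns = MOs,
#'   first nocc occupied).
#' @param eta coherent-state parameter vector.
#' @param dress optional precomputed [dress_integrals()] result for `eta`.
#' @return total energy in hartree.
#' @export
scqed_energy <- function(sys, W, eta, dress = NULL) {
  if (is.null(dress)) dress <- dress_integrals(sys, eta)
  D <- density_from_W(sys, W)
  jk <- jk_build(dress, D)
  sum(dress$h_eff * D) + 0.5 * sum(D * jk$J) - 0.25 * sum(D * jk$K) +
    sys$e_nuc + 0.5 * sys$cavity$lambda^2 * sys$c_nuc^2
}

#' SC-QED Fock matrix in the dipole basis
#'
#' The derivative of the energy with respect to the dipole-basis density,
#' i.e. the effective-integral RHF Fock matrix F = h_eff + J(D) - K(D)/2.
#'
#' @inheritParams scqed_energy
#' @param D optional density matrix (computed from `W` if missing).
#' @return symmetric Fock matrix in the dipole basis.
#' @export
fock_dipole_basis <- function(sys, W, eta, dress = NULL, D = NULL) {
  if (is.null(dress)) dress <- dress_integrals(sys, eta)
  if (is.null(D)) D <- density_from_W(sys, W)
  jk <- jk_build(dress, D)
  dress$h_eff + jk$J - 0.5 * jk$K
}

#' Orbital-rotation (kappa) gradient
#'
#' Gradient of the energy with respect to the nonredundant occupied-virtual
#' rotation generators kappa_ai, evaluated at kappa = 0 in the current MO
#' basis: g_ai = 4 (W^T F W)_ai.
#'
#' @inheritParams scqed_energy
#' @param fock optional precomputed Fock matrix in the dipole basis.
#' @return matrix (nvirt x nocc) of gradient components.
#' @export
kappa_gradient <- function(sys, W, eta, dress = NULL, fock = NULL) {
  if (is.null(fock)) fock <- fock_dipole_basis(sys, W, eta, dress)
  fmo <- crossprod(W, fock %*% W)
  no <- sys$nocc
  4 * fmo[-seq_len(no), seq_len(no), drop = FALSE]
}

#' Coherent-state parameter (eta) gradient
#'
#' Analytic derivative of the energy with respect to each eta_p: Gaussian-
#' factor derivatives of the dressed one- and two-electron terms plus the
#' dipole self-energy contributions. At lambda = 0 the energy does not
#' depend on eta and the gradient vanishes identically.
#'
#' @inheritParams scqed_energy
#' @return numeric vector of length n (orbital count).
#' @export
eta_gradient <- function(sys, W, eta, dress = NULL) {
  n <- sys$n
  lam2 <- sys$cavity$lambda^2
  if (lam2 == 0) return(numeric(n))
  if (is.null(dress)) dress <- dress_integrals(sys, eta)
  s <- sys$s_exp
  D <- density_from_W(sys, W)
  # one-electron dressing derivative
  M1 <- sys$h * D * dress$G1 * (-2 * s) * dress$u
  g1 <- 2 * rowSums(M1)
  # two-electron dressing derivative (contract over q,r,s for each first index)
  a <- as.vector(dress$u)
  Delta <- outer(a, a, "+")
  Pt <- .pair_density(D)
  TT <- as.vector(sys$g) * as.vector(Delta) * as.vector(Pt)
  rm(Delta)
  G2v <- .g2_factor(s, dress$u)
  TT <- TT * G2v
  dim(TT) <- c(n, n^3)
  g2 <- -4 * s * rowSums(TT)
  rm(TT)
  # dipole self-energy derivative
  delta <- dress$delta
  Pi <- outer(diag(D), diag(D)) - 0.5 * D^2
  gdse <- -lam2 * (as.vector(Pi %*% delta) + delta * diag(D) +
                     sys$c_nuc * diag(D))
  g1 + g2 + gdse
}

# pair density P_pqrs = D_pq D_rs - 1/2 D_ps D_rq as an N^2 x N^2 matrix
.pair_density <- function(D) {
  n <- nrow(D)
  P <- outer(as.vector(D), as.vector(D))
  X <- aperm(outer(D, D), c(1L, 4L, 3L, 2L))  # [p,q,r,s] = D_ps D_rq
  dim(X) <- c(n * n, n * n)
  P - 0.5 * X
}

# two-electron Gaussian factor as a plain vector (length n^4)
.g2_factor <- function(s, u) {
  a <- as.vector(u)
  Delta <- outer(a, a, "+")
  v <- exp(-s * as.vector(Delta)^2)
  v
}

#' Convert AO-basis MOs to the dipole-basis orbital state
#'
#' @param sys a [scqed_system()].
#' @param C_ao AO-basis MO coefficients (orthonormal w.r.t. the AO overlap).
#' @return orthogonal matrix W with columns = MOs in the dipole basis.
#' @export
W_from_ao_mos <- function(sys, C_ao) {
  W <- crossprod(sys$Ct, sys$ao$S %*% C_ao)
  # clean up to exact orthogonality
  sv <- svd(W)
  sv$u %*% t(sv$v)
}
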
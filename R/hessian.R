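# Second-order machinery: matrix-free Hessian linear transformations for the
# kappa-kappa and eta-eta blocks (optionally the mixed blocks), the dense
# eta-eta Hessian, and the Fock-difference diagonal preconditioner.
#
# All transformations are expressed through gradient-style contractions:
# Fock builds of transformed densities for kappa-kappa, and first-index
# contractions of factor-weighted integral tensors for eta-eta, so no
# explicit Hessian tensor is ever formed.

# occupied projector helper
.occ_proj <- function(n, nocc) {
  p <- numeric(n)
  p[seq_len(nocc)] <- 1
  diag(p)
}

.kappa_full <- function(vkappa, n, nocc) {
  K <- matrix(0, n, n)
  K[(nocc + 1):n, seq_len(nocc)] <- vkappa
  K[seq_len(nocc), (nocc + 1):n] <- -t(vkappa)
  K
}

#' kappa-kappa Hessian linear transformation
#'
#' Applies the orbital-rotation block of the electronic Hessian to a trial
#' rotation, evaluated at kappa = 0 in the current MO basis, through two
#' gradient-like ingredients: commutators with the MO Fock matrix and one
#' Fock-type build from the first-order (transition) density. Valid at
#' non-stationary points (the occupied-virtual Fock block enters).
#'
#' @param sys a [scqed_system()].
#' @param W orbital state (orthogonal matrix in the dipole basis).
#' @param eta coherent-state parameters.
#' @param vkappa trial rotation, matrix (nvirt x nocc).
#' @param dress optional [dress_integrals()] result.
#' @param fock optional Fock matrix in the dipole basis.
#' @return matrix (nvirt x nocc): Hessian-vector product components.
#' @export
lt_kappa_kappa <- function(sys, W, eta, vkappa, dress = NULL, fock = NULL) {
  n <- sys$n
  no <- sys$nocc
  if (!all(dim(vkappa) == c(n - no, no))) {
    stop("trial vector must be nvirt x nocc")
  }
  if (is.null(dress)) dress <- dress_integrals(sys, eta)
  if (is.null(fock)) fock <- fock_dipole_basis(sys, W, eta, dress)
  fmo <- crossprod(W, fock %*% W)
  K <- .kappa_full(vkappa, n, no)
  P <- .occ_proj(n, no)
  X <- K %*% P - P %*% K            # symmetric first-order density generator
  D1 <- 2 * W %*% X %*% t(W)
  jk <- jk_build(dress, D1)
  Gmo <- crossprod(W, (jk$J - 0.5 * jk$K) %*% W)
  Y <- fmo %*% K - K %*% fmo
  M1 <- (X %*% fmo - fmo %*% X) + (P %*% Y - Y %*% P)
  Hv <- -2 * M1 + 4 * Gmo
  Hv[(no + 1):n, seq_len(no), drop = FALSE]
}

# Per-state cache for eta-eta products: everything that depends on (W, eta)
# but not on the trial vector.
eta_eta_cache <- function(sys, W, eta, dress = NULL) {
  n <- sys$n
  lam2 <- sys$cavity$lambda^2
  D <- density_from_W(sys, W)
  if (lam2 == 0) {
    return(list(zero = TRUE, n = n))
  }
  if (is.null(dress)) dress <- dress_integrals(sys, eta)
  s <- sys$s_exp
  u <- dress$u
  a <- as.vector(u)
  Delta <- outer(a, a, "+")
  G2 <- exp(-s * Delta^2)
  Pt <- .pair_density(D)
  M2 <- matrix(as.vector(sys$g), n * n, n * n) * Pt * G2 *
    (1 - 2 * s * Delta^2)
  rm(G2, Delta, Pt)
  B <- sys$h * D * dress$G1 * (-2 * s) * (1 - 2 * s * u^2)
  Pi <- outer(diag(D), diag(D)) - 0.5 * D^2
  list(zero = FALSE, n = n, s = s, lam2 = lam2, M2 = M2, B = B,
       b = rowSums(B), Pi = Pi, dD = diag(D))
}

#' eta-eta Hessian linear transformation
#'
#' Applies the coherent-state block of the Hessian to a trial vector,
#' matrix-free: the trial vector enters only through the antisymmetrized
#' difference pattern v_p - v_q + v_r - v_s multiplying a cached
#' factor-weighted integral tensor. At lambda = 0 the block vanishes.
#'
#' @inheritParams lt_kappa_kappa
#' @param veta trial vector (length n).
#' @param cache optional [eta_eta_cache()] for the current state.
#' @return numeric vector of length n.
#' @export
lt_eta_eta <- function(sys, W, eta, veta, dress = NULL, cache = NULL) {
  n <- sys$n
  if (length(veta) != n) stop("trial vector must have length n")
  if (sys$cavity$lambda == 0) return(numeric(n))
  if (is.null(cache)) cache <- eta_eta_cache(sys, W, eta, dress)
  w <- as.vector(outer(veta, veta, "-"))
  Vc <- outer(w, w, "+")
  TT <- cache$M2 * Vc
  dim(TT) <- c(n, n^3)
  hv2 <- -4 * cache$s * rowSums(TT)
  hv1 <- 2 * cache$b * veta - 2 * as.vector(cache$B %*% veta)
  hvd <- cache$lam2 * (as.vector(cache$Pi %*% veta) + cache$dD * veta)
  hv1 + hv2 + hvd
}

#' Dense eta-eta Hessian block
#'
#' Builds the full (n x n) eta-eta Hessian by partial traces of the same
#' cached factor-weighted integral tensor used by [lt_eta_eta()] (an
#' independent contraction path, used to cross-check the matrix-free
#' transformation and for the direct-inversion optimizer). Reuses the
#' already dressed integrals; cost N^4.
#'
#' @inheritParams lt_eta_eta
#' @return symmetric n x n matrix.
#' @export
build_dense_eta_eta <- function(sys, W, eta, dress = NULL, cache = NULL) {
  n <- sys$n
  if (sys$cavity$lambda == 0) return(matrix(0, n, n))
  if (is.null(cache)) cache <- eta_eta_cache(sys, W, eta, dress)
  B4 <- -cache$s * cache$M2          # = 1/2 * (-2s) * weighted tensor
  dim(B4) <- rep(n, 4)
  s1 <- rowSums(matrix(B4, n, n^3))
  a_tu <- matrix(rowSums(matrix(B4, n^2, n^2)), n, n)
  Tm <- aperm(B4, c(1L, 3L, 2L, 4L))   # [p,r,q,s]
  dim(Tm) <- c(n^2, n^2)
  T_tu <- matrix(rowSums(Tm), n, n)
  Um <- aperm(B4, c(1L, 4L, 2L, 3L))   # [p,s,q,r]
  dim(Um) <- c(n^2, n^2)
  U_tu <- matrix(rowSums(Um), n, n)
  H2 <- 4 * diag(s1) - 4 * a_tu + 4 * T_tu - 2 * (U_tu + t(U_tu))
  H1 <- 2 * diag(cache$b) - 2 * cache$B
  Hd <- cache$lam2 * (cache$Pi + diag(cache$dD))
  H <- H1 + H2 + Hd
  (H + t(H)) / 2
}

#' Mixed kappa-eta / eta-kappa Hessian blocks
#'
#' Applies the coupling blocks of the Hessian to a trial vector with kappa
#' and eta parts. The kappa output receives the eta-derivative of the Fock
#' matrix contracted with the orbital basis; the eta output receives the
#' eta-derivative integrals contracted with the first-order density. Both
#' are exact second derivatives, verified against finite differences; they
#' are disabled by default in the optimizers.
#'
#' @inheritParams lt_kappa_kappa
#' @param vkappa trial kappa part (nvirt x nocc).
#' @param veta trial eta part (length n).
#' @return list with `kappa` (nvirt x nocc, from the kappa-eta block) and
#'   `eta` (length n, from the eta-kappa block).
#' @export
lt_mixed <- function(sys, W, eta, vkappa, veta, dress = NULL) {
  n <- sys$n
  no <- sys$nocc
  lam2 <- sys$cavity$lambda^2
  if (lam2 == 0) {
    return(list(kappa = matrix(0, n - no, no), eta = numeric(n)))
  }
  if (is.null(dress)) dress <- dress_integrals(sys, eta)
  s <- sys$s_exp
  u <- dress$u
  D <- density_from_W(sys, W)
  delta <- dress$delta

  # eta-derivative of the effective one-electron integrals, contracted with
  # the trial eta vector: dh[v]_pq
  dh <- sys$h * dress$G1 * (-2 * s) * u * outer(veta, veta, "-")
  dh <- dh + diag(-lam2 * (delta + sys$c_nuc) * veta)

  # eta-derivative of the effective two-electron tensor along v:
  #   dgv = g * G2 * (-2 s) * Delta * (v_p - v_q + v_r - v_s)  + DSE part
  a <- as.vector(u)
  Delta <- outer(a, a, "+")
  G2 <- exp(-s * Delta^2)
  w <- as.vector(outer(veta, veta, "-"))
  Vc <- outer(w, w, "+")
  dgv <- matrix(as.vector(sys$g), n * n, n * n) * G2 * (-2 * s) * Delta * Vc
  rm(G2, Delta, Vc)
  dd <- seq(1L, n * n, by = n + 1L)
  dgv[dd, dd] <- dgv[dd, dd] -
    lam2 * (outer(veta * rep(1, n)^0, delta) + outer(delta, veta))
  # ^ d(delta_p delta_r)/deta along v = -(v_p delta_r + delta_p v_r)

  # kappa output: 4 * (W^T F'[v] W)_vo with F'[v] = dh + J' - K'/2 over D
  dgv4 <- dgv
  dim(dgv4) <- rep(n, 4)
  Jp <- matrix(dgv %*% as.vector(D), n, n)
  gkv <- aperm(dgv4, c(1L, 4L, 3L, 2L))
  dim(gkv) <- c(n^2, n^2)
  Kp <- matrix(gkv %*% as.vector(D), n, n)
  Fp <- dh + Jp - 0.5 * Kp
  Fp <- (Fp + t(Fp)) / 2
  fmo <- crossprod(W, Fp %*% W)
  out_kappa <- 4 * fmo[(no + 1):n, seq_len(no), drop = FALSE]

  # eta output: Tr(dF/deta_t D1) for all t, with D1 the first-order density
  K <- .kappa_full(vkappa, n, no)
  P <- .occ_proj(n, no)
  X <- K %*% P - P %*% K
  D1 <- 2 * W %*% X %*% t(W)
  # one-electron + DSE-diagonal parts
  dh_t <- sys$h * dress$G1 * (-2 * s) * u * D1   # then contract indices
  g1 <- 2 * rowSums(dh_t)
  g1 <- g1 - lam2 * (delta + sys$c_nuc) * diag(D1)
  # two-electron dressing part: contract derivative tensor with the
  # symmetrized mixed pair density over each derivative slot
  Pmix <- .pair_density_mixed(D, D1)
  DG <- matrix(as.vector(sys$g), n * n, n * n) *
    exp(-s * outer(a, a, "+")^2) * (-2 * s) * outer(a, a, "+")
  M <- DG * Pmix
  dim(M) <- rep(n, 4)
  r1 <- rowSums(matrix(M, n, n^3))
  r2 <- rowSums(matrix(aperm(M, c(2L, 1L, 3L, 4L)), n, n^3))
  r3 <- rowSums(matrix(aperm(M, c(3L, 1L, 2L, 4L)), n, n^3))
  r4 <- rowSums(matrix(aperm(M, c(4L, 1L, 2L, 3L)), n, n^3))
  g2 <- r1 - r2 + r3 - r4
  # DSE two-electron part
  Pm4 <- Pmix
  dim(Pm4) <- rep(n, 4)
  pp <- vapply(seq_len(n), function(p) Pm4[p, p, , ], array(0, c(n, n)))
  # pp[r,s,p] = Pmix[p,p,r,s]; need sum_r delta_r (Pmix_ttrr + Pmix_rrtt)
  ppd <- sapply(seq_len(n), function(p) diag(pp[, , p]))  # ppd[r, p] = Pmix[p,p,r,r]
  gdse2 <- -lam2 * (as.vector(t(ppd) %*% delta) + as.vector(ppd %*% delta))
  out_eta <- g1 + g2 + gdse2
  list(kappa = out_kappa, eta = out_eta)
}

# symmetrized mixed pair density: Q(D, D1) cross term
# Pmix_pqrs = D1_pq D_rs - 1/2 D1_ps D_rq   (as N^2 x N^2 matrix)
.pair_density_mixed <- function(D, D1) {
  n <- nrow(D)
  P <- outer(as.vector(D1), as.vector(D))
  X <- aperm(outer(D1, D), c(1L, 4L, 3L, 2L))
  dim(X) <- c(n * n, n * n)
  P - 0.5 * X
}

#' Fock-difference diagonal preconditioner for the kappa block
#'
#' The dominant diagonal of the orbital-rotation Hessian, 4 (F_aa - F_ii)
#' in the current MO basis, floored at a small positive constant so it can
#' be used as a conjugate-gradient preconditioner even at non-aufbau or
#' early-iteration states.
#'
#' @inheritParams lt_kappa_kappa
#' @param floor_const positive flooring value.
#' @return matrix (nvirt x nocc) of positive diagonal entries.
#' @export
kk_diagonal_preconditioner <- function(sys, W, eta, dress = NULL,
                                       fock = NULL, floor_const = 1e-3) {
  if (is.null(fock)) fock <- fock_dipole_basis(sys, W, eta, dress)
  fmo <- crossprod(W, fock %*% W)
  no <- sys$nocc
  n <- sys$n
  d <- 4 * outer(diag(fmo)[(no + 1):n], diag(fmo)[seq_len(no)], "-")
  pmax(d, floor_const)
}
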
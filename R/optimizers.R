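# SCF drivers: gradient-based DIIS baseline (gb-DIIS), trust-region
# Newton-Raphson on the concatenated (kappa, eta) parameters (tr-NR), and
# Roothaan-Hall/DIIS with direct inversion of the dense eta-eta Hessian
# block (gb-DBI). All three are deterministic.

#' SCF control parameters
#'
#' @param energy_threshold convergence threshold on |E_i - E_{i-1}| (hartree).
#' @param gradient_threshold threshold on the absolute maximum of the total
#'   gradient vector (a.u.).
#' @param max_iterations macro-iteration cap (`NULL`: per-algorithm default —
#'   50 for tr-NR, 300 for gb-DBI, 2000 for gb-DIIS).
#' @param diis_dim DIIS subspace size.
#' @param eta_step steepest-descent step for eta in gb-DIIS (the baseline is
#'   known to stagnate; smaller steps trade speed for stability).
#' @param trust_radius_init,trust_radius_min,trust_radius_max trust-region
#'   radius start and bounds.
#' @param micro_cap cap on conjugate-gradient micro-iterations per solve.
#' @param mixed_blocks include the kappa-eta coupling blocks of the Hessian
#'   in tr-NR (off by default; they cost more than the iterations they save).
#' @param eta_floor eigenvalue floor for the pseudo-inverse of the dense
#'   eta-eta block in gb-DBI.
#' @return list of class `"scf_control"`.
#' @export
scf_control <- function(energy_threshold = 1e-10,
                        gradient_threshold = 1e-10,
                        max_iterations = NULL,
                        diis_dim = 8L,
                        eta_step = 0.1,
                        trust_radius_init = 2,
                        trust_radius_min = 1e-3,
                        trust_radius_max = 10,
                        micro_cap = 100L,
                        mixed_blocks = FALSE,
                        eta_floor = 1e-8) {
  stopifnot(energy_threshold > 0, gradient_threshold > 0)
  structure(list(energy_threshold = energy_threshold,
                 gradient_threshold = gradient_threshold,
                 max_iterations = max_iterations, diis_dim = diis_dim,
                 eta_step = eta_step,
                 trust_radius_init = trust_radius_init,
                 trust_radius_min = trust_radius_min,
                 trust_radius_max = trust_radius_max,
                 micro_cap = as.integer(micro_cap),
                 mixed_blocks = isTRUE(mixed_blocks),
                 eta_floor = eta_floor),
            class = "scf_control")
}

# exact exponential of an antisymmetric matrix (orbital rotation)
.expm_antisym <- function(K) {
  es <- eigen(1i * K)
  U <- Re(es$vectors %*% diag(exp(-1i * es$values), nrow(K)) %*%
            Conj(t(es$vectors)))
  sv <- svd(U)
  sv$u %*% t(sv$v)
}

#' Per-iteration convergence metrics
#'
#' The diagnostics monitored by all drivers: absolute energy change from the
#' previous iteration, absolute maximum of the total gradient vector, and the
#' L2 norms of the kappa and eta gradients scaled by the number of
#' nonredundant parameters in each class (N_kappa = nocc x nvirt,
#' N_eta = n orbitals).
#'
#' @param energy current total energy (hartree).
#' @param energy_prev previous iteration's energy, or `NA` on the first
#'   iteration (the energy change is then reported as `NA`).
#' @param g_kappa kappa gradient (matrix or vector).
#' @param g_eta eta gradient vector.
#' @return list with `dE`, `max_grad`, `gk_scaled`, `ge_scaled`, `N_kappa`,
#'   `N_eta`.
#' @export
convergence_metrics <- function(energy, energy_prev, g_kappa, g_eta) {
  nk <- length(g_kappa)
  ne <- length(g_eta)
  list(dE = if (is.na(energy_prev)) NA_real_ else abs(energy - energy_prev),
       max_grad = max(abs(c(as.vector(g_kappa), g_eta))),
       gk_scaled = sqrt(sum(g_kappa^2)) / nk,
       ge_scaled = sqrt(sum(g_eta^2)) / ne,
       N_kappa = nk, N_eta = ne)
}

.report_row <- function(it, energy, met, micro = NA_integer_,
                        radius = NA_real_, mu = NA_real_) {
  data.frame(iteration = it, energy = energy, dE = met$dE,
             max_grad = met$max_grad, gk_scaled = met$gk_scaled,
             ge_scaled = met$ge_scaled, micro = micro, radius = radius,
             mu = mu)
}

.is_converged <- function(met, control) {
  !is.na(met$max_grad) && met$max_grad <= control$gradient_threshold &&
    (is.na(met$dE) || met$dE <= control$energy_threshold)
}

# initial state: converged field-free RHF orbitals, eta at the dipole
# operator eigenvalues
.initial_state <- function(sys) {
  hf <- rhf(sys$mol)
  if (!hf$converged) stop("field-free RHF reference did not converge")
  list(W = W_from_ao_mos(sys, hf$C), eta = sys$d_diag, rhf_energy = hf$energy)
}

# semicanonical orbitals at the final state: diagonalize the MO Fock matrix
# within the occupied and virtual blocks separately
.semicanonicalize <- function(sys, W, eta, dress = NULL) {
  fock <- fock_dipole_basis(sys, W, eta, dress)
  fmo <- crossprod(W, fock %*% W)
  no <- sys$nocc
  n <- sys$n
  io <- seq_len(no)
  iv <- setdiff(seq_len(n), io)
  eo <- eigen((fmo[io, io] + t(fmo[io, io])) / 2, symmetric = TRUE)
  ev <- eigen((fmo[iv, iv] + t(fmo[iv, iv])) / 2, symmetric = TRUE)
  ro <- order(eo$values)
  rv <- order(ev$values)
  U <- matrix(0, n, n)
  U[io, io] <- eo$vectors[, ro]
  U[iv, iv] <- ev$vectors[, rv]
  list(W = W %*% U, orbital_energies = c(eo$values[ro], ev$values[rv]))
}

# ---------------------------------------------------------------------------
# preconditioned conjugate gradients for (H + shift I) x = b, matrix-free.
# The preconditioner is either a diagonal (numeric vector) or a function
# factory: precond(shift) returning a function r -> z.
.pcg <- function(apply_H, b, precond, shift, tol, maxit, radius = Inf) {
  x <- numeric(length(b))
  r <- b
  psolve <- if (is.function(precond)) {
    precond(shift)
  } else {
    pd <- pmax(precond + shift, 1e-8)
    function(r) r / pd
  }
  z <- psolve(r)
  p <- z
  rz <- sum(r * z)
  iters <- 0L
  negcurv <- FALSE
  exceeded <- FALSE
  b_norm <- sqrt(sum(b^2))
  if (b_norm == 0) {
    return(list(x = x, iters = 0L, negcurv = FALSE, exceeded = FALSE))
  }
  repeat {
    if (iters >= maxit) break
    Hp <- apply_H(p) + shift * p
    iters <- iters + 1L
    pHp <- sum(p * Hp)
    if (pHp <= 0) {
      negcurv <- TRUE
      break
    }
    alpha <- rz / pHp
    x <- x + alpha * p
    r <- r - alpha * Hp
    if (sqrt(sum(x^2)) > radius) {
      # the step has already left the trust region: no need to refine it,
      # the caller will re-solve with a larger level shift
      exceeded <- TRUE
      break
    }
    if (sqrt(sum(r^2)) <= tol) break
    z <- psolve(r)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  list(x = x, iters = iters, negcurv = negcurv, exceeded = exceeded)
}

#' Solve the level-shifted trust-region Newton equations
#'
#' Computes the step from (E2 - mu I) dz = -E1 matrix-free with
#' preconditioned conjugate gradients. If the unshifted Newton step is
#' positive definite along the probed directions and fits inside the trust
#' radius, mu = 0; otherwise mu < 0 is located by a one-dimensional search
#' so the step lands (approximately) on the trust-region boundary.
#'
#' @param apply_H function mapping a parameter vector to the Hessian-vector
#'   product.
#' @param grad gradient vector E1.
#' @param radius trust radius.
#' @param precond preconditioner: either a numeric vector (approximate
#'   Hessian diagonal) or a function `precond(shift)` returning a function
#'   that applies the inverse preconditioner to a residual vector.
#' @param tol residual tolerance for the micro-solver.
#' @param maxit micro-iteration cap per solve.
#' @param sigma0 optional warm-start value for the positive shift (e.g. the
#'   shift accepted in the previous macro-iteration).
#' @return list with `step`, `mu` (level shift, <= 0), `micro` (total
#'   micro-iterations across all solves), `on_boundary`.
#' @export
solve_trust_region_step <- function(apply_H, grad, radius, precond,
                                    tol = NULL, maxit = 100L,
                                    sigma0 = NULL) {
  g <- as.vector(grad)
  if (is.null(tol)) tol <- min(1e-2 * sqrt(sum(g^2)), 1e-6)
  b <- -g
  res <- .pcg(apply_H, b, precond, 0, tol, maxit, radius)
  micro <- res$iters
  nx <- sqrt(sum(res$x^2))
  if (!res$negcurv && !res$exceeded && nx <= radius) {
    return(list(step = res$x, mu = 0, micro = micro, on_boundary = FALSE))
  }
  # boundary solution: find a positive shift sigma for which the step lands
  # near the boundary (||x|| monotonically decreasing in sigma); reported
  # level shift is mu = -sigma. Warm-started from the previous iteration.
  band_lo <- 0.6
  sig_lo <- 0
  sig_hi <- if (!is.null(sigma0) && sigma0 > 0) sigma0 else
    max(sqrt(sum(g^2)) / radius, 1e-4)
  x_hi <- NULL
  for (k in 1:60) {
    res <- .pcg(apply_H, b, precond, sig_hi, tol, maxit, radius)
    micro <- micro + res$iters
    nx <- sqrt(sum(res$x^2))
    if (!res$negcurv && !res$exceeded && nx <= radius) {
      x_hi <- res$x
      break
    }
    sig_lo <- sig_hi
    sig_hi <- sig_hi * 4
  }
  if (is.null(x_hi)) stop("trust-region shift search failed to bracket")
  # move toward the boundary band; for the soft-mode dominated steps of
  # this problem ||x(sigma)|| ~ C/sigma, so sigma * ||x|| / radius is an
  # excellent one-point root update (bisection as safeguard)
  x <- x_hi
  sig <- sig_hi
  for (k in 1:30) {
    nx <- sqrt(sum(x^2))
    if (nx >= band_lo * radius && nx <= radius) break
    sig_new <- sig * nx / (0.9 * radius)
    if (sig_new <= sig_lo || sig_new >= sig) {
      sig_new <- 0.5 * (sig_lo + sig)
    }
    res <- .pcg(apply_H, b, precond, sig_new, tol, maxit, radius)
    micro <- micro + res$iters
    if (res$negcurv || res$exceeded || sqrt(sum(res$x^2)) > radius) {
      sig_lo <- sig_new
    } else {
      sig <- sig_new
      x <- res$x
    }
  }
  list(step = x, mu = -sig, micro = micro, on_boundary = TRUE)
}

# ---------------------------------------------------------------------------
#' Trust-region Newton-Raphson driver
#'
#' Second-order optimization of the concatenated (kappa, eta) parameters
#' using only the kappa-kappa and eta-eta Hessian blocks by default (the
#' coupling blocks can be enabled). Each macro-iteration assembles the
#' gradients, solves the level-shifted Newton equations matrix-free, applies
#' the orbital rotation through the exponential map and the eta step
#' additively, and accepts or rejects by the trust-region gain ratio.
#'
#' @param sys a [scqed_system()].
#' @param control an [scf_control()].
#' @param state optional initial state (list with `W`, `eta`).
#' @return list with the final `W`, `eta`, `energy`, a per-iteration
#'   `report` data frame, `converged`, `iterations`.
#' @export
run_tr_nr <- function(sys, control = scf_control(), state = NULL) {
  maxit <- control$max_iterations %||% 50L
  if (is.null(state)) state <- .initial_state(sys)
  W <- state$W
  eta <- state$eta
  n <- sys$n
  no <- sys$nocc
  nv <- n - no
  radius <- control$trust_radius_init
  sigma_prev <- NULL
  report <- NULL
  E_prev <- NA_real_
  converged <- FALSE
  E <- NA_real_
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    dress <- dress_integrals(sys, eta)
    D <- density_from_W(sys, W)
    fock <- fock_dipole_basis(sys, W, eta, dress, D)
    E <- sum(dress$h_eff * D) +
      0.5 * sum(D * (fock - dress$h_eff)) + sys$e_nuc +
      0.5 * sys$cavity$lambda^2 * sys$c_nuc^2
    gk <- kappa_gradient(sys, W, eta, dress, fock)
    ge <- eta_gradient(sys, W, eta, dress)
    met <- convergence_metrics(E, E_prev, gk, ge)
    if (.is_converged(met, control)) {
      report <- rbind(report, .report_row(it, E, met, 0L, radius, 0))
      converged <- TRUE
      break
    }
    cache <- eta_eta_cache(sys, W, eta, dress)
    Hd <- build_dense_eta_eta(sys, W, eta, dress, cache)
    # preconditioner: Fock-difference diagonal for the kappa block, the
    # (already built) dense eta-eta block for the eta part
    kk_diag <- as.vector(kk_diagonal_preconditioner(sys, W, eta, dress,
                                                    fock))
    ridge <- max(1e-10, 1e-7 * max(abs(diag(Hd))))
    precond <- function(shift) {
      pk <- pmax(kk_diag + shift, 1e-8)
      Hs <- Hd + diag(shift + ridge, n)
      ch <- tryCatch(chol(Hs), error = function(e) NULL)
      if (is.null(ch)) {
        pe <- pmax(diag(Hd) + shift, max(1e-10, 1e-6 * max(diag(Hd), 0)))
        return(function(r) c(r[seq_len(nv * no)] / pk,
                             r[nv * no + seq_len(n)] / pe))
      }
      function(r) c(r[seq_len(nv * no)] / pk,
                    backsolve(ch, forwardsolve(t(ch), r[nv * no + seq_len(n)])))
    }
    apply_H <- function(z) {
      vk <- matrix(z[seq_len(nv * no)], nv, no)
      ve <- z[nv * no + seq_len(n)]
      hk <- lt_kappa_kappa(sys, W, eta, vk, dress, fock)
      he <- lt_eta_eta(sys, W, eta, ve, dress, cache)
      if (control$mixed_blocks) {
        mx <- lt_mixed(sys, W, eta, vk, ve, dress)
        hk <- hk + mx$kappa
        he <- he + mx$eta
      }
      c(as.vector(hk), he)
    }
    grad <- c(as.vector(gk), ge)
    ts <- solve_trust_region_step(apply_H, grad, radius, precond,
                                  maxit = control$micro_cap,
                                  sigma0 = sigma_prev)
    # the accepted shift shrinks roughly an order of magnitude per
    # macro-iteration; warm-start the next search below the previous value
    sigma_prev <- if (ts$mu < 0) -ts$mu / 8 else NULL
    dz <- ts$step
    vk <- matrix(dz[seq_len(nv * no)], nv, no)
    ve <- dz[nv * no + seq_len(n)]
    W_new <- W %*% .expm_antisym(.kappa_full(vk, n, no))
    eta_new <- eta + ve
    E_new <- scqed_energy(sys, W_new, eta_new)
    pred <- sum(grad * dz) + 0.5 * sum(dz * apply_H(dz))
    noise <- 1e-13 * max(1, abs(E))
    if (abs(pred) < noise) {
      # predicted change below the numerical noise floor of the energy:
      # the gain ratio is meaningless, take the (tiny) Newton step
      rho <- 1
    } else {
      rho <- if (pred < 0) (E_new - E) / pred else -1
    }
    accepted <- rho > 0
    if (accepted) {
      W <- W_new
      eta <- eta_new
    }
    if (rho > 0.75 && ts$on_boundary) {
      radius <- min(radius * 2, control$trust_radius_max)
    } else if (rho < 0.25) {
      radius <- max(radius * 0.7, control$trust_radius_min)
    }
    report <- rbind(report, .report_row(it, E, met, ts$micro, radius, ts$mu))
    E_prev <- E
  }
  list(W = W, eta = eta, energy = E, report = report,
       converged = converged, iterations = it)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
#' Gradient-based DIIS driver (baseline)
#'
#' The first-generation optimizer: Roothaan-Hall diagonalization of the
#' dipole-basis Fock matrix with DIIS on the density, and damped
#' steepest-descent updates of eta accelerated by a second DIIS buffer. The
#' eta updates lack curvature information, and on several benchmark systems
#' the scaled eta-gradient norm plateaus above threshold (the documented
#' pathology that motivates the second-order drivers).
#'
#' @inheritParams run_tr_nr
#' @return as [run_tr_nr()] (micro/radius/mu columns are `NA`).
#' @export
run_gb_diis <- function(sys, control = scf_control(), state = NULL) {
  maxit <- control$max_iterations %||% 2000L
  if (is.null(state)) state <- .initial_state(sys)
  W <- state$W
  eta <- state$eta
  report <- NULL
  E_prev <- NA_real_
  converged <- FALSE
  E <- NA_real_
  fbuf <- diis_buffer(control$diis_dim)
  ebuf <- diis_buffer(control$diis_dim)
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    dress <- dress_integrals(sys, eta)
    D <- density_from_W(sys, W)
    fock <- fock_dipole_basis(sys, W, eta, dress, D)
    E <- sum(dress$h_eff * D) +
      0.5 * sum(D * (fock - dress$h_eff)) + sys$e_nuc +
      0.5 * sys$cavity$lambda^2 * sys$c_nuc^2
    gk <- kappa_gradient(sys, W, eta, dress, fock)
    ge <- eta_gradient(sys, W, eta, dress)
    met <- convergence_metrics(E, E_prev, gk, ge)
    report <- rbind(report, .report_row(it, E, met))
    if (.is_converged(met, control)) {
      converged <- TRUE
      break
    }
    # Roothaan-Hall with DIIS on the Fock matrix (basis is orthonormal)
    err <- fock %*% D - D %*% fock
    fbuf <- diis_push(fbuf, as.vector(fock), as.vector(err))
    Fx <- matrix(diis_extrapolate(fbuf), sys$n, sys$n)
    es <- eigen((Fx + t(Fx)) / 2, symmetric = TRUE)
    W <- es$vectors[, order(es$values), drop = FALSE]
    # damped steepest descent + DIIS for eta
    eta_new <- eta - control$eta_step * ge
    ebuf <- diis_push(ebuf, eta_new, ge)
    eta <- diis_extrapolate(ebuf)
    E_prev <- E
  }
  list(W = W, eta = eta, energy = E, report = report,
       converged = converged, iterations = it)
}

# ---------------------------------------------------------------------------
#' Roothaan-Hall + direct inversion of the eta-eta Hessian block
#'
#' DIIS-accelerated Roothaan-Hall for the density, and a Newton step for eta
#' from the dense eta-eta Hessian block built by partial traces of the
#' dressed integrals (cost N^4, inversion N^3; no micro-iterations). When
#' the block is not positive definite (possible in early iterations) the
#' driver falls back to a damped gradient step; near-singular blocks are
#' inverted through an eigenvalue-floored pseudo-inverse.
#'
#' @inheritParams run_tr_nr
#' @return as [run_tr_nr()].
#' @export
run_gb_dbi <- function(sys, control = scf_control(), state = NULL) {
  maxit <- control$max_iterations %||% 300L
  if (is.null(state)) state <- .initial_state(sys)
  W <- state$W
  eta <- state$eta
  report <- NULL
  E_prev <- NA_real_
  converged <- FALSE
  E <- NA_real_
  fbuf <- diis_buffer(control$diis_dim)
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    dress <- dress_integrals(sys, eta)
    D <- density_from_W(sys, W)
    fock <- fock_dipole_basis(sys, W, eta, dress, D)
    E <- sum(dress$h_eff * D) +
      0.5 * sum(D * (fock - dress$h_eff)) + sys$e_nuc +
      0.5 * sys$cavity$lambda^2 * sys$c_nuc^2
    gk <- kappa_gradient(sys, W, eta, dress, fock)
    ge <- eta_gradient(sys, W, eta, dress)
    met <- convergence_metrics(E, E_prev, gk, ge)
    report <- rbind(report, .report_row(it, E, met))
    if (.is_converged(met, control)) {
      converged <- TRUE
      break
    }
    err <- fock %*% D - D %*% fock
    fbuf <- diis_push(fbuf, as.vector(fock), as.vector(err))
    Fx <- matrix(diis_extrapolate(fbuf), sys$n, sys$n)
    es <- eigen((Fx + t(Fx)) / 2, symmetric = TRUE)
    Wn <- es$vectors[, order(es$values), drop = FALSE]
    if (sys$cavity$lambda > 0) {
      # eta step concurrent with the orbital update, at the current state
      Hd <- build_dense_eta_eta(sys, W, eta, dress)
      eh <- eigen(Hd, symmetric = TRUE)
      if (min(eh$values) <= 0) {
        eta <- eta - control$eta_step * ge
      } else {
        inv_vals <- 1 / pmax(eh$values, control$eta_floor)
        deta <- -as.vector(eh$vectors %*% (inv_vals *
                                             crossprod(eh$vectors, ge)))
        eta <- eta + deta
      }
    }
    W <- Wn
    E_prev <- E
  }
  list(W = W, eta = eta, energy = E, report = report,
       converged = converged, iterations = it)
}
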
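# Validation harness: finite-difference differentiation, the origin
# invariance check (with the frozen-eta ablation), and the lambda -> 0
# reduction check. These are the oracles the test suite leans on; none of
# them share derivative code with the analytic implementations they test.

#' Central finite-difference directional derivative
#'
#' @param f scalar function of a numeric vector.
#' @param x evaluation point.
#' @param direction direction vector (same length as `x`).
#' @param step step size h; the estimate is (f(x + h d) - f(x - h d)) / 2h.
#' @return the directional-derivative estimate.
#' @export
fd_gradient <- function(f, x, direction, step = 1e-4) {
  if (step <= 0) stop("step must be positive")
  fp <- f(x + step * direction)
  fm <- f(x - step * direction)
  if (!is.finite(fp) || !is.finite(fm)) {
    stop("objective not finite at displaced point")
  }
  (fp - fm) / (2 * step)
}

# Fixed-eta SCF: Roothaan-Hall + DIIS on the dipole-basis Fock matrix with
# eta clamped (ablation used to demonstrate the origin-variance of a
# QED-HF-style treatment that lacks the coherent-state relaxation).
.fixed_eta_scf <- function(sys, eta, control = scf_control()) {
  maxit <- control$max_iterations %||% 300L
  dress <- dress_integrals(sys, eta)
  st <- .initial_state(sys)
  W <- st$W
  fbuf <- diis_buffer(control$diis_dim)
  E_prev <- NA_real_
  converged <- FALSE
  E <- NA_real_
  for (it in seq_len(maxit)) {
    D <- density_from_W(sys, W)
    fock <- fock_dipole_basis(sys, W, eta, dress, D)
    E <- sum(dress$h_eff * D) +
      0.5 * sum(D * (fock - dress$h_eff)) + sys$e_nuc +
      0.5 * sys$cavity$lambda^2 * sys$c_nuc^2
    err <- fock %*% D - D %*% fock
    if (!is.na(E_prev) && abs(E - E_prev) < control$energy_threshold &&
        max(abs(err)) < 1e-8) {
      converged <- TRUE
      break
    }
    fbuf <- diis_push(fbuf, as.vector(fock), as.vector(err))
    Fx <- matrix(diis_extrapolate(fbuf), sys$n, sys$n)
    es <- eigen((Fx + t(Fx)) / 2, symmetric = TRUE)
    W <- es$vectors[, order(es$values), drop = FALSE]
    E_prev <- E
  }
  list(energy = E, W = W, converged = converged, iterations = it)
}

#' Origin-invariance check
#'
#' Converges SC-QED-HF for a molecule at its given position and after a
#' rigid translation, and returns the absolute energy difference. For the
#' fully relaxed ansatz the energy is origin independent even for charged
#' systems (the coherent-state parameters absorb the dipole-operator shift
#' `d -> d - a Q_tot`); with the eta parameters frozen (`frozen_eta = TRUE`,
#' an ablation mimicking a plain QED-HF-style treatment) a charged system
#' becomes visibly origin dependent.
#'
#' @param mol a [molecule()].
#' @param cav a [cavity()].
#' @param translation length-3 translation vector in bohr.
#' @param algorithm optimizer for the relaxed runs.
#' @param frozen_eta if `TRUE`, clamp eta = 0 and optimize orbitals only.
#' @param control an [scf_control()].
#' @return list with `delta_e` (|E(translated) - E(original)|), both
#'   energies, and `conclusive` (FALSE if either run failed to converge).
#' @export
origin_invariance_check <- function(mol, cav, translation = c(10, 0, 0),
                                    algorithm = c("gb-dbi", "tr-nr"),
                                    frozen_eta = FALSE,
                                    control = scf_control()) {
  algorithm <- match.arg(algorithm)
  mol2 <- mol
  mol2$coords <- sweep(mol$coords, 2, -as.numeric(translation))
  run1 <- .origin_run(mol, cav, algorithm, frozen_eta, control)
  run2 <- .origin_run(mol2, cav, algorithm, frozen_eta, control)
  list(delta_e = abs(run2$energy - run1$energy),
       energy_original = run1$energy, energy_translated = run2$energy,
       conclusive = run1$converged && run2$converged)
}

.origin_run <- function(mol, cav, algorithm, frozen_eta, control) {
  sys <- scqed_system(mol, cav)
  if (frozen_eta) {
    .fixed_eta_scf(sys, eta = rep(0, sys$n), control)
  } else {
    runner <- switch(algorithm, "tr-nr" = run_tr_nr, "gb-dbi" = run_gb_dbi)
    runner(sys, control)
  }
}

#' Zero-coupling reduction check
#'
#' Runs SC-QED-HF at lambda = 0 with the chosen driver and compares with the
#' plain restricted Hartree-Fock oracle; the two must agree since all
#' photonic dressing disappears at zero coupling.
#'
#' @param mol a [molecule()].
#' @param algorithm optimizer to exercise.
#' @param omega_ev cavity frequency (irrelevant at lambda = 0 but part of
#'   the cavity definition).
#' @return list with `delta_e` (absolute energy difference), `e_scqed`,
#'   `e_rhf`.
#' @export
rhf_limit_check <- function(mol, algorithm = c("tr-nr", "gb-dbi", "gb-diis"),
                            omega_ev = 2.71) {
  algorithm <- match.arg(algorithm)
  cav <- cavity(lambda = 0, omega_ev = omega_ev)
  fit <- scqed_hf(mol, cav, algorithm = algorithm)
  hf <- rhf(mol)
  list(delta_e = abs(fit$energy - hf$energy), e_scqed = fit$energy,
       e_rhf = hf$energy)
}

#' Run the package's validation suite
#'
#' A condensed pass/fail table over the main physics oracles: zero-coupling
#' reduction, finite-difference consistency of both gradients, the
#' variational bound against the Fock-space oracle, and origin invariance
#' (neutral molecule). Runs in well under a minute on small fixtures.
#'
#' @param verbose print the table.
#' @return data frame with columns `check`, `value`, `tolerance`, `pass`.
#' @export
scqed_selftest <- function(verbose = TRUE) {
  rows <- list()
  add <- function(check, value, tol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, value = value, tolerance = tol, pass = value <= tol)
  }
  h2o <- fixture_molecule("h2o", basis = "sto-3g")
  add("zero-coupling reduction (H2O/STO-3G, tr-NR)",
      rhf_limit_check(h2o, "tr-nr")$delta_e, 1e-9)
  cavs <- cavity(lambda = 0.05, omega = 0.5)
  sys <- scqed_system(h2o, cavs)
  st <- .initial_state(sys)
  eta0 <- sys$d_diag + 0.1 * sin(seq_len(sys$n))  # fixed non-stationary point
  ge <- eta_gradient(sys, st$W, eta0)
  dir <- cos(seq_len(sys$n))
  fd <- fd_gradient(function(e) scqed_energy(sys, st$W, e), eta0, dir)
  add("eta-gradient vs finite differences", abs(sum(ge * dir) - fd), 1e-6)
  no <- sys$nocc
  nv <- sys$n - no
  vk <- matrix(sin(seq_len(nv * no)), nv, no)
  gk <- kappa_gradient(sys, st$W, eta0)
  fdk <- fd_gradient(function(t) {
    K <- .kappa_full(t[1] * vk, sys$n, no)
    scqed_energy(sys, st$W %*% .expm_antisym(K), eta0)
  }, 0, 1)
  add("kappa-gradient vs finite differences", abs(sum(gk * vk) - fdk), 1e-6)
  h2 <- fixture_molecule("h2", basis = "sto-3g")
  cav2 <- cavity(lambda = 0.05, omega = 0.5)
  e_exact <- exact_polariton_converged(h2, cav2)$energy
  e_mf <- scqed_hf(h2, cav2, algorithm = "tr-nr")$energy
  add("variational bound (H2/STO-3G)", e_exact - e_mf, 0)
  oi <- origin_invariance_check(h2o, cavity(lambda = 0.05, omega_ev = 2.71),
                                translation = c(5, 0, 0))
  add("origin invariance (neutral H2O)", oi$delta_e, 1e-9)
  out <- do.call(rbind, rows)
  if (verbose) print(out, row.names = FALSE)
  invisible(out)
}
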
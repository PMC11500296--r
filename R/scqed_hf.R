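# Front-end: one fitting function returning a classed object, in the spirit
# of R's modelling functions.

#' Fit a strong-coupling QED Hartree-Fock wave function
#'
#' Variationally optimizes the SC-QED-HF ansatz — a Slater determinant
#' dressed, orbital by orbital, with photonic coherent states — for a
#' molecule coupled to a single cavity mode. The two wave-function parameter
#' classes are the occupied-virtual orbital rotations (kappa) and the
#' orbital-specific coherent-state displacements (eta); the optimizer
#' choices differ in how they treat the poorly conditioned eta subspace.
#'
#' @param mol a [molecule()] object (or the name of a bundled fixture, see
#'   [fixture_molecule()]).
#' @param cav a [cavity()] object.
#' @param algorithm `"tr-nr"` (trust-region Newton-Raphson, default),
#'   `"gb-dbi"` (Roothaan-Hall/DIIS plus direct inversion of the eta-eta
#'   Hessian block) or `"gb-diis"` (the gradient-based baseline).
#' @param control an [scf_control()] list.
#' @param basis optional basis-set name overriding the molecule's.
#' @return an object of class `"scqed_hf"` with components `energy`
#'   (hartree), `eta`, `orbital_energies` (semicanonical), `C_ao`
#'   (AO-basis MO coefficients), `W` (MOs in the dipole basis), `d_diag`
#'   (dipole-basis eigenvalues), `report` (per-iteration convergence
#'   diagnostics), `converged`, `iterations`, `rhf_energy` (field-free
#'   reference), plus the inputs.
#' @examples
#' \donttest{
#' mol <- fixture_molecule("h2o", basis = "sto-3g")
#' cav <- cavity(lambda = 0.005, omega_ev = 2.71)
#' fit <- scqed_hf(mol, cav, algorithm = "tr-nr")
#' summary(fit)
#' }
#' @export
scqed_hf <- function(mol, cav, algorithm = c("tr-nr", "gb-dbi", "gb-diis"),
                     control = scf_control(), basis = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.character(mol)) mol <- fixture_molecule(mol, basis = basis %||% "sto-3g")
  if (!is.null(basis)) mol$basis_name <- tolower(basis)
  sys <- scqed_system(mol, cav)
  state <- .initial_state(sys)
  runner <- switch(algorithm, "tr-nr" = run_tr_nr, "gb-dbi" = run_gb_dbi,
                   "gb-diis" = run_gb_diis)
  res <- runner(sys, control, state)
  sc <- .semicanonicalize(sys, res$W, res$eta)
  structure(list(
    energy = res$energy, eta = res$eta, W = sc$W,
    orbital_energies = sc$orbital_energies,
    C_ao = sys$Ct %*% sc$W, d_diag = sys$d_diag,
    report = res$report, converged = res$converged,
    iterations = res$iterations, algorithm = algorithm,
    rhf_energy = state$rhf_energy, molecule = mol, cavity = cav,
    control = control, sys = sys), class = "scqed_hf")
}

#' @export
print.scqed_hf <- function(x, ...) {
  cat("SC-QED-HF (", x$algorithm, ")\n", sep = "")
  cat(sprintf("  molecule: %s atoms, charge %+d, basis %s\n",
              length(x$molecule$atoms), x$molecule$charge,
              x$molecule$basis_name))
  cat(sprintf("  cavity:   omega = %.6f Eh, lambda = %g, eps = (%g, %g, %g)\n",
              x$cavity$omega, x$cavity$lambda, x$cavity$polarization[1],
              x$cavity$polarization[2], x$cavity$polarization[3]))
  cat(sprintf("  energy:   %.12f hartree (%s in %d iterations)\n",
              x$energy, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
summary.scqed_hf <- function(object, ...) {
  last <- object$report[nrow(object$report), ]
  out <- list(
    energy = object$energy, rhf_energy = object$rhf_energy,
    cavity_shift = object$energy - object$rhf_energy,
    converged = object$converged, iterations = object$iterations,
    algorithm = object$algorithm, final = last,
    mean_micro = if (all(is.na(object$report$micro))) NA_real_ else
      mean(object$report$micro[!is.na(object$report$micro) &
                                 object$report$micro > 0]),
    eta_range = range(object$eta))
  class(out) <- "summary.scqed_hf"
  out
}

#' @export
print.summary.scqed_hf <- function(x, ...) {
  cat(sprintf("SC-QED-HF summary (%s)\n", x$algorithm))
  cat(sprintf("  total energy      %18.12f hartree\n", x$energy))
  cat(sprintf("  field-free RHF    %18.12f hartree\n", x$rhf_energy))
  cat(sprintf("  cavity shift      %18.12f hartree\n", x$cavity_shift))
  cat(sprintf("  converged         %s after %d macro-iterations\n",
              x$converged, x$iterations))
  if (!is.na(x$mean_micro)) {
    cat(sprintf("  mean micro-iterations per solve  %.2f\n", x$mean_micro))
  }
  cat(sprintf("  final max|E^(1)|  %g\n", x$final$max_grad))
  cat(sprintf("  final ||g_k||/N_k %g   ||g_eta||/N_eta %g\n",
              x$final$gk_scaled, x$final$ge_scaled))
  invisible(x)
}

#' @export
coef.scqed_hf <- function(object, type = c("eta", "orbitals"), ...) {
  type <- match.arg(type)
  if (type == "eta") object$eta else object$C_ao
}

#' Residual optimality measures of a converged fit
#'
#' Returns the kappa and eta gradient vectors at the final state: the
#' first-order conditions of the variational problem (all should be below
#' the convergence threshold for a converged fit).
#'
#' @param object an `"scqed_hf"` fit.
#' @param ... unused.
#' @export
residuals.scqed_hf <- function(object, ...) {
  sys <- object$sys
  list(kappa = kappa_gradient(sys, object$W, object$eta),
       eta = eta_gradient(sys, object$W, object$eta))
}

#' Convergence-history plot
#'
#' Plots the per-iteration diagnostics (energy change, maximum gradient,
#' scaled kappa and eta gradient norms) on a log scale, the quantities by
#' which the drivers are compared.
#'
#' @param x an `"scqed_hf"` fit.
#' @param ... passed to [graphics::matplot()].
#' @importFrom graphics matplot legend abline
#' @export
plot.scqed_hf <- function(x, ...) {
  r <- x$report
  y <- cbind(r$dE, r$max_grad, r$gk_scaled, r$ge_scaled)
  y[y <= 0] <- NA
  matplot(r$iteration, log10(y), type = "b", pch = 1:4, lty = 1,
          xlab = "macro-iteration", ylab = "log10(value)  [a.u.]",
          main = paste("SC-QED-HF convergence,", x$algorithm), ...)
  abline(h = log10(x$control$gradient_threshold), lty = 3)
  legend("topright",
         c("|dE|", "max|E(1)|", "||g_k||/N_k", "||g_eta||/N_eta"),
         pch = 1:4, col = 1:4, bty = "n")
  invisible(x)
}

#' Save / load a restart checkpoint
#'
#' Stores the state needed to restart any optimizer: MO coefficients in the
#' dipole basis, eta parameters, dipole-basis data, energy and iteration
#' metadata.
#'
#' @param fit an `"scqed_hf"` object (or an optimizer result list with `W`,
#'   `eta`).
#' @param path file path.
#' @return `path` for `save_checkpoint`; a list for `load_checkpoint`.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(W = fit$W, eta = fit$eta, energy = fit$energy,
               iterations = fit$iterations, converged = fit$converged,
               d_diag = fit$d_diag %||% NULL), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
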
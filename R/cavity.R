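#' Define the optical cavity mode
#'
#' A single effective cavity photon mode characterised by its frequency, the
#' light-matter coupling strength and a (real) polarization unit vector. The
#' bilinear interaction and the dipole self-energy both enter through the
#' projected molecular dipole along `polarization`.
#'
#' @param lambda coupling strength in atomic units (>= 0).
#' @param omega_ev photon frequency in eV (converted internally to hartree);
#'   give either this or `omega`.
#' @param omega photon frequency in hartree.
#' @param polarization length-3 field polarization vector; must have unit
#'   norm within 1e-12 (it is not silently renormalized).
#' @return object of class `"cavity"` with `omega` (hartree), `lambda`,
#'   `polarization`.
#' @export
cavity <- function(lambda, omega_ev = NULL, omega = NULL,
                   polarization = c(0, 0, 1)) {
  if (is.null(omega) == is.null(omega_ev)) {
    stop("give exactly one of omega (hartree) or omega_ev (eV)")
  }
  if (is.null(omega)) omega <- omega_ev * HARTREE_PER_EV
  if (!is.finite(omega) || omega <= 0) stop("cavity frequency must be > 0")
  if (!is.numeric(lambda) || lambda < 0) {
    stop("coupling strength lambda must be >= 0")
  }
  polarization <- as.numeric(polarization)
  if (length(polarization) != 3 ||
      abs(sqrt(sum(polarization^2)) - 1) > 1e-12) {
    stop("polarization must be a unit 3-vector (norm within 1e-12 of 1)")
  }
  structure(list(omega = omega, lambda = lambda,
                 polarization = polarization),
            class = "cavity")
}

#' @export
print.cavity <- function(x, ...) {
  cat(sprintf(
    "Cavity mode: omega = %.6f hartree (%.4f eV), lambda = %g a.u., eps = (%g, %g, %g)\n",
    x$omega, x$omega / HARTREE_PER_EV, x$lambda,
    x$polarization[1], x$polarization[2], x$polarization[3]))
  invisible(x)
}
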
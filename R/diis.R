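# DIIS (direct inversion in the iterative subspace): ring buffer of
# (parameter, error) pairs and Pulay extrapolation with a Lagrange
# normalization constraint.

#' Create a DIIS buffer
#'
#' @param max_dim subspace size (number of retained pairs).
#' @return empty buffer object of class `"diis_buffer"`.
#' @export
diis_buffer <- function(max_dim = 8L) {
  structure(list(par = list(), err = list(), max_dim = as.integer(max_dim)),
            class = "diis_buffer")
}

#' Push a (parameter, error) pair into a DIIS buffer
#'
#' @param buf a [diis_buffer()].
#' @param par parameter vector.
#' @param err error vector.
#' @return the updated buffer (oldest pair dropped beyond `max_dim`).
#' @export
diis_push <- function(buf, par, err) {
  buf$par[[length(buf$par) + 1L]] <- as.vector(par)
  buf$err[[length(buf$err) + 1L]] <- as.vector(err)
  if (length(buf$par) > buf$max_dim) {
    buf$par <- buf$par[-1L]
    buf$err <- buf$err[-1L]
  }
  buf
}

#' DIIS extrapolation
#'
#' Solves the Pulay least-squares system with the sum-to-one Lagrange
#' constraint and returns the extrapolated parameter vector. A single stored
#' pair is returned unchanged; if the B matrix is numerically singular the
#' most recent parameter vector is returned (safe fallback).
#'
#' @param buf a [diis_buffer()] with at least one stored pair.
#' @param return_coefficients if `TRUE`, also return the mixing weights.
#' @return extrapolated parameter vector, or a list if
#'   `return_coefficients = TRUE`.
#' @export
diis_extrapolate <- function(buf, return_coefficients = FALSE) {
  m <- length(buf$par)
  if (m == 0L) stop("DIIS buffer is empty")
  if (m == 1L) {
    out <- buf$par[[1L]]
    if (return_coefficients) return(list(par = out, coefficients = 1))
    return(out)
  }
  B <- matrix(0, m + 1L, m + 1L)
  for (i in seq_len(m)) {
    for (j in i:m) {
      B[i, j] <- B[j, i] <- sum(buf$err[[i]] * buf$err[[j]])
    }
  }
  B[m + 1L, seq_len(m)] <- -1
  B[seq_len(m), m + 1L] <- -1
  rhs <- c(rep(0, m), -1)
  co <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
  if (is.null(co) || any(!is.finite(co))) {
    out <- buf$par[[m]]
    co <- c(rep(0, m - 1L), 1)
  } else {
    out <- Reduce(`+`, Map(`*`, buf$par, co))
  }
  if (return_coefficients) return(list(par = out, coefficients = co))
  out
}
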
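# Shared fixtures, memoized so expensive objects (integral sets, converged
# fits) are built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

h2o_sto3g <- function() cached("h2o_sto3g", fixture_molecule("h2o", basis = "sto-3g"))
h2_sto3g <- function() cached("h2_sto3g", fixture_molecule("h2", basis = "sto-3g"))

sys_h2o_l05 <- function() cached("sys_h2o_l05",
  scqed_system(h2o_sto3g(), cavity(lambda = 0.05, omega = 0.5)))

rhf_h2o <- function() cached("rhf_h2o", rhf(h2o_sto3g()))

# a fixed, recorded non-stationary state for derivative checks
perturbed_state <- function(sys) {
  n <- sys$n
  set.seed(42)
  hf <- rhf_h2o()
  W0 <- W_from_ao_mos(sys, hf$C)
  K <- matrix(rnorm(n * n, sd = 0.05), n, n)
  K <- K - t(K)
  W <- W0 %*% expm_antisym(K)
  eta <- sys$d_diag + rnorm(n, sd = 0.1)
  list(W = W, eta = eta, W0 = W0)
}

expm_antisym <- function(K) scqedhf:::.expm_antisym(K)

rnorm_fixed <- function(n) {
  set.seed(99)
  rnorm(n)
}
kappa_full <- function(vk, n, no) scqedhf:::.kappa_full(vk, n, no)

# directional FD of the energy along a kappa direction
fd_kappa <- function(sys, W, eta, vk, h = 1e-4) {
  no <- sys$nocc
  K <- kappa_full(h * vk, sys$n, no)
  (scqed_energy(sys, W %*% expm_antisym(K), eta) -
     scqed_energy(sys, W %*% expm_antisym(-K), eta)) / (2 * h)
}
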
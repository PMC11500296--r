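# Hessian machinery: matrix-free linear transformations, dense eta-eta
# block, mixed blocks, preconditioner.

test_that("kappa-kappa linear transformation is linear, symmetric and exact", {
  sys <- sys_h2o_l05()
  st <- perturbed_state(sys)
  n <- sys$n; no <- sys$nocc; nv <- n - no
  dress <- dress_integrals(sys, st$eta)
  zero <- lt_kappa_kappa(sys, st$W, st$eta, matrix(0, nv, no), dress)
  expect_equal(zero, matrix(0, nv, no))
  set.seed(5)
  x <- matrix(rnorm(nv * no), nv, no)
  y <- matrix(rnorm(nv * no), nv, no)
  Hx <- lt_kappa_kappa(sys, st$W, st$eta, x, dress)
  Hy <- lt_kappa_kappa(sys, st$W, st$eta, y, dress)
  # linearity
  Hxy <- lt_kappa_kappa(sys, st$W, st$eta, 2 * x - 3 * y, dress)
  expect_lt(max(abs(Hxy - (2 * Hx - 3 * Hy))), 1e-10)
  # symmetry
  expect_equal(sum(x * Hy), sum(y * Hx), tolerance = 1e-8)
  # matches finite differences of the kappa gradient
  h <- 1e-4
  K <- kappa_full(h * x, n, no)
  gp <- kappa_gradient(sys, st$W %*% expm_antisym(K), st$eta, dress)
  gm <- kappa_gradient(sys, st$W %*% expm_antisym(-K), st$eta, dress)
  expect_lt(max(abs(Hx - (gp - gm) / (2 * h))) / max(abs(Hx)), 1e-6)
})

test_that("eta-eta linear transformation matches FD and the dense build", {
  sys <- sys_h2o_l05()
  st <- perturbed_state(sys)
  n <- sys$n
  dress <- dress_integrals(sys, st$eta)
  set.seed(6)
  v <- rnorm(n)
  Hv <- lt_eta_eta(sys, st$W, st$eta, v, dress)
  h <- 1e-4
  fd <- (eta_gradient(sys, st$W, st$eta + h * v) -
           eta_gradient(sys, st$W, st$eta - h * v)) / (2 * h)
  expect_lt(max(abs(Hv - fd)), 1e-6)
  # dense block equals the transformation applied to the standard basis
  Hd <- build_dense_eta_eta(sys, st$W, st$eta, dress)
  cols <- vapply(seq_len(n), function(t) {
    lt_eta_eta(sys, st$W, st$eta, replace(numeric(n), t, 1), dress)
  }, numeric(n))
  expect_lt(max(abs(Hd - cols)), 1e-8)
  expect_lt(max(abs(Hd - t(Hd))), 1e-10)
  # lambda = 0: block vanishes
  sys0 <- cached("sys_h2o_l0",
                 scqed_system(h2o_sto3g(), cavity(lambda = 0, omega = 0.5)))
  expect_identical(lt_eta_eta(sys0, st$W, rep(0, n), v), numeric(n))
})

test_that("dense eta-eta block is strongly nondiagonal and PSD at the minimum", {
  fit <- cached("fit_h2o_l05_trnr",
                scqed_hf(h2o_sto3g(), cavity(lambda = 0.05, omega = 0.5),
                         algorithm = "tr-nr"))
  sys <- fit$sys
  Hd <- build_dense_eta_eta(sys, fit$W, fit$eta)
  ev <- eigen(Hd, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # off-diagonal mass: the couplings are a large share of the block
  off_mass <- (sum(abs(Hd)) - sum(abs(diag(Hd)))) / sum(abs(Hd))
  expect_gt(off_mass, 0.1)
})

test_that("mixed blocks respect the block structure and match FD", {
  sys <- sys_h2o_l05()
  st <- perturbed_state(sys)
  n <- sys$n; no <- sys$nocc; nv <- n - no
  set.seed(8)
  vk <- matrix(rnorm(nv * no), nv, no)
  ve <- rnorm(n)
  # zero eta part: the kappa-eta block contributes nothing
  mx0 <- lt_mixed(sys, st$W, st$eta, vk, numeric(n))
  expect_equal(mx0$kappa, matrix(0, nv, no), tolerance = 1e-12)
  mx <- lt_mixed(sys, st$W, st$eta, vk, ve)
  h <- 1e-4
  gkp <- kappa_gradient(sys, st$W, st$eta + h * ve)
  gkm <- kappa_gradient(sys, st$W, st$eta - h * ve)
  expect_lt(max(abs(mx$kappa - (gkp - gkm) / (2 * h))), 1e-6)
  K <- kappa_full(h * vk, n, no)
  gep <- eta_gradient(sys, st$W %*% expm_antisym(K), st$eta)
  gem <- eta_gradient(sys, st$W %*% expm_antisym(-K), st$eta)
  expect_lt(max(abs(mx$eta - (gep - gem) / (2 * h))), 1e-6)
  # with all four blocks the full Hessian is symmetric
  vk2 <- matrix(rnorm(nv * no), nv, no)
  ve2 <- rnorm(n)
  mx2 <- lt_mixed(sys, st$W, st$eta, vk2, ve2)
  Hx <- c(as.vector(lt_kappa_kappa(sys, st$W, st$eta, vk) + mx$kappa),
          lt_eta_eta(sys, st$W, st$eta, ve) + mx$eta)
  Hy <- c(as.vector(lt_kappa_kappa(sys, st$W, st$eta, vk2) + mx2$kappa),
          lt_eta_eta(sys, st$W, st$eta, ve2) + mx2$eta)
  x <- c(as.vector(vk), ve)
  y <- c(as.vector(vk2), ve2)
  expect_equal(sum(y * Hx), sum(x * Hy), tolerance = 1e-8)
})

test_that("enabling mixed blocks reaches the same stationary point", {
  mol <- h2o_sto3g()
  cav <- cavity(lambda = 0.05, omega = 0.5)
  f1 <- cached("fit_h2o_l05_trnr", scqed_hf(mol, cav, algorithm = "tr-nr"))
  f2 <- scqed_hf(mol, cav, algorithm = "tr-nr",
                 control = scf_control(mixed_blocks = TRUE))
  expect_true(f2$converged)
  expect_equal(f1$energy, f2$energy, tolerance = 1e-9)
})

test_that("kappa diagonal preconditioner reduces to the RHF form at lambda=0", {
  mol <- h2o_sto3g()
  sys0 <- cached("sys_h2o_l0",
                 scqed_system(mol, cavity(lambda = 0, omega = 0.5)))
  hf <- rhf_h2o()
  W0 <- W_from_ao_mos(sys0, hf$C)
  n <- sys0$n; no <- sys0$nocc
  pd <- kk_diagonal_preconditioner(sys0, W0, rep(0, n))
  ref <- 4 * outer(hf$orbital_energies[(no + 1):n],
                   hf$orbital_energies[1:no], "-")
  expect_equal(pd, pmax(ref, 1e-3), tolerance = 1e-6)
  expect_true(all(pd >= 1e-3))
})

test_that("preconditioning saves micro-iterations (water/6-31G)", {
  mol <- cached("mol_h2o_631g", fixture_molecule("h2o", basis = "6-31g"))
  sys <- cached("sys_h2o631_l005",
                scqed_system(mol, cavity(lambda = 0.005, omega_ev = 2.71)))
  st <- scqedhf:::.initial_state(sys)
  dress <- dress_integrals(sys, st$eta)
  fock <- fock_dipole_basis(sys, st$W, st$eta, dress)
  cache <- scqedhf:::eta_eta_cache(sys, st$W, st$eta, dress)
  n <- sys$n; no <- sys$nocc; nv <- n - no
  gk <- kappa_gradient(sys, st$W, st$eta, dress, fock)
  ge <- eta_gradient(sys, st$W, st$eta, dress)
  grad <- c(as.vector(gk), ge)
  apply_H <- function(z) {
    vk <- matrix(z[seq_len(nv * no)], nv, no)
    ve <- z[nv * no + seq_len(n)]
    c(as.vector(lt_kappa_kappa(sys, st$W, st$eta, vk, dress, fock)),
      lt_eta_eta(sys, st$W, st$eta, ve, dress, cache))
  }
  pdiag <- c(as.vector(kk_diagonal_preconditioner(sys, st$W, st$eta, dress,
                                                  fock)),
             pmax(diag(build_dense_eta_eta(sys, st$W, st$eta, dress, cache)),
                  1e-8))
  big_r <- 1e6   # interior solves: compare pure micro-solver effort
  with_p <- solve_trust_region_step(apply_H, grad, big_r, pdiag, tol = 1e-10)
  without_p <- solve_trust_region_step(apply_H, grad, big_r,
                                       rep(1, length(grad)), tol = 1e-10)
  expect_lt(with_p$micro, without_p$micro)
})
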
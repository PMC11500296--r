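# Dipole basis, dressed integrals, energy, Fock matrix and gradients.

test_that("dipole basis diagonalizes the projected dipole", {
  sys <- sys_h2o_l05()
  ints <- ao_integrals(h2o_sto3g())
  cav <- sys$cavity
  hf <- rhf_h2o()
  db <- build_dipole_basis(hf$C, ints, cav)
  expect_lt(max(abs(crossprod(db$V) - diag(sys$n))), 1e-10)
  dmo <- crossprod(hf$C, scqedhf:::dip_projected(ints, cav$polarization) %*%
                     hf$C)
  dd <- crossprod(db$V, dmo %*% db$V)
  expect_lt(max(abs(dd - diag(diag(dd)))), 1e-10)
  expect_false(is.unsorted(db$d_diag))
  # already-diagonal input: V is the identity up to the sign fix
  Ct_mo <- sys$Ct   # dipole-basis orbitals as the MO input
  db2 <- build_dipole_basis(Ct_mo, ints, cav)
  expect_lt(max(abs(abs(db2$V) - diag(sys$n))), 1e-8)
  # non-orthonormal input rejected
  expect_error(build_dipole_basis(hf$C * 1.01, ints, cav), "orthonormal")
})

test_that("H2 dipole basis matches a by-hand 2x2 diagonalization", {
  mol <- h2_sto3g()
  ints <- cached("ints_h2", ao_integrals(mol))
  cav <- cavity(lambda = 0.05, omega = 0.5, polarization = c(0, 0, 1))
  sys <- scqed_system(mol, cav)
  # generalized 2x2 problem solved through the closed-form quadratic
  S <- ints$S
  Dm <- scqedhf:::dip_projected(ints, cav$polarization)
  X <- scqedhf:::.inv_sqrt(S)
  M <- crossprod(X, Dm %*% X)
  tr <- M[1, 1] + M[2, 2]
  det_ <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  lam_hand <- sort(c((tr - sqrt(tr^2 - 4 * det_)) / 2,
                     (tr + sqrt(tr^2 - 4 * det_)) / 2))
  expect_equal(sys$d_diag, lam_hand, tolerance = 1e-12)
  # eigenvalues symmetric about the bond-midpoint dipole value
  mid <- -mean(mol$coords[, 3])   # electronic dipole sign convention
  expect_equal(mean(sys$d_diag), mid, tolerance = 1e-10)
})

test_that("dressing factors behave at the zero-coupling and equal-eta limits", {
  mol <- h2o_sto3g()
  sys0 <- cached("sys_h2o_l0",
                 scqed_system(mol, cavity(lambda = 0, omega = 0.5)))
  n <- sys0$n
  d0 <- dress_integrals(sys0, rnorm_fixed(n))
  expect_equal(dim(d0$gm), c(n^2, n^2))
  expect_equal(d0$h_eff, sys0$h, tolerance = 1e-15)
  expect_equal(matrix(d0$gm, n^2, n^2), matrix(sys0$g, n^2, n^2),
               tolerance = 1e-15)
  sys <- sys_h2o_l05()
  de <- dress_integrals(sys, rep(0.37, n))
  expect_equal(de$G1, matrix(1, n, n))
  # factors lie in (0, 1]
  eta <- perturbed_state(sys)$eta
  dr <- dress_integrals(sys, eta)
  expect_true(all(dr$G1 > 0 & dr$G1 <= 1))
  # single-element spot check against a scalar evaluation of the exponent
  s <- sys$cavity$lambda^2 / (4 * sys$cavity$omega)
  p <- 2; q <- 5
  expect_equal(dr$G1[p, q], exp(-s * (eta[p] - eta[q])^2), tolerance = 1e-14)
  g4 <- array(dr$gm, rep(n, 4))
  p <- 1; q <- 4; r <- 2; t <- 6
  expect_equal(g4[p, q, r, t],
               sys$g[p, q, r, t] *
                 exp(-s * (eta[p] - eta[q] + eta[r] - eta[t])^2),
               tolerance = 1e-13)
  # permutational symmetries implied by the eta-difference arguments
  expect_equal(g4, aperm(g4, c(2, 1, 4, 3)), tolerance = 1e-12)
  expect_equal(g4, aperm(g4, c(3, 4, 1, 2)), tolerance = 1e-12)
})

test_that("energy reduces to RHF at lambda = 0 and is occ-rotation invariant", {
  mol <- h2o_sto3g()
  sys0 <- cached("sys_h2o_l0",
                 scqed_system(mol, cavity(lambda = 0, omega = 0.5)))
  hf <- rhf_h2o()
  W0 <- W_from_ao_mos(sys0, hf$C)
  expect_equal(scqed_energy(sys0, W0, rep(0, sys0$n)), hf$energy,
               tolerance = 1e-10)
  # occupied-occupied mixing leaves the energy unchanged
  sys <- sys_h2o_l05()
  st <- perturbed_state(sys)
  no <- sys$nocc
  set.seed(11)
  A <- matrix(rnorm(no * no), no, no)
  A <- A - t(A)
  U <- diag(sys$n)
  U[1:no, 1:no] <- expm_antisym(A)
  e1 <- scqed_energy(sys, st$W, st$eta)
  e2 <- scqed_energy(sys, st$W %*% U, st$eta)
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("Fock matrix is the density derivative of the energy", {
  sys <- sys_h2o_l05()
  st <- perturbed_state(sys)
  dress <- dress_integrals(sys, st$eta)
  Fm <- fock_dipole_basis(sys, st$W, st$eta, dress)
  expect_lt(max(abs(Fm - t(Fm))), 1e-10)
  # finite difference of E w.r.t. a symmetric density perturbation
  D <- scqedhf:::density_from_W(sys, st$W)
  e_of_d <- function(D) {
    jk <- scqedhf:::jk_build(dress, D)
    sum(dress$h_eff * D) + 0.5 * sum(D * jk$J) - 0.25 * sum(D * jk$K) +
      sys$e_nuc + 0.5 * sys$cavity$lambda^2 * sys$c_nuc^2
  }
  h <- 1e-5
  for (idx in list(c(1, 1), c(2, 5))) {
    P <- matrix(0, sys$n, sys$n)
    P[idx[1], idx[2]] <- P[idx[2], idx[1]] <- 1
    fd <- (e_of_d(D + h * P) - e_of_d(D - h * P)) / (2 * h)
    analytic <- sum(Fm * P)
    expect_equal(analytic, fd, tolerance = 1e-6)
  }
  # lambda = 0: equals the canonical RHF Fock matrix in the dipole basis
  mol <- h2o_sto3g()
  sys0 <- cached("sys_h2o_l0",
                 scqed_system(mol, cavity(lambda = 0, omega = 0.5)))
  hf <- rhf_h2o()
  ints <- ao_integrals(mol)
  n <- sys0$n
  gm <- matrix(ints$eri, n^2, n^2)
  gk <- matrix(aperm(ints$eri, c(1, 4, 3, 2)), n^2, n^2)
  F_ao <- ints$hcore + matrix(gm %*% as.vector(hf$D), n, n) -
    0.5 * matrix(gk %*% as.vector(hf$D), n, n)
  W0 <- W_from_ao_mos(sys0, hf$C)
  F_dip <- fock_dipole_basis(sys0, W0, rep(0, n))
  expect_equal(F_dip, crossprod(sys0$Ct, F_ao %*% sys0$Ct),
               tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  sys <- sys_h2o_l05()
  st <- perturbed_state(sys)
  n <- sys$n
  no <- sys$nocc
  nv <- n - no
  # eta gradient, every component
  ge <- eta_gradient(sys, st$W, st$eta)
  h <- 1e-4
  fd <- vapply(seq_len(n), function(t) {
    ep <- st$eta; ep[t] <- ep[t] + h
    em <- st$eta; em[t] <- em[t] - h
    (scqed_energy(sys, st$W, ep) - scqed_energy(sys, st$W, em)) / (2 * h)
  }, 0)
  expect_lt(max(abs(ge - fd)), 1e-6)
  # kappa gradient along fixed directions
  gk <- kappa_gradient(sys, st$W, st$eta)
  set.seed(3)
  for (k in 1:3) {
    vk <- matrix(rnorm(nv * no), nv, no)
    expect_equal(sum(gk * vk), fd_kappa(sys, st$W, st$eta, vk),
                 tolerance = 1e-6)
  }
})

test_that("gradients vanish where theory says they must", {
  mol <- h2o_sto3g()
  sys0 <- cached("sys_h2o_l0",
                 scqed_system(mol, cavity(lambda = 0, omega = 0.5)))
  hf <- rhf_h2o()
  W0 <- W_from_ao_mos(sys0, hf$C)
  n <- sys0$n
  # lambda = 0: eta gradient identically zero, kappa gradient zero at the
  # RHF stationary point
  expect_identical(eta_gradient(sys0, W0, rnorm_fixed(n)), numeric(n))
  expect_lt(max(abs(kappa_gradient(sys0, W0, rep(0, n)))), 1e-7)
  # at a converged cavity state both gradients are at threshold
  fit <- cached("fit_h2o_l05_trnr",
                scqed_hf(h2o_sto3g(), cavity(lambda = 0.05, omega = 0.5),
                         algorithm = "tr-nr"))
  res <- residuals(fit)
  expect_lt(max(abs(res$kappa)), 1e-10)
  expect_lt(max(abs(res$eta)), 1e-10)
  expect_lt(sqrt(sum(res$eta^2)) / length(res$eta), 1e-10)
})
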
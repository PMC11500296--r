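# DIIS, trust-region solver and the three SCF drivers.

test_that("DIIS extrapolation satisfies its contract", {
  buf <- diis_buffer(5)
  expect_error(diis_extrapolate(buf), "empty")
  buf <- diis_push(buf, c(1, 2, 3), c(0.1, -0.1, 0))
  expect_equal(diis_extrapolate(buf), c(1, 2, 3))
  set.seed(13)
  p2 <- rnorm(3); e2 <- rnorm(3, sd = 0.05)
  buf <- diis_push(buf, p2, e2)
  out <- diis_extrapolate(buf, return_coefficients = TRUE)
  expect_equal(sum(out$coefficients), 1, tolerance = 1e-10)
  # two-vector closed form: minimize ||c e1 + (1-c) e2||^2
  e1 <- c(0.1, -0.1, 0)
  c1 <- sum(e2 * (e2 - e1)) / sum((e1 - e2)^2)
  expect_equal(out$coefficients[1], c1, tolerance = 1e-10)
  expect_equal(out$par, c1 * c(1, 2, 3) + (1 - c1) * p2, tolerance = 1e-10)
  # ring buffer caps at max_dim
  for (k in 1:10) buf <- diis_push(buf, rnorm(3), rnorm(3))
  expect_length(buf$par, 5)
})

test_that("trust-region solver: closed form, dense oracle, indefinite case", {
  # identity Hessian, interior: step is -g
  g <- c(0.3, -0.2, 0.1)
  ts <- solve_trust_region_step(function(z) z, g, radius = 10,
                                precond = rep(1, 3), tol = 1e-12)
  expect_equal(ts$step, -g, tolerance = 1e-10)
  expect_identical(ts$mu, 0)
  # dense SPD system constrained to the boundary: the returned step solves
  # the level-shifted system at the returned mu
  set.seed(21)
  A <- crossprod(matrix(rnorm(64), 8, 8)) + diag(8)
  g <- rnorm(8, sd = 5)
  ts <- solve_trust_region_step(function(z) A %*% z, g, radius = 0.5,
                                precond = diag(A), tol = 1e-12)
  expect_true(ts$on_boundary)
  expect_lte(sqrt(sum(ts$step^2)), 0.5 + 1e-12)
  dense <- solve(A + (-ts$mu) * diag(8), -g)
  expect_lt(max(abs(ts$step - dense)), 1e-8)
  # indefinite Hessian: the shift makes the operator positive definite
  # along all probed directions
  B <- A
  B[1, 1] <- -5
  ts2 <- solve_trust_region_step(function(z) B %*% z, g, radius = 0.5,
                                 precond = pmax(diag(B), 1e-2), tol = 1e-10)
  evB <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(-ts2$mu, -min(evB))   # shifted operator is PD
  expect_lte(sqrt(sum(ts2$step^2)), 0.5 + 1e-12)
})

test_that("all drivers reproduce plain RHF at zero coupling", {
  mol <- h2o_sto3g()
  hf <- rhf_h2o()
  for (alg in c("tr-nr", "gb-dbi", "gb-diis")) {
    fit <- scqed_hf(mol, cavity(lambda = 0, omega_ev = 2.71),
                    algorithm = alg)
    expect_true(fit$converged)
    expect_equal(fit$energy, hf$energy, tolerance = 1e-9)
    if (alg == "gb-dbi") {
      # eta machinery inert: parameters stay at their initialization
      expect_identical(fit$eta, fit$sys$d_diag)
    }
  }
})

test_that("tr-NR: accepted steps descend, rejected steps leave state alone", {
  fit <- cached("fit_h2o_l05_trnr",
                scqed_hf(h2o_sto3g(), cavity(lambda = 0.05, omega = 0.5),
                         algorithm = "tr-nr"))
  e <- fit$report$energy
  expect_true(all(diff(e) <= 1e-12))
  expect_true(fit$converged)
  expect_lte(fit$report$max_grad[nrow(fit$report)], 1e-10)
  expect_equal(nrow(fit$report), fit$iterations)
})

test_that("gb-DBI converges where the gradient baseline stagnates", {
  mol <- cached("mol_nh3_631g", fixture_molecule("nh3", basis = "6-31g"))
  cav <- cavity(lambda = 0.005, omega_ev = 2.71)
  dbi <- cached("fit_nh3_dbi", scqed_hf(mol, cav, algorithm = "gb-dbi"))
  diis <- cached("fit_nh3_diis",
                 scqed_hf(mol, cav, algorithm = "gb-diis",
                          control = scf_control(max_iterations = 300)))
  expect_true(dbi$converged)
  expect_false(diis$converged)
  expect_lt(dbi$iterations, diis$iterations)
  expect_lte(dbi$report$max_grad[nrow(dbi$report)], 1e-10)
  expect_equal(nrow(diis$report), diis$iterations)
})

test_that("identical configurations give bit-identical trajectories", {
  mol <- h2o_sto3g()
  cav <- cavity(lambda = 0.01, omega_ev = 2.71)
  f1 <- scqed_hf(mol, cav, algorithm = "tr-nr")
  f2 <- scqed_hf(mol, cav, algorithm = "tr-nr")
  expect_identical(f1$iterations, f2$iterations)
  expect_lt(max(abs(f1$report$energy - f2$report$energy)), 1e-12)
  expect_lt(abs(f1$energy - f2$energy), 1e-12)
})

test_that("convergence metrics match hand computation", {
  gk <- matrix(c(3e-4, -4e-4), 2, 1)
  ge <- c(1e-5, -2e-5, 2e-5)
  met <- convergence_metrics(-75.1, -75.0995, gk, ge)
  expect_equal(met$dE, 5e-4)
  expect_equal(met$max_grad, 4e-4)
  expect_equal(met$gk_scaled, 5e-4 / 2)
  expect_equal(met$ge_scaled, 3e-5 / 3)
  expect_equal(met$N_kappa, 2)
  expect_equal(met$N_eta, 3)
  first <- convergence_metrics(-75.1, NA, gk, ge)
  expect_true(is.na(first$dE))
})

test_that("the model object supports the standard S3 interface", {
  fit <- cached("fit_h2o_l05_trnr",
                scqed_hf(h2o_sto3g(), cavity(lambda = 0.05, omega = 0.5),
                         algorithm = "tr-nr"))
  expect_s3_class(fit, "scqed_hf")
  expect_output(print(fit), "converged")
  s <- summary(fit)
  expect_output(print(s), "cavity shift")
  expect_length(coef(fit), fit$sys$n)
  expect_equal(dim(coef(fit, "orbitals")), c(fit$sys$n, fit$sys$n))
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  chk <- load_checkpoint(f)
  expect_equal(chk$energy, fit$energy)
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_silent(plot(fit))
})
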
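# Geometry / config input layer and units.

test_that("XYZ reading converts Angstrom to bohr and validates input", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "hydrogen molecule", "H 0 0 0", "H 0 0 0.74"), f)
  mol <- read_xyz(f)
  expect_equal(mol$n_electrons, 2L)
  expect_equal(sqrt(sum((mol$coords[2, ] - mol$coords[1, ])^2)),
               0.74 / 0.52917721092, tolerance = 1e-10)

  writeLines(c("3", "broken", "H 0 0 0", "H 0 0 0.74"), f)
  expect_error(read_xyz(f), "atom lines")
  writeLines(c("1", "bad element", "Xx 0 0 0"), f)
  expect_error(read_xyz(f), "unknown element")
})

test_that("XYZ write/read round-trips coordinates to 1e-10 bohr", {
  mol <- fixture_molecule("nh3", basis = "sto-3g")
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(mol, f, comment = "roundtrip")
  mol2 <- read_xyz(f)
  expect_lt(max(abs(mol$coords - mol2$coords)), 1e-10)
})

test_that("electron counting honours total charge and closed-shell rule", {
  expect_equal(h2o_sto3g()$n_electrons, 10L)   # sum(Z) - 0
  nh4 <- fixture_molecule("nh4+")
  expect_equal(nh4$charge, 1L)
  expect_equal(nh4$n_electrons, 10L)           # 7 + 4 - 1
  expect_error(molecule("N", matrix(0, 1, 3), charge = 0), "odd electron")
})

test_that("cavity constructor enforces units and invariants", {
  cav <- cavity(lambda = 0.005, omega_ev = 2.71)
  expect_equal(cav$omega, 2.71 / 27.211386, tolerance = 1e-12)
  expect_equal(cav$omega, 0.099592, tolerance = 3e-5)
  expect_error(cavity(lambda = -0.01, omega_ev = 2.71), "lambda")
  expect_error(cavity(lambda = 0.01, omega = -1), "frequency")
  expect_error(cavity(lambda = 0.01, omega_ev = 2.71,
                      polarization = c(0, 0, 2)), "unit")
  expect_silent(cavity(lambda = 0, omega_ev = 2.71,
                       polarization = c(0, 0, 1)))
})

test_that("config loader resolves geometry, converts units and validates", {
  dir <- withr::local_tempdir()
  write_xyz(h2o_sto3g(), file.path(dir, "w.xyz"))
  cfg_path <- file.path(dir, "run.yaml")
  writeLines(c(
    "geometry: w.xyz", "charge: 0", "basis: sto-3g", "coupling: 0.005",
    "frequency_ev: 2.71", "polarization: [0, 0, 1]", "algorithm: tr-nr",
    "max_iterations: 25"), cfg_path)
  cfg <- load_config(cfg_path)
  expect_s3_class(cfg$molecule, "molecule")
  expect_equal(cfg$cavity$lambda, 0.005)
  expect_equal(cfg$cavity$omega, 2.71 / 27.211386)
  expect_equal(cfg$control$max_iterations, 25)
  writeLines(c("geometry: w.xyz", "basis: sto-3g", "coupling: -1",
               "frequency_ev: 2.71", "polarization: [0, 0, 1]"), cfg_path)
  expect_error(load_config(cfg_path), "coupling")
  writeLines(c("geometry: w.xyz", "basis: sto-3g"), cfg_path)
  expect_error(load_config(cfg_path), "missing required")
})

test_that("AO integral sets satisfy their structural invariants", {
  ints <- cached("ints_h2", ao_integrals(h2_sto3g()))
  expect_lt(max(abs(ints$S - t(ints$S))), 1e-12)
  expect_lt(max(abs(ints$hcore - t(ints$hcore))), 1e-12)
  g <- ints$eri
  # 8-fold permutational symmetry
  expect_equal(g, aperm(g, c(2, 1, 3, 4)), tolerance = 1e-12)
  expect_equal(g, aperm(g, c(1, 2, 4, 3)), tolerance = 1e-12)
  expect_equal(g, aperm(g, c(3, 4, 1, 2)), tolerance = 1e-12)
  # nuclear dipole
  nh4 <- fixture_molecule("nh4+")
  i2 <- ao_integrals(nh4)
  z <- c(7, 1, 1, 1, 1)
  expect_equal(i2$d_nuc, colSums(nh4$coords * z), tolerance = 1e-12)
  # water/6-31G overlap positive definite
  w631 <- cached("ints_h2o_631g",
                 ao_integrals(fixture_molecule("h2o", basis = "6-31g")))
  expect_gt(min(eigen(w631$S, symmetric = TRUE, only.values = TRUE)$values),
            0)
  # determinism
  ints_b <- ao_integrals(h2_sto3g())
  expect_identical(ints$eri, ints_b$eri)
  expect_identical(ints$hcore, ints_b$hcore)
})

test_that("integral engine matches closed-form s-Gaussian formulas (H2)", {
  # independent oracle: textbook closed forms for s-type Gaussians
  boys0 <- function(t) {
    ifelse(t < 1e-12, 1 - t / 3,
           0.5 * sqrt(pi / t) * 2 * stats::pnorm(sqrt(2 * t)) - 0.5 *
             sqrt(pi / t))
  }
  s_ov <- function(a, b, A, B) {
    (pi / (a + b))^1.5 * exp(-a * b / (a + b) * sum((A - B)^2))
  }
  s_eri <- function(a, b, cc, d, A, B, C, D) {
    p <- a + b; q <- cc + d
    P <- (a * A + b * B) / p; Q <- (cc * C + d * D) / q
    2 * pi^2.5 / (p * q * sqrt(p + q)) *
      exp(-a * b / p * sum((A - B)^2)) * exp(-cc * d / q * sum((C - D)^2)) *
      boys0(p * q / (p + q) * sum((P - Q)^2))
  }
  mol <- h2_sto3g()
  ints <- cached("ints_h2", ao_integrals(mol))
  sh <- scqedhf:::build_shells(mol)
  S0 <- matrix(0, 2, 2)
  G0 <- array(0, rep(2, 4))
  for (i in 1:2) for (j in 1:2) {
    for (a in 1:3) for (b in 1:3) {
      S0[i, j] <- S0[i, j] + sh[[i]]$coef[a] * sh[[j]]$coef[b] *
        s_ov(sh[[i]]$alpha[a], sh[[j]]$alpha[b], sh[[i]]$center,
             sh[[j]]$center)
    }
  }
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
    acc <- 0
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (d in 1:3) {
      acc <- acc + sh[[i]]$coef[a] * sh[[j]]$coef[b] * sh[[k]]$coef[cc] *
        sh[[l]]$coef[d] *
        s_eri(sh[[i]]$alpha[a], sh[[j]]$alpha[b], sh[[k]]$alpha[cc],
              sh[[l]]$alpha[d], sh[[i]]$center, sh[[j]]$center,
              sh[[k]]$center, sh[[l]]$center)
    }
    G0[i, j, k, l] <- acc
  }
  expect_lt(max(abs(S0 - ints$S)), 1e-12)
  expect_lt(max(abs(G0 - ints$eri)), 1e-12)
})

test_that("stored STO-3G exponents follow the Slater-zeta scaling rule", {
  # every element's 2sp exponents are the universal 3-Gaussian expansion
  # scaled by zeta^2, so exponent ratios across elements are constant
  b <- load_basis("sto-3g")
  sp_c <- b$C[[2]]$alpha
  sp_n <- b$N[[2]]$alpha
  sp_o <- b$O[[2]]$alpha
  expect_equal(sd(sp_n / sp_c) / mean(sp_n / sp_c), 0, tolerance = 1e-6)
  expect_equal(sd(sp_o / sp_c) / mean(sp_o / sp_c), 0, tolerance = 1e-6)
})
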
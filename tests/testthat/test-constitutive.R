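test_that("isotropic stiffness entries follow the closed form", {
  tns <- build_tensors(material_bone())
  E <- 22e9; nu <- 0.32
  f <- E / ((1 + nu) * (1 - 2 * nu))
  expect_equal(tns$C[1, 1], f * (1 - nu), tolerance = 1e-14)  # 31.48 GPa
  expect_equal(tns$C[4, 4], E / (2 * (1 + nu)), tolerance = 1e-14)  # 8.333 GPa
  expect_equal(tns$C[1, 2], f * nu, tolerance = 1e-14)
  expect_true(isSymmetric(tns$C))
  expect_true(all(eigen(tns$C, symmetric = TRUE, only.values = TRUE)$values > 0))

  # nu -> 0 degenerates to uncoupled axes: C11 = E, C12 = 0, C44 = E/2
  t0 <- build_tensors(phase_material(10, 1e-9))
  expect_equal(t0$C[1, 1], 10e9, tolerance = 1e-6)
  expect_lt(abs(t0$C[1, 2]), 1e-6 * t0$C[1, 1])
  expect_equal(t0$C[4, 4], 5e9, tolerance = 1e-6)
})

test_that("piezoelectric tensor carries the shear-mode sparsity", {
  tns <- build_tensors(material_bone())
  e <- tns$e
  expect_equal(e[1, 5], 3.0e-3)
  expect_equal(e[2, 6], -3.0e-3)
  e[1, 5] <- 0; e[2, 6] <- 0
  expect_equal(max(abs(e)), 0)
  # marrow has no piezoelectric coupling, bone no conduction/viscosity
  tm <- build_tensors(material_marrow())
  expect_equal(max(abs(tm$e)), 0)
  expect_equal(tns$kappa[1, 1], 0)
  expect_equal(tns$mu_v, 0)
})

test_that("material parameter validation rejects unphysical inputs", {
  expect_error(phase_material(-1, 0.3), "positive")
  expect_error(phase_material(1, 0.5), "Poisson")
  expect_error(build_tensors(structure(list(E = 1, nu = 0.5), class = "phase_material")))
})

test_that("deviatoric projector removes hydrostatic parts, keeps shears", {
  expect_equal(deviatoric(c(1, 1, 1, 0, 0, 0)), rep(0, 6))
  expect_equal(deviatoric(c(1, 0, 0, 0, 0, 0)), c(2/3, -1/3, -1/3, 0, 0, 0))
  s <- c(0, 0, 0, 1.5, -2, 0.3)
  expect_equal(deviatoric(s), s)
  # idempotent and trace-free on random stresses
  set.seed(42)
  for (i in 1:5) {
    s <- rnorm(6)
    d <- deviatoric(s)
    expect_equal(sum(d[1:3]), 0, tolerance = 1e-15)
    expect_equal(deviatoric(d), d, tolerance = 1e-14)
  }
})

test_that("constitutive fluxes follow the two-phase laws", {
  tb <- build_tensors(material_bone())
  tm <- build_tensors(material_marrow())
  z <- evaluate_fluxes(numeric(6), numeric(3), numeric(3), tb)
  expect_true(all(vapply(z, function(v) all(v == 0), logical(1L))))

  # fully relaxed marrow: eps == eps_i gives zero stress
  eps <- c(1, -2, 0.5, 0.1, 0, 0.3) * 1e-4
  fm <- evaluate_fluxes(eps, numeric(3), numeric(3), tm, eps_i = eps)
  expect_equal(max(abs(fm$sigma)), 0, tolerance = 1e-20)

  # bone under pure E_x: single stress component, Voigt slot 5 (yz)
  fb <- evaluate_fluxes(numeric(6), c(1, 0, 0), numeric(3), tb)
  oracle <- -t(tb$e) %*% c(1, 0, 0)
  expect_equal(fb$sigma, drop(oracle))
  expect_equal(which(fb$sigma != 0), 5L)
  expect_equal(fb$sigma[5], -3.0e-3)

  # Ohm's law in marrow, none in bone
  fE <- evaluate_fluxes(numeric(6), c(2, -1, 3), numeric(3), tm)
  expect_equal(fE$J, 1e4 * c(2, -1, 3))
  expect_equal(evaluate_fluxes(numeric(6), c(2, -1, 3), numeric(3), tb)$J,
               numeric(3))
})

test_that("inelastic strain evolution is trace-free over many steps", {
  set.seed(7)
  mu_v <- 5e-13; dt <- 1e-3
  eps_i <- numeric(6)
  for (n in 1:200) {
    sigma <- rnorm(6) * 1e5
    eps_i <- evolve_inelastic_strain(eps_i, sigma, mu_v, dt)
    expect_lt(abs(sum(eps_i[1:3])),
              1e-14 * sqrt(sum(eps_i^2)) + 1e-20)
  }
  # hydrostatic stress and mu_v = 0 leave the state unchanged
  expect_equal(evolve_inelastic_strain(eps_i, c(5, 5, 5, 0, 0, 0), mu_v, dt), eps_i)
  expect_equal(evolve_inelastic_strain(eps_i, rnorm(6), 0, dt), eps_i)
  expect_error(evolve_inelastic_strain(eps_i, rnorm(6), mu_v, -1), "negative")
})

test_that("one explicit step from zero reproduces the hand-computed value", {
  # dt * mu_v = 1, sigma = (1,0,0,0,0,0) Pa -> deviatoric projection
  out <- evolve_inelastic_strain(numeric(6), c(1, 0, 0, 0, 0, 0),
                                 mu_v = 1, dt = 1)
  expect_equal(out, c(2/3, -1/3, -1/3, 0, 0, 0))
})

test_that("consistent tangent matches finite differences of the step update", {
  tm <- build_tensors(material_marrow(dt = 1e-3))
  dt <- 1e-3
  Ct <- tangent_stiffness(tm, dt)
  set.seed(11)
  eps0 <- rnorm(6) * 1e-5
  eps_i <- deviatoric(rnorm(6) * 1e-6)
  h <- 1e-9
  fd <- matrix(0, 6, 6)
  for (j in 1:6) {
    ep <- eps0; em <- eps0
    ep[j] <- ep[j] + h; em[j] <- em[j] - h
    fd[, j] <- (osteoFE2:::marrow_step_stress(ep, eps_i, tm, dt) -
                  osteoFE2:::marrow_step_stress(em, eps_i, tm, dt)) / (2 * h)
  }
  expect_rel_equal(fd, Ct, 1e-6)
  # bone tangent is the elastic stiffness; mu_v = 0 reduces marrow likewise
  tb <- build_tensors(material_bone())
  expect_identical(tangent_stiffness(tb, dt), tb$C)
  tm0 <- tm; tm0$mu_v <- 0
  expect_identical(tangent_stiffness(tm0, dt), tm$C)
})

test_that("current density is proportional to the conductivity at fixed E", {
  E <- c(1, 2, -0.5)
  J1 <- evaluate_fluxes(numeric(6), E, numeric(3),
                        build_tensors(material_marrow(kappa1 = 1e2)))$J
  J2 <- evaluate_fluxes(numeric(6), E, numeric(3),
                        build_tensors(material_marrow(kappa1 = 1e4)))$J
  expect_equal(J2, 100 * J1)
})
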
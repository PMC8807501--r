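test_that("alpha parameters follow the spectral-radius formulas", {
  expect_equal(alpha_parameters(1), list(alpha_m = 0.5, alpha_f = 0.5,
                                         gamma_a = 0.5))
  expect_equal(alpha_parameters(0.5), list(alpha_m = 5/6, alpha_f = 2/3,
                                           gamma_a = 2/3))
  expect_equal(alpha_parameters(0), list(alpha_m = 1.5, alpha_f = 1,
                                         gamma_a = 1))
  expect_error(alpha_parameters(1.2), "rho_inf")
  expect_error(alpha_parameters(-0.1), "rho_inf")
})

test_that("generalized tangent is the printed linear combination", {
  cfg <- time_config(rho_inf = 0.5, dt = 1)
  a <- cfg$alpha
  # scalar substitution: coefficients on identity M, C, K
  S <- effective_tangent(diag(2), diag(2), diag(2), cfg)
  coef <- a$alpha_m^2 / (a$alpha_f * a$gamma_a^2) + a$alpha_m / a$gamma_a +
    a$alpha_f
  expect_equal(S, coef * diag(2))
  # M = C = 0 leaves alpha_f * K
  expect_equal(effective_tangent(0 * diag(2), 0 * diag(2), diag(2), cfg),
               a$alpha_f * diag(2))
  # doubling dt divides the M coefficient by 4 and the C coefficient by 2
  cfg2 <- time_config(rho_inf = 0.5, dt = 2)
  SM1 <- effective_tangent(diag(2), 0 * diag(2), 0 * diag(2), cfg)
  SM2 <- effective_tangent(diag(2), 0 * diag(2), 0 * diag(2), cfg2)
  expect_equal(SM1, 4 * SM2)
  SC1 <- effective_tangent(0 * diag(2), diag(2), 0 * diag(2), cfg)
  SC2 <- effective_tangent(0 * diag(2), diag(2), 0 * diag(2), cfg2)
  expect_equal(SC1, 2 * SC2)
})

test_that("update recurrences reproduce the printed tangent coefficients", {
  # independent derivation: differentiate the scheme's recurrences for
  # (d, v, vdot) at the evaluation points with respect to d_{n+1}
  a <- alpha_parameters(0.5)
  dt <- 0.37
  dud1 <- 1 / (a$gamma_a * dt)                 # d ud_{n+1} / d d_{n+1}
  dudam <- a$alpha_m * dud1
  dv1 <- dudam / a$alpha_f
  dvd1 <- dv1 / (a$gamma_a * dt)
  expect_equal(a$alpha_f * dv1, a$alpha_m / (a$gamma_a * dt))
  expect_equal(a$alpha_m * dvd1,
               a$alpha_m^2 / (a$alpha_f * a$gamma_a^2 * dt^2))
})

test_that("quiescent state with zero loads stays quiescent", {
  rve <- tiny_rve()
  cfg <- time_config(dt = 1e-3, n_steps = 3)
  res <- transient_solve(rve$model, rve$constr,
                         matrix(0, 12, 3), cfg)
  expect_equal(max(abs(res$state$d)), 0)
  expect_equal(max(abs(res$state$v)), 0)
  expect_equal(res$newton_iters, rep(0L, 3))
})

test_that("the linear coupled problem converges in one Newton correction", {
  rve <- coarse_rve()
  cfg <- time_config(dt = 1e-3, n_steps = 5)
  res <- solve_rve(rve, macro_state(eps_bar = c(0, 0, 0, 0, 1e-5, 0)), cfg)
  expect_true(all(res$newton_iters <= 1L))
  expect_gt(max(abs(res$state$d)), 0)
})

test_that("held strain relaxes the marrow stress like the scalar recurrence", {
  # homogeneous viscoelastic cell under a held deviatoric macro strain:
  # the micro fields are uniform, so the step update reduces to a scalar
  # geometric recurrence for the deviatoric stress
  mu_v_gpa_s <- 50           # exaggerated viscosity so decay shows quickly
  mats <- homogeneous_materials(mu_v = mu_v_gpa_s)
  rve <- tiny_rve(materials = mats)
  cfg <- time_config(dt = 1e-3, n_steps = 30)
  gam <- 1e-4
  res <- solve_rve(rve, macro_state(eps_bar = c(0, 0, 0, gam, 0, 0)), cfg)
  s_xy <- vapply(res$avg, function(a) a$sigma[4], numeric(1L))

  # oracle: independent pointwise recurrence of the one-step law
  tm <- build_tensors(mats$marrow)
  eps <- c(0, 0, 0, gam, 0, 0)
  eps_i <- numeric(6)
  oracle <- numeric(cfg$n_steps)
  for (n in seq_len(cfg$n_steps)) {
    s_tr <- tm$C %*% (eps - eps_i)
    eps_i <- eps_i + cfg$dt * tm$mu_v * deviatoric(drop(s_tr))
    oracle[n] <- (tm$C %*% (eps - eps_i))[4]
  }
  expect_rel_equal(s_xy, oracle, 1e-8)
  expect_true(all(diff(s_xy) < 0))            # monotone relaxation
  expect_lt(s_xy[30], s_xy[1])
})

test_that("trace of the inelastic strain stays at machine zero while stepping", {
  rve <- tiny_rve()
  cfg <- time_config(dt = 1e-3, n_steps = 10)
  res <- solve_rve(rve, macro_state(eps_bar = c(1, 0, 0, 0, 1, 0) * 1e-5), cfg)
  ei <- res$state$eps_i
  expect_lt(max(abs(colSums(ei[1:3, ]))), 1e-14 * sqrt(sum(ei^2)) + 1e-20)
})
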
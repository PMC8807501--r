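test_that("operator matrices reproduce affine fields exactly (patch consistency)", {
  set.seed(3)
  # a randomly stretched box and a sheared (non-box) hexahedron
  X1 <- sweep((osteoFE2:::hex_local_nodes() + 1) / 2, 2L, c(0.4, 0.7, 1.2), "*")
  X2 <- X1 + 0.05 * matrix(rnorm(24), 8, 3)
  for (X in list(X1, X2)) {
    eps_star <- c(1, -2, 0.5, 0.3, -0.7, 0.2) * 1e-3
    emat <- matrix(c(eps_star[1], eps_star[4]/2, eps_star[6]/2,
                     eps_star[4]/2, eps_star[2], eps_star[5]/2,
                     eps_star[6]/2, eps_star[5]/2, eps_star[3]), 3, 3)
    uhat <- as.vector(t(X %*% emat))          # nodal u from the affine field
    g <- c(2, -1, 0.5)
    phihat <- drop(X %*% g)                   # linear potential
    for (xi in list(c(0, 0, 0), c(0.3, -0.8, 0.5))) {
      op <- operator_matrices(X, xi)
      expect_equal(drop(op$B_u %*% uhat), eps_star, tolerance = 1e-12)
      expect_equal(drop(op$B_grad %*% phihat), g, tolerance = 1e-12)
    }
  }
})

test_that("curl and divergence operators are exact on linear vector fields", {
  X <- sweep((osteoFE2:::hex_local_nodes() + 1) / 2, 2L, c(1, 1, 1), "*")
  # A = (-y/2, x/2, 0) has curl (0,0,1) and zero divergence
  Ahat <- as.vector(t(cbind(-X[, 2] / 2, X[, 1] / 2, 0)))
  op <- operator_matrices(X, c(0.2, -0.4, 0.9))
  expect_equal(drop(op$B_curl %*% Ahat), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(drop(op$B_div %*% Ahat), 0, tolerance = 1e-12)
  # constant nodal A: curl and divergence vanish
  Aconst <- as.vector(t(matrix(c(3, -2, 5), 8, 3, byrow = TRUE)))
  expect_equal(max(abs(op$B_curl %*% Aconst)), 0, tolerance = 1e-12)
  expect_equal(max(abs(op$B_div %*% Aconst)), 0, tolerance = 1e-12)
  # inverted geometry (negative Jacobian) is rejected
  Xbad <- X; Xbad[, 1] <- -X[, 1]
  expect_error(operator_matrices(Xbad, c(0, 0, 0)), "Jacobian")
})

test_that("2-point quadrature is exact against a 4-point oracle on boxes", {
  X <- sweep((osteoFE2:::hex_local_nodes() + 1) / 2, 2L, c(0.5, 0.8, 1.1), "*")
  tns <- build_tensors(material_bone())
  b2 <- element_matrices(X, tns, gamma = 1, dt = 1e-3, nquad = 2L)
  b4 <- element_matrices(X, tns, gamma = 1, dt = 1e-3, nquad = 4L)
  for (nm in c("Kuu", "Kup", "Kpu", "Kpp", "KAA", "CuA", "MAA"))
    expect_rel_equal(b2[[nm]], b4[[nm]], 1e-12)
  expect_equal(b2$volume, prod(c(0.5, 0.8, 1.1)), tolerance = 1e-13)
})

test_that("element blocks vanish where the physics decouples", {
  X <- (osteoFE2:::hex_local_nodes() + 1) / 2
  tb <- element_matrices(X, build_tensors(material_bone()))     # kappa = 0
  expect_equal(max(abs(tb$KAp)), 0)
  expect_equal(max(abs(tb$CAA)), 0)
  tm <- element_matrices(X, build_tensors(material_marrow()))   # e = 0
  for (nm in c("Kup", "Kpu", "CuA", "CAu"))
    expect_equal(max(abs(tm[[nm]])), 0)
})

test_that("mechanical stiffness has zero force on rigid translations", {
  X <- (osteoFE2:::hex_local_nodes() + 1) / 2 + 0.03 * matrix(rnorm(24), 8, 3)
  blk <- element_matrices(X, build_tensors(material_bone()))
  for (dir in 1:3) {
    rigid <- rep(0, 24); rigid[seq(dir, 24, 3)] <- 1
    expect_lt(max(abs(blk$Kuu %*% rigid)), 1e-6 * max(abs(blk$Kuu)))
  }
})

test_that("assembled operators have the block structure of the coupled system", {
  rve <- tiny_rve()
  m <- rve$model
  nnode <- nrow(m$mesh$nodes)
  u <- osteoFE2:::field_dofs(nnode, "u")
  phi <- osteoFE2:::field_dofs(nnode, "phi")
  A <- osteoFE2:::field_dofs(nnode, "A")
  # M: only the A-A permittivity mass block
  expect_gt(sum(abs(m$M[A, A])), 0)
  expect_equal(sum(abs(m$M)) - sum(abs(m$M[A, A])), 0)
  # K: no u-A coupling in either direction
  expect_equal(sum(abs(m$K[u, A])), 0)
  expect_equal(sum(abs(m$K[A, u])), 0)
  # C: no u-u and no phi-phi blocks
  expect_equal(sum(abs(m$C[u, u])), 0)
  expect_equal(sum(abs(m$C[phi, phi])), 0)
})

test_that("static patch test: affine macro state is reproduced exactly", {
  # a homogeneous RVE under any macro state has zero fluctuations, so the
  # quadrature-point states must equal the imposed macro state everywhere
  rve <- tiny_rve(materials = homogeneous_materials())
  p <- macro_state(eps_bar = c(2, -1, 0.5, 1, -0.3, 0.7) * 1e-5,
                   E_bar = c(3, -2, 1), B_bar = c(0.1, 0.2, -0.4) * 1e-3)
  d <- solve_static(rve$model, rve$constr, p)
  st <- qp_states(rve$model, d)
  expect_rel_equal(st$eps, matrix(p[1:6], 6, rve$model$nqp), 1e-10)
  expect_rel_equal(st$E, matrix(p[7:9], 3, rve$model$nqp), 1e-10)
  expect_rel_equal(st$B, matrix(p[10:12], 3, rve$model$nqp), 1e-10)
})

test_that("zero state with zero loads has zero residual and zero solution", {
  rve <- tiny_rve()
  d <- solve_static(rve$model, rve$constr, macro_state())
  expect_equal(max(abs(d)), 0, tolerance = 1e-30)
})

test_that("micro solutions are periodic on paired nodes", {
  rve <- coarse_rve()
  p <- macro_state(eps_bar = c(0, 0, 0, 0, 1e-5, 0))
  d <- solve_static(rve$model, rve$constr, p)
  fluct <- d - as.numeric(rve$constr$P %*% p)
  pairs <- rve$mesh$periodic_pairs
  ds <- matrix(fluct, nrow = 7L)
  expect_lt(max(abs(ds[, pairs[, "slave"]] - ds[, pairs[, "master"]])),
            1e-12 * max(abs(ds)) + 1e-30)
  expect_equal(max(abs(ds[, attr(pairs, "fixed_nodes")])), 0)
})
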
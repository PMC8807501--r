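test_that("smoothstep load amplitude has the right endpoints and symmetry", {
  n <- 40
  expect_equal(load_amplitude(0, n), 0)
  expect_equal(load_amplitude(n, n), 1)
  expect_equal(load_amplitude(n / 2, n), 0.5)
  a <- load_amplitude(0:n, n)
  expect_true(all(diff(a) >= 0))
  # derivative maximal at mid-run, zero slope at the ends
  da <- diff(a)
  expect_equal(which.max(da), n / 2, tolerance = 1)
  expect_lt(da[1], da[n / 2])
  expect_lt(da[n], da[n / 2])
})

test_that("butterfly cylinder mesh is conforming with correct volume and sets", {
  mesh <- build_cylinder_mesh(length = 0.30, radius = 0.015,
                              nsq = 6L, nr = 2L, nz = 10L)
  v <- element_volumes(mesh)          # errors if any Jacobian is degenerate
  expect_true(all(v > 0))
  expect_equal(sum(v), pi * 0.015^2 * 0.30, tolerance = 0.02)
  expect_equal(length(mesh$face_sets$zmin), length(mesh$face_sets$zmax))
  # all outer-boundary nodes lie inside the circle, boundary ring on it
  r <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  expect_lt(max(r), 0.015 + 1e-12)
  expect_error(build_cylinder_mesh(nsq = 1L), "resolution")
})

test_that("reference resolution reproduces the documented mesh size", {
  mesh <- build_cylinder_mesh()
  expect_equal(nrow(mesh$nodes), 1767L)
  expect_equal(nrow(mesh$conn), 1440L)
})

test_that("grounded and driven node sets satisfy their geometric definitions", {
  macro <- macro_cylinder_model(nsq = 4L, nr = 2L, nz = 10L)
  nodes <- macro$mesh$nodes
  g <- macro$grounded_set
  expect_gt(length(g), 0)
  expect_true(all(sqrt(nodes[g, 1]^2 + nodes[g, 2]^2) < 0.0075))
  expect_true(all(abs(nodes[g, 3]) < 1e-12))
  b <- macro$driven_set
  expect_true(all(abs(nodes[b, 3] - 0.15) <= 0.015 + 1e-9))
  # driven band does not intersect the clamped faces
  expect_length(intersect(b, c(macro$fixed_sets$left, macro$fixed_sets$right)), 0)
})

test_that("field statistics reduce correctly for constant and two-region fields", {
  rve <- tiny_rve()
  m <- rve$model
  const <- matrix(c(3, 4, 0), 3, m$nqp)      # |c| = 5 everywhere
  fl <- list(sigma = matrix(0, 6, m$nqp), D = const, H = const, J = const)
  st <- field_statistics(m, fl)
  expect_equal(unname(st["avg_H"]), 5, tolerance = 1e-12)
  expect_equal(unname(st["max_H"]), 5, tolerance = 1e-12)
  expect_equal(unname(st["mag_avg_H"]), 5, tolerance = 1e-12)
  # sign flip leaves magnitude summaries unchanged
  st2 <- field_statistics(m, lapply(fl, function(x) -x))
  expect_equal(st2[c("avg_D", "max_D")], st[c("avg_D", "max_D")])
  # two-region field: volume-weighted mean of magnitudes
  f <- matrix(0, 3, m$nqp)
  f[1, m$qp_phase == "bone"] <- 2
  f[1, m$qp_phase == "marrow"] <- 1
  fl$H <- f
  rho <- rve$params$rho_b
  st3 <- field_statistics(m, fl)
  expect_equal(unname(st3["avg_H"]), 2 * rho + (1 - rho), tolerance = 1e-12)
  expect_equal(unname(st3["max_H"]), 2)
})

test_that("maxima dominate averages in every recorded summary", {
  rve <- tiny_rve(dt = 1e-2)
  tg <- perturbation_tangents(rve)
  macro <- macro_cylinder_model(nsq = 2L, nr = 1L, nz = 4L, length = 0.1)
  cfg <- time_config(dt = 1e-2, n_steps = 6)
  res <- fe2_run(macro, rve, cfg, mode = "cached", tangents = tg)
  s <- res$summary
  for (nm in c("D", "H", "J")) {
    expect_true(all(s[[paste0("max_", nm)]] >= s[[paste0("avg_", nm)]] - 1e-30))
    expect_true(all(s[[paste0("avg_", nm)]] >= 0))
  }
})

test_that("zero prescribed displacement produces an identically zero response", {
  rve <- tiny_rve(dt = 1e-2)
  tg <- perturbation_tangents(rve)
  macro <- macro_cylinder_model(nsq = 2L, nr = 1L, nz = 4L, length = 0.1,
                                u_max = 1)
  macro$constr$P <- 0 * macro$constr$P
  cfg <- time_config(dt = 1e-2, n_steps = 3)
  res <- fe2_run(macro, rve, cfg, mode = "cached", tangents = tg)
  expect_equal(max(abs(res$state$d)), 0)
})

test_that("cached tangents reproduce the full nested FE2 solve for linear RVEs", {
  mats <- list(bone = material_bone(),
               marrow = phase_material(2, 0.3, name = "marrow"))  # mu_v = 0
  rve <- tiny_rve(dt = 1e-2, materials = mats)
  tg <- perturbation_tangents(rve)
  macro <- macro_cylinder_model(nsq = 2L, nr = 1L, nz = 4L, length = 0.1)
  cfg <- time_config(dt = 1e-2, n_steps = 3)
  rc <- fe2_run(macro, rve, cfg, mode = "cached", tangents = tg)
  rf <- fe2_run(macro, rve, cfg, mode = "full", tangents = tg)
  expect_rel_equal(rf$summary$avg_H, rc$summary$avg_H, 0.01)
  expect_rel_equal(rf$summary$avg_D, rc$summary$avg_D, 0.01)
  sel <- setdiff(seq_len(length(rc$state$d)), osteoFE2:::field_dofs(
    nrow(macro$mesh$nodes), "A"))
  expect_rel_equal(rf$state$d[sel], rc$state$d[sel], 1e-8)
})
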
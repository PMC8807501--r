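# Shared fixture builders. Everything is generated in code; the "tiny" RVE
# (one element per segment, 3^3 elements) keeps constraint and transient
# tests fast while exercising the full two-phase machinery.

tiny_rve <- function(dt = 1e-3, materials = NULL)
  rve_problem(rve_params(0.32, 0.36, 1), dt = dt, materials = materials)

coarse_rve <- function(dt = 1e-3, materials = NULL)
  rve_problem(rve_params(0.32, 0.36, 2), dt = dt, materials = materials)

# truly identical phases, no piezoelectricity: the uniform-field solution
# is the exact periodic solution for any macro state
homogeneous_materials <- function(kappa1 = 0, mu_v = 0) {
  m <- phase_material(E_GPa = 5, nu = 0.3, kappa1 = kappa1,
                      mu_v = mu_v, name = "marrow")
  b <- m; b$name <- "bone"
  class(b) <- "phase_material"
  list(bone = b, marrow = m)
}

# a single unit-cube element mesh (vertices of [0,1]^3)
unit_cube_mesh <- function() {
  g <- osteoFE2:::structured_hex_grid(c(0, 1), c(0, 1), c(0, 1))
  osteoFE2:::new_hex_mesh(g$nodes, g$conn, phase = "bone")
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y), .Machine$double.xmin), tol)
}
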
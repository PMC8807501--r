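#' Impose a macro state on a periodic RVE
#'
#' Packs a macroscopic state (Voigt strain, electric field, magnetic flux
#' density) into the 12-component parameter vector of
#' [periodic_constraints()], which realizes it as affine nodal fields plus
#' periodic fluctuations.
#'
#' @param eps_bar Voigt 6-vector macro strain
#' @param E_bar macro electric field 3-vector (V/m)
#' @param B_bar macro magnetic flux density 3-vector (T)
#' @return numeric parameter vector of length 12
#' @export
macro_state <- function(eps_bar = numeric(6), E_bar = numeric(3),
                        B_bar = numeric(3)) {
  stopifnot(length(eps_bar) == 6L, length(E_bar) == 3L, length(B_bar) == 3L,
            all(is.finite(c(eps_bar, E_bar, B_bar))))
  c(eps_bar, E_bar, B_bar)
}

#' Assemble the micro model of a bone RVE
#'
#' Convenience constructor: builds the mesh from the lengths parameters,
#' the two default phase materials (viscosity tied to the configured time
#' increment) and the periodic constraint set.
#'
#' @param params an [rve_params()]
#' @param dt micro time increment (s); enters the marrow viscosity default
#' @param gamma divergence gauge penalty
#' @param materials optional override list with `bone`/`marrow`
#'   [phase_material()] entries
#' @return list with `model` ([fe_model()]), `constr`, `mesh`, `params`
#' @export
rve_problem <- function(params, dt = 1e-3, gamma = 1.0, materials = NULL) {
  mesh <- build_rve_mesh(params)
  if (is.null(materials))
    materials <- list(bone = material_bone(), marrow = material_marrow(dt = dt))
  tensors <- lapply(materials, build_tensors)
  names(tensors) <- names(materials)
  model <- fe_model(mesh, tensors, gamma = gamma, dt = dt)
  constr <- periodic_constraints(mesh)
  list(model = model, constr = constr, mesh = mesh, params = params)
}

#' Transient micro solve of an RVE under a macro-state history
#'
#' Advances the periodic micro problem with the JWH-alpha scheme and
#' returns the volume-averaged fluxes sent back to the macroscale each
#' step together with the final internal state.
#'
#' @param rve an [rve_problem()]
#' @param macro_history 12 x n_steps matrix of [macro_state()] columns, or a
#'   single state recycled over `cfg$n_steps`
#' @param cfg a [time_config()]
#' @return see [transient_solve()]
#' @export
solve_rve <- function(rve, macro_history, cfg) {
  if (!is.matrix(macro_history))
    macro_history <- matrix(macro_history, nrow = 12L, ncol = cfg$n_steps)
  transient_solve(rve$model, rve$constr, macro_history, cfg)
}

#' Effective tangents by numerical perturbation
#'
#' Computes the five homogenized moduli (stiffness, permittivity,
#' piezoelectric coupling, inverse permeability, conductivity) column by
#' column: each macro-state component is perturbed by `delta_tol` about the
#' given base state, the stationary periodic micro problem is solved, and
#' the forward difference of the volume-averaged fluxes yields one column.
#' The micro problem is linear, so the result is independent of the
#' perturbation size and is computed once and reused for all macro points
#' and time steps.
#'
#' @param rve an [rve_problem()]
#' @param base_state base [macro_state()] (zero by default)
#' @param delta_tol perturbation increment
#' @return list of class `effective_tangents` with `C_bar` (6x6, Pa),
#'   `xi_bar` (3x3), `e_bar` (3x6), `mu_inv_bar` (3x3), `kappa_bar` (3x3)
#'   and `delta_tol`
#' @export
perturbation_tangents <- function(rve, base_state = macro_state(),
                                  delta_tol = 1e-8) {
  model <- rve$model; constr <- rve$constr
  solver <- static_solver(model, constr)
  base_fl <- static_avg_fluxes(model, constr, base_state, solver)
  cols <- lapply(seq_len(12L), function(i) {
    p <- base_state; p[i] <- p[i] + delta_tol
    fl <- static_avg_fluxes(model, constr, p, solver)
    lapply(names(base_fl), function(nm) (fl[[nm]] - base_fl[[nm]]) / delta_tol)
  })
  getcol <- function(i, nm) cols[[i]][[match(nm, c("sigma", "D", "H", "J"))]]
  structure(list(
    C_bar = vapply(1:6, getcol, numeric(6), nm = "sigma"),
    e_bar = vapply(1:6, getcol, numeric(3), nm = "D"),
    xi_bar = vapply(7:9, getcol, numeric(3), nm = "D"),
    kappa_bar = vapply(7:9, getcol, numeric(3), nm = "J"),
    mu_inv_bar = vapply(10:12, getcol, numeric(3), nm = "H"),
    delta_tol = delta_tol
  ), class = "effective_tangents")
}

## Stationary periodic solve + volume-averaged fluxes for one macro state
static_avg_fluxes <- function(model, constr, p, solver) {
  d <- solve_static(model, constr, p, solver = solver)
  st <- qp_states(model, d)                 # rate-free states
  fl <- qp_fluxes(model, st)
  average_fluxes(model, fl[c("sigma", "D", "H", "J")])
}

#' Hill-Mandel virtual-work residuals of periodic micro solves
#'
#' Checks scale-transition energy consistency: for each work pair the
#' macroscopic product of averages must equal the volume average of the
#' microscopic product, e.g. \eqn{\bar\sigma\cdot\bar\varepsilon =
#' \frac1\Omega\int\sigma\cdot\varepsilon\,dV}. Each line is evaluated on
#' its canonical test variation — a macro state exciting only that physics
#' (the mechanical line under the strain part of `p`, the electric line
#' under the field part, the magnetic line under the flux-density part) —
#' because the cross-coupled self-field product additionally carries
#' genuine transfer terms (piezoelectrically driven eddy-current work) that
#' are not part of the scale-transition identity. Periodic fluctuations
#' with fixed corner nodes satisfy each identity by construction; the
#' residuals measure how far the discrete solution is from it.
#'
#' @param rve an [rve_problem()]
#' @param p a [macro_state()] supplying the test variations (its strain,
#'   electric-field and flux-density parts are applied separately)
#' @return named vector of three normalized gaps
#'   (`mechanical`, `electric`, `magnetic`)
#' @export
hill_mandel_residual <- function(rve, p) {
  model <- rve$model; constr <- rve$constr
  solver <- static_solver(model, constr)
  gap <- function(pline, field_nm, flux_nm) {
    d <- solve_static(model, constr, pline, solver = solver)
    st <- qp_states(model, d)
    fl <- qp_fluxes(model, st)
    macro <- sum(average_fluxes(model, fl[[flux_nm]]) *
                   average_fluxes(model, st[[field_nm]]))
    micro <- sum(model$qp_w * colSums(st[[field_nm]] * fl[[flux_nm]])) /
      model$volume
    abs(macro - micro) / max(abs(macro), abs(micro), .Machine$double.xmin)
  }
  c(mechanical = gap(macro_state(eps_bar = p[1:6]), "eps", "sigma"),
    electric = gap(macro_state(E_bar = p[7:9]), "E", "D"),
    magnetic = gap(macro_state(B_bar = p[10:12]), "B", "H"))
}

#' Effective Young's modulus from the homogenized stiffness
#'
#' Isotropic-recovery expression
#' \deqn{E_{eff} = \frac{\bar C_{44} (3 \bar C_{12} + 2 \bar C_{44})}
#'   {\bar C_{12} + \bar C_{44}},}
#' the classical identity \eqn{E = \mu(3\lambda + 2\mu)/(\lambda + \mu)}
#' applied to the (1,2) (off-diagonal normal) and (4,4) (shear) entries of
#' the homogenized Voigt stiffness.
#'
#' @param C_bar homogenized 6x6 stiffness (Pa)
#' @return effective Young's modulus (Pa)
#' @export
effective_young_modulus <- function(C_bar) {
  C12 <- C_bar[1L, 2L]; C44 <- C_bar[4L, 4L]
  if (abs(C12 + C44) < .Machine$double.xmin * 1e10)
    stop("singular isotropic recovery: C12 + C44 = 0")
  C44 * (3 * C12 + 2 * C44) / (C12 + C44)
}

#' Homogenize one RVE of the osteoporosis family
#'
#' End-to-end micro pipeline: build the RVE, compute the perturbation
#' tangents and the effective Young's modulus.
#'
#' @inheritParams rve_problem
#' @return list with `params`, `rho_b`, `tangents` and `E_eff_GPa`
#' @export
homogenize_rve <- function(params, dt = 1e-3, gamma = 1.0, materials = NULL) {
  rve <- rve_problem(params, dt = dt, gamma = gamma, materials = materials)
  tg <- perturbation_tangents(rve)
  list(params = params, rho_b = params$rho_b, tangents = tg,
       E_eff_GPa = effective_young_modulus(tg$C_bar) / 1e9)
}

#' Reuss and Voigt bounds on the effective Young's modulus
#'
#' Elementary mixture bounds from the phase moduli and the cortical volume
#' fraction, used as a sanity bracket for the homogenized modulus.
#'
#' @param E_b,E_m phase Young's moduli
#' @param rho_b cortical volume fraction
#' @return named vector `c(reuss, voigt)`
#' @export
young_modulus_bounds <- function(E_b, E_m, rho_b) {
  c(reuss = 1 / (rho_b / E_b + (1 - rho_b) / E_m),
    voigt = rho_b * E_b + (1 - rho_b) * E_m)
}
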
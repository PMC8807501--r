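#' Phase material parameters
#'
#' Parameter set of one phase of the cancellous-bone composite, in the units
#' customary for bone tissue (GPa for stiffness, SI for the electromagnetic
#' constants). Cortical bone is a piezoelectric insulating elastic solid
#' (`kappa1 = 0`, `mu_v = 0`); marrow is a viscoelastic conducting solid
#' without piezoelectricity (`e15 = 0`).
#'
#' @param E_GPa Young's modulus in GPa
#' @param nu Poisson ratio, in `(0, 0.5)`
#' @param xi1 permittivity (F/m)
#' @param mu_c permeability (H/m)
#' @param e15 shear-mode piezoelectric coefficient (As/m^2)
#' @param kappa1 electric conductivity (S/m)
#' @param mu_v viscosity rate coefficient in 1/(GPa s); the stress-driven
#'   inelastic strain evolves as `d(eps_i)/dt = mu_v * dev(sigma)`
#' @param name phase label
#' @return object of class `phase_material` (all quantities converted to SI)
#' @export
phase_material <- function(E_GPa, nu, xi1 = 8.85e-12, mu_c = 1.257e-6,
                           e15 = 0, kappa1 = 0, mu_v = 0, name = "phase") {
  if (E_GPa <= 0) stop("Young's modulus must be positive")
  if (nu <= 0 || nu >= 0.5) stop("Poisson ratio must lie in (0, 0.5)")
  if (xi1 <= 0 || mu_c <= 0) stop("permittivity and permeability must be positive")
  if (kappa1 < 0 || mu_v < 0) stop("conductivity and viscosity must be non-negative")
  structure(list(
    E = E_GPa * 1e9, nu = nu, xi1 = xi1, mu_c = mu_c,
    e15 = e15, kappa1 = kappa1, mu_v = mu_v * 1e-9, name = name
  ), class = "phase_material")
}

#' Default cortical bone phase (Table of default bone parameters)
#' @return a [phase_material()]
#' @export
material_bone <- function() {
  phase_material(E_GPa = 22, nu = 0.32, e15 = 3.0e-3, kappa1 = 0, mu_v = 0,
                 name = "bone")
}

#' Default bone marrow phase
#'
#' @param dt time increment (s) the viscosity parameter is tied to; the
#'   default viscosity is `0.5 * dt` in 1/(GPa s)
#' @param kappa1 electric conductivity (S/m)
#' @return a [phase_material()]
#' @export
material_marrow <- function(dt = 1e-3, kappa1 = 1.0e4) {
  phase_material(E_GPa = 2, nu = 0.3, e15 = 0, kappa1 = kappa1,
                 mu_v = 0.5 * dt, name = "marrow")
}

#' Assemble the material tensors of one phase
#'
#' Builds the isotropic stiffness (6x6, Voigt order xx, yy, zz, xy, yz, xz
#' with engineering shear strains), diagonal permittivity, inverse
#' permeability and conductivity tensors, and the shear-mode piezoelectric
#' coupling matrix with entries `+e15` at (1,5) and `-e15` at (2,6); the
#' preferred axis of the collagen fibers is z.
#'
#' @param mat a [phase_material()]
#' @return list of class `material_tensors` with `C` (Pa), `xi`, `mu_inv`,
#'   `e`, `kappa`, and scalars `mu_v` (1/(Pa s)) and `name`
#' @export
build_tensors <- function(mat) {
  stopifnot(inherits(mat, "phase_material"))
  E <- mat$E; nu <- mat$nu
  if (abs(nu - 0.5) < 1e-12) stop("nu = 0.5 gives a singular stiffness")
  f <- E / ((1 + nu) * (1 - 2 * nu))
  C <- diag(c(rep(1 - nu, 3), rep((1 - 2 * nu) / 2, 3))) * f
  C[1:3, 1:3][diag(3) == 0] <- nu * f
  e <- matrix(0, 3, 6)
  e[1, 5] <- mat$e15
  e[2, 6] <- -mat$e15
  structure(list(
    C = C,
    xi = diag(mat$xi1, 3),
    mu_inv = diag(1 / mat$mu_c, 3),
    e = e,
    kappa = diag(mat$kappa1, 3),
    mu_v = mat$mu_v,
    name = mat$name
  ), class = "material_tensors")
}

#' Deviatoric projector applied to a Voigt stress
#'
#' Voigt stresses carry no engineering factors, so the deviatoric operator is
#' `I - (1/3) * ones(3)` on the normal block and the identity on the shear
#' block.
#'
#' @param sigma Voigt 6-vector stress (or 6 x n matrix of stresses)
#' @return deviatoric stress of the same shape; normal components sum to zero
#' @export
deviatoric <- function(sigma) {
  D <- deviatoric_projector()
  if (is.matrix(sigma)) D %*% sigma else drop(D %*% sigma)
}

deviatoric_projector <- function() {
  D <- diag(6)
  D[1:3, 1:3] <- D[1:3, 1:3] - 1 / 3
  D
}

#' Constitutive fluxes at a quadrature point
#'
#' Evaluates stress, electric displacement, magnetic field strength and
#' electric current from the point state. Cortical bone couples stress and
#' electric displacement through the piezoelectric tensor; marrow carries the
#' inelastic strain and Ohmic conduction `J = kappa E`.
#'
#' @param eps Voigt strain (engineering shears)
#' @param E_field electric field 3-vector (V/m)
#' @param B_field magnetic flux density 3-vector (T)
#' @param tensors a [build_tensors()] result
#' @param eps_i Voigt inelastic strain (marrow only; ignored for bone)
#' @return list with `sigma` (Pa), `D` (As/m^2), `H` (A/m), `J` (A/m^2)
#' @export
evaluate_fluxes <- function(eps, E_field, B_field, tensors,
                            eps_i = numeric(6)) {
  stopifnot(length(eps) == 6L, length(E_field) == 3L, length(B_field) == 3L)
  if (tensors$name == "bone") {
    list(sigma = drop(tensors$C %*% eps - t(tensors$e) %*% E_field),
         D = drop(tensors$e %*% eps + tensors$xi %*% E_field),
         H = drop(tensors$mu_inv %*% B_field),
         J = numeric(3))
  } else {
    list(sigma = drop(tensors$C %*% (eps - eps_i)),
         D = drop(tensors$xi %*% E_field),
         H = drop(tensors$mu_inv %*% B_field),
         J = drop(tensors$kappa %*% E_field))
  }
}

#' Explicit-Euler step of the inelastic strain
#'
#' Integrates the stress-driven flow rule `d(eps_i)/dt = mu_v * dev(sigma)`
#' with one explicit Euler step. The deviatoric driving stress keeps the
#' inelastic strain exactly trace-free, realizing the volume-conservation
#' constraint of the inelastic deformation.
#'
#' @param eps_i_n Voigt inelastic strain at step n (6-vector or 6 x n matrix)
#' @param sigma stress driving the flow, same shape
#' @param mu_v viscosity rate coefficient (1/(Pa s))
#' @param dt time increment (s), non-negative
#' @return inelastic strain at step n+1
#' @export
evolve_inelastic_strain <- function(eps_i_n, sigma, mu_v, dt) {
  if (dt < 0) stop("negative time increment")
  eps_i_n + dt * mu_v * deviatoric(sigma)
}

#' Consistent mechanical tangent stiffness of a phase
#'
#' Derivative of the one-step stress update with respect to strain. Bone is
#' purely elastic; for marrow the explicit inelastic increment evaluated on
#' the trial stress yields
#' \deqn{C_{tang} = C_m - C_m (\Delta t\, \mu_v\, D_{dev}\, C_m).}
#'
#' @param tensors a [build_tensors()] result
#' @param dt time increment (s)
#' @return 6x6 tangent stiffness (Pa)
#' @export
tangent_stiffness <- function(tensors, dt) {
  C <- tensors$C
  if (tensors$mu_v == 0) return(C)
  C - C %*% (dt * tensors$mu_v * deviatoric_projector() %*% C)
}

## One-step marrow stress update used both by the residual and (via its
## exact derivative) the tangent: trial stress on frozen eps_i_n, explicit
## increment on the trial stress, reported stress on the updated eps_i.
## Returns sigma = C_tang (eps - eps_i_n).
marrow_step_stress <- function(eps, eps_i_n, tensors, dt) {
  sig_tr <- tensors$C %*% (eps - eps_i_n)
  eps_i1 <- evolve_inelastic_strain(eps_i_n, sig_tr, tensors$mu_v, dt)
  tensors$C %*% (eps - eps_i1)
}
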
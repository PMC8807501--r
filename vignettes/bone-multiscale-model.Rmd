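---
title: "A coupled mechano-electro-magnetic two-scale model of cancellous bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled mechano-electro-magnetic two-scale model of cancellous bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoFE2)
```

## The model

Cancellous (spongy) bone is a composite of interconnected cortical-bone
struts and interstitial marrow. Cortical bone is piezoelectric: shearing the
collagen fibers separates charge, so mechanical loading generates an electric
displacement field, and its time variation generates a magnetic field through
Ampère's law. Because osteoporosis removes cortical bone (volume fractions
dropping from about 30% to 5%), the magnetically measurable response of a
mechanically excited bone carries diagnostic information. This package
models that chain of effects with a two-scale finite element method.

The microscale unknowns per node are the displacement $\mathbf u$, the
electric scalar potential $\varphi$ and the magnetic vector potential
$\mathbf A$ — seven degrees of freedom. The state variables are
$$\boldsymbol\varepsilon = \tfrac12(\nabla\mathbf u + \nabla^T\mathbf u),
\qquad \mathbf E = -\nabla\varphi - \dot{\mathbf A}, \qquad
\mathbf B = \nabla\times\mathbf A,$$
which satisfies Faraday's law and the absence of magnetic monopoles
identically. Voigt notation is used with strain order
$(\varepsilon_{xx},\varepsilon_{yy},\varepsilon_{zz},
2\varepsilon_{xy},2\varepsilon_{yz},2\varepsilon_{xz})$; stresses carry no
engineering factors.

The two phases obey

* **cortical bone** (insulating, piezoelectric, elastic):
  $\boldsymbol\sigma = \mathbb C_b\boldsymbol\varepsilon - \mathbf e^T\mathbf E$,
  $\mathbf D = \mathbf e\boldsymbol\varepsilon + \boldsymbol\xi\mathbf E$,
  $\mathbf H = \boldsymbol\mu^{-1}\mathbf B$, $\mathbf J = \mathbf 0$;
* **marrow** (conducting, viscoelastic):
  $\boldsymbol\sigma = \mathbb C_m(\boldsymbol\varepsilon - \boldsymbol\varepsilon^i)$,
  $\mathbf D = \boldsymbol\xi\mathbf E$, $\mathbf H = \boldsymbol\mu^{-1}\mathbf B$,
  $\mathbf J = \boldsymbol\kappa\mathbf E$,

with the volume-preserving flow rule
$\dot{\boldsymbol\varepsilon}^i = \mu_v\,\mathrm{dev}\,\boldsymbol\sigma$
for the inelastic strain. The piezoelectric tensor has the shear-mode
pattern $e_{15}$ at positions $(1,5)$ and $-(2,6)$, reflecting the
longitudinal orientation of the collagen fibers along $z$. A quadratic
penalty $\tfrac\gamma2(\nabla\cdot\mathbf A)^2$ fixes the gauge of the
vector potential.

### Parameters

| parameter | cortical bone | marrow | units |
|---|---|---|---|
| Young's modulus $E$ | 22 | 2 | GPa |
| Poisson ratio $\nu$ | 0.32 | 0.3 | – |
| permittivity $\xi_1$ | $8.85\cdot10^{-12}$ | $8.85\cdot10^{-12}$ | F/m |
| permeability $\mu_c$ | $1.257\cdot10^{-6}$ | $1.257\cdot10^{-6}$ | H/m |
| piezo coefficient $e_{15}$ | $3.0\cdot10^{-3}$ | 0 | As/m² |
| conductivity $\kappa_1$ | 0 | $10^{4}$ | S/m |
| viscosity $\mu_v$ | 0 | $0.5\,\Delta t$ | 1/(GPa s) |

Numerical defaults: spectral radius $\rho_\infty = 0.5$, Newton tolerance
$10^{-8}$, gauge penalty $\gamma = 1.0$, micro time increment
$\Delta t = 10^{-3}$ s (macro $10^{-2}$ s), 100 steps, peak driven
displacement $u_{\max} = 2\cdot10^{-6}$ m.

A note on $\mu_v$: the flow rule requires $\mu_v$ to carry units of inverse
viscosity, 1/(GPa s); the package takes the printed value $0.5\,\Delta t$ in
those units and converts to SI. Because the default ties $\mu_v$ to the
configured time increment, the marrow model is nominally
increment-dependent; the viscous correction to the tangent is of relative
size $\Delta t\,\mu_v\,\mathbb C_m \sim 10^{-6}$, so this choice is
numerically inconsequential. The consistent tangent
$\mathbb C_m - \mathbb C_m(\Delta t\,\mu_v\,\mathbf D_{dev}\mathbb C_m)$ is
the exact derivative of the one-step update (trial stress on the frozen
inelastic strain, explicit Euler increment on the trial stress), which makes
the per-step residual exactly linear in the nodal unknowns — Newton
converges in a single correction, and the inelastic strain stays trace-free
to machine precision because the increment is a deviatoric projection.

## The RVE and its homogenization

The representative volume element is a cube of edge $2a+b$ containing three
orthogonal $b\times b$ cortical rods crossing at the center. By
inclusion–exclusion the cortical volume fraction is
$$\rho_b = \frac{6ab^2 + b^3}{(2a+b)^3},$$
and the mesh reproduces it exactly because each axis is partitioned into
segments $[a, b, a]$ whose boundaries coincide with element faces. Two
elements per segment give the standard 6³-element RVE; four give the 12³
refinement. The disease family spans $\rho_b$ = 5.3% ("degenerated",
$a$=0.43, $b$=0.14 mm) to 29.5% ("healthy", $a$=0.32, $b$=0.36 mm), all at
1 mm³ total volume.

Periodic boundary conditions impose the additive split of micro states into
an affine macro part plus a periodic fluctuation:
$$\mathbf u = \bar{\boldsymbol\varepsilon}\,\mathbf y + \tilde{\mathbf u},\quad
\varphi = -\bar{\mathbf E}\cdot\mathbf y + \tilde\varphi,\quad
\mathbf A = \tfrac12\bar{\mathbf B}\times\mathbf y + \tilde{\mathbf A},$$
with fluctuations linked on opposite faces and all corner-node degrees of
freedom fixed. The symmetric-gauge affine part $\tfrac12\bar{\mathbf B}
\times\mathbf y$ was chosen because its curl is exactly $\bar{\mathbf B}$
and it is divergence-free, so the imposed flux density does not load the
gauge penalty. Edge and corner chains (nodes shared by several face pairs)
are resolved by union-find so every constrained node has exactly one
ultimate master; constraints are eliminated by a reduction matrix rather
than Lagrange multipliers, keeping the printed block structure of the
system intact.

Effective tangents are computed by forward-differencing the volume-averaged
fluxes under unit perturbations ($\Delta_{tol}=10^{-8}$) of each macro state
component, about the zero state, from stationary periodic solves. The micro
problem is linear, so the differences are exact derivatives and the tangents
are computed once and cached for all macro points and steps. The effective
Young's modulus is recovered isotropically,
$$E_{\mathrm{eff}} = \frac{\bar C_{44}(3\bar C_{12} + 2\bar C_{44})}
{\bar C_{12} + \bar C_{44}},$$
the classical identity $E = \mu(3\lambda+2\mu)/(\lambda+\mu)$ applied to the
homogenized Voigt entries. On the coarse healthy RVE this yields 3.89 GPa;
on the degenerated RVE 2.23 GPa, a reduction to 57%. (Published figures for
this configuration quote both "2.32 GPa" and "a reduction to 57%", which
are mutually inconsistent — $2.32/3.89 = 60\%$; our value supports the
percentage, and mesh refinement moves both moduli down, not up.)

Scale-transition consistency (equality of macroscopic and volume-averaged
microscopic virtual work) is verified per physics line on canonical test
states: a strain-only state for the mechanical line, a field-only state for
the electric line, a flux-density-only state for the magnetic line. The
cross-coupled self-field product additionally contains genuine
piezoelectrically-driven eddy-current work, which is a power transfer, not
a violation of the transition identity.

## Time integration

The transient coupled system
$\mathbf R = \mathbf F - \mathbf M\ddot{\mathbf d} - \mathbf C\dot{\mathbf d}
- \mathbf K\mathbf d$ (mass only in the A–A permittivity block, no
structural inertia) is integrated with the JWH generalized-alpha scheme.
The update recurrences are
$$\mathbf d_{n+1} = \mathbf d_n + \Delta t\,\dot{\mathbf d}_n +
\gamma_a\Delta t(\dot{\mathbf d}_{n+1} - \dot{\mathbf d}_n),$$
the same recurrence for the auxiliary velocity from its rate, and the
compatibility $\dot{\mathbf d}_{n+\alpha_m} = \mathbf v_{n+\alpha_f}$, with
$$\alpha_m = \frac{3-\rho_\infty}{2(1+\rho_\infty)},\quad
\alpha_f = \frac1{1+\rho_\infty},\quad
\gamma_a = \tfrac12 + \alpha_m - \alpha_f.$$
Differentiating these recurrences reproduces exactly the generalized
tangent
$\mathbf S = \frac{\alpha_m^2}{\alpha_f\gamma_a^2\Delta t^2}\mathbf M +
\frac{\alpha_m}{\gamma_a\Delta t}\mathbf C + \alpha_f\mathbf K$
(a unit-tested identity). Prescribed degrees of freedom follow the same
recurrences with their increments fixed by the load history, so
time-dependent boundary data generate consistent rate fields. Initial
conditions are quiescent. The inelastic strain is advanced once per
accepted step. Newton convergence is declared at an absolute residual of
$10^{-8}$, or at the same factor relative to the step's initial residual
when that exceeds unity — the mixed-unit residuals of macroscale problems
(stiffness $\sim10^{10}$ Pa against permittivity $\sim10^{-11}$ F/m) have a
roundoff floor far above tiny absolute values.

### Numerical conditioning of the vector-potential block

Two deliberate numerical choices concern the equal-order $\mathbf A$
discretization on bounded (macroscale) domains; periodic RVEs are not
affected because corner fixing excludes the offending modes.

**Gauge fixing.** Nodal fields that are discretely curl-free *and*
divergence-free at the quadrature points (discrete-harmonic gradients) see
neither the curl–curl stiffness nor the divergence penalty; their only
stiffness is the permittivity mass, $\sim10^{-12}$ relative to the
curl–curl block. A gauge-consistent Tikhonov term
$\theta\int\mathbf A\cdot\delta\mathbf A\,dV$ with $\theta = \gamma/L^2$
($L$ the domain diagonal) gives these modes a stiffness of the same
magnitude as the gauge penalty itself while perturbing the physical
curl-carrying modes by only $\sim\gamma/\mu^{-1}\approx10^{-6}$ relative —
below discretization error.

**Relaxed-conductor limit.** In a conductor with $\kappa_1 = 10^4$ S/m,
free charge relaxes on the time scale $\xi/\kappa\sim10^{-15}$ s —
instantaneous relative to any load step — screening the irrotational part
of $\mathbf E$. The quasi-static potential formulation does not track free
charge, so without this limit the dielectric-scale electric field (bound
piezoelectric charge over permittivity) would drive a persistent DC
conduction current whose magnetic field grows with the load amplitude and
exceeds the displacement-current contribution by many orders — physically
wrong at these parameters, and incompatible with the known behavior of
this model class (magnetic response peaking where the load *rate* peaks,
and insensitive to $\kappa_1$ below $10^6$ S/m). The macroscale model
therefore screens the irrotational conduction current: the conduction
coupling of the vector-potential equation to the scalar potential is
dropped and $\mathbf J$ is driven by the inductive field $-\dot{\mathbf A}$
alone. With an insulating marrow the two formulations coincide exactly;
the microscale RVE always uses the unmodified equations.

## Macroscale driver

The benchmark body is a cylinder (length 30 cm, diameter 3 cm) meshed with
an all-hexahedral butterfly/O-grid: a central square block of `nsq`²
quads per section, `nr` ring layers morphing its boundary to the circle,
extruded into `nz` axial layers. The reference resolution
(`nsq=4, nr=2, nz=30`) has 1767 nodes and 1440 elements. Both end faces
are clamped; the nodes of a central axial band (10% of the length,
configurable) are driven as $u_x = u_{\max}a(t)$; the inner disc
($r<0.75$ cm) of the left face is grounded ($\varphi=0$, $\mathbf A=
\mathbf 0$). The load amplitude is the smoothstep $a = 3s^2-2s^3$,
$s = t/T$: monotone 0→1, flat at both ends, steepest at mid-run — the
qualitative shape required of the published loading curve, whose analytic
form is not stated.

The macro constitutive response comes from the RVE in one of two modes.
In **cached** mode the five effective tangents act as a linear
constitutive law — justified because the tangents are state-independent
and the inelastic nonlinearity is very small. In **full** mode every
macro quadrature point carries its own persistent transient RVE; the macro
residual is the effective-operator residual plus the alpha-weighted defect
between the RVE's averaged fluxes and the effective-law prediction at the
same state (a defect-correction formulation: for a linear micro response
the defect vanishes identically and the modes agree to roundoff, which is
also the package's cross-check between them).

With the healthy RVE, the simulated cylinder shows the expected physics:
the electric displacement magnitude tracks the displacement amplitude
(correlation 1.000 in the test suite), the magnetic field strength peaks
at mid-run and decays to below 1% of its peak by the end, and the mid-run
magnetic response increases strictly with the cortical volume fraction
across the six-stage disease family.

## What the generator emulates — and what it does not

All inputs are procedural: the RVE family and cylinder mesh are the study
conditions, not samples of real microstructure. The idealized three-rod
RVE captures the volume fraction and connectivity of trabecular bone but
not its geometric disorder, anisotropy or marrow fluidity; material
parameters beyond the elastic and piezoelectric constants are of
acknowledged academic character. Passing tests therefore demonstrate
correctness of the numerical machinery and reproduction of the reference
configuration's results — not clinical validity on real bone geometry.

## Problem sizes and known limitations

The test suite runs the coarse (6³, ~2 400 DOF) RVE for homogenization and
100-step transients, the fine (12³, ~15 000 DOF) RVE for a 20-step
mesh-independence comparison (both averaged fluxes are quasi-steady well
before step 20, and the coarse/fine ratio is time-independent), and a
reduced cylinder (96 hexahedra, 20 steps) for the disease-trend study; the
reference cylinder resolution is available through the same constructors.

Known limitations: equal-order interpolation for all seven fields (LBB-type
risks accepted, stabilized through the gauge terms); tetrahedral meshes and
image-derived microstructures are out of scope; the anisotropic elongated
RVE variant is not implemented (its printed axial segment pattern does not
determine the stated geometry); no surrounding medium, contact or fracture;
mesh convergence of the homogenized piezoelectric coupling is slower than
that of the stiffness (the coarse/fine averaged electric displacement
differs by ~7%, against ~3.5% for the shear stress).
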
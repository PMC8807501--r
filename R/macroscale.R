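#' All-hexahedral cylinder mesh (butterfly / O-grid)
#'
#' Builds a structured all-hex mesh of a circular cylinder with axis along
#' z: a central square block of `nsq` x `nsq` quads surrounded by `nr` ring
#' layers that morph the square boundary onto the circle, extruded into
#' `nz` axial layers. With `nsq = 4, nr = 2, nz = 30` the mesh has 1767
#' nodes and 1440 hexahedra. The circular boundary is a polygon with
#' `4 nsq` vertices, so the mesh volume approaches `pi r^2 L` from below as
#' the cross-section is refined.
#'
#' @param length cylinder length (m)
#' @param radius outer radius (m)
#' @param nsq central-square divisions per side (>= 2)
#' @param nr ring layers (>= 1)
#' @param nz axial element layers (>= 1)
#' @return a `hex_mesh` (no phase tags)
#' @export
build_cylinder_mesh <- function(length = 0.30, radius = 0.015,
                                nsq = 4L, nr = 2L, nz = 30L) {
  if (length <= 0 || radius <= 0) stop("cylinder dimensions must be positive")
  if (nsq < 2L || nr < 1L || nz < 1L)
    stop("resolution too low for the O-grid pattern")
  s <- radius / 2                       # half-width of the central square

  ## 2D cross-section nodes: square grid then ring layers
  xs <- seq(-s, s, length.out = nsq + 1L)
  sq <- as.matrix(expand.grid(x = xs, y = xs, KEEP.OUT.ATTRS = FALSE))
  sq_id <- function(i, j) i + (nsq + 1L) * (j - 1L)   # i, j in 1..nsq+1
  # square perimeter, counterclockwise from (-s, -s)
  per <- c(sq_id(1:nsq, 1L), sq_id(nsq + 1L, 1:nsq),
           sq_id((nsq + 1L):2L, nsq + 1L), sq_id(1L, (nsq + 1L):2L))
  nper <- base::length(per)
  theta <- atan2(sq[per, 2L], sq[per, 1L])
  ring_nodes <- NULL
  for (k in seq_len(nr)) {
    t <- k / nr
    ring_nodes <- rbind(ring_nodes,
                        (1 - t) * sq[per, , drop = FALSE] +
                          t * radius * cbind(cos(theta), sin(theta)))
  }
  nodes2d <- rbind(sq, ring_nodes)
  ring_id <- function(k, m) nrow(sq) + (k - 1L) * nper + m   # m in 1..nper

  ## 2D quads (counterclockwise)
  ij <- expand.grid(i = seq_len(nsq), j = seq_len(nsq))
  quads <- cbind(sq_id(ij$i, ij$j), sq_id(ij$i + 1L, ij$j),
                 sq_id(ij$i + 1L, ij$j + 1L), sq_id(ij$i, ij$j + 1L))
  layer_ids <- function(k) if (k == 0L) per else vapply(1:nper, ring_id, integer(1L), k = k)
  for (k in seq_len(nr)) {
    inner <- layer_ids(k - 1L); outer <- layer_ids(k)
    m <- seq_len(nper); m2 <- c(2:nper, 1L)
    quads <- rbind(quads, cbind(inner[m], outer[m], outer[m2], inner[m2]))
  }

  ## extrude along z
  n2d <- nrow(nodes2d)
  zs <- seq(0, length, length.out = nz + 1L)
  nodes <- do.call(rbind, lapply(zs, function(z) cbind(nodes2d, z)))
  dimnames(nodes) <- NULL
  conn <- do.call(rbind, lapply(seq_len(nz), function(k) {
    lo <- (k - 1L) * n2d; hi <- k * n2d
    cbind(quads + lo, quads + hi)
  }))
  new_hex_mesh(nodes, conn)
}

#' Smoothstep load amplitude
#'
#' Monotone 0 to 1 ramp `a = 3 s^2 - 2 s^3`, `s = step/n_steps`: zero slope
#' at both ends and maximal rate at mid-run, so rate-driven fields (the
#' magnetic field strength in particular) peak at the middle of the run and
#' decay toward its end.
#'
#' @param step step index in `0:n_steps`
#' @param n_steps total number of steps
#' @return amplitude in `[0, 1]`
#' @export
load_amplitude <- function(step, n_steps) {
  s <- pmin(pmax(step / n_steps, 0), 1)
  3 * s^2 - 2 * s^3
}

#' Macroscale cylinder benchmark model
#'
#' The cylinder is clamped (`u = 0`) on both end faces; the nodes of a
#' central axial band are driven in x by `u_x = u_max a(t)`; the inner disc
#' of the left face (`r < r_inner`) is grounded (`phi = 0`, `A = 0`).
#'
#' @param mesh optional pre-built cylinder `hex_mesh`
#' @param length,radius,nsq,nr,nz passed to [build_cylinder_mesh()]
#' @param band_frac axial fraction of the driven middle band (default 10%)
#' @param r_inner grounded-disc radius on the left face (m)
#' @param u_max peak driven displacement (m)
#' @return list of class `macro_model` with `mesh`, `constr`
#'   ([dirichlet_constraints()] with the load amplitude as single
#'   parameter), `u_max` and the node sets
#' @export
macro_cylinder_model <- function(mesh = NULL, length = 0.30, radius = 0.015,
                                 nsq = 4L, nr = 2L, nz = 30L,
                                 band_frac = 0.10, r_inner = 0.0075,
                                 u_max = 2e-6) {
  if (is.null(mesh)) mesh <- build_cylinder_mesh(length, radius, nsq, nr, nz)
  if (u_max <= 0) stop("u_max must be positive")
  nodes <- mesh$nodes
  nnode <- nrow(nodes)
  L <- mesh$bbox[2L, 3L] - mesh$bbox[1L, 3L]
  zmid <- (mesh$bbox[2L, 3L] + mesh$bbox[1L, 3L]) / 2
  left <- mesh$face_sets$zmin; right <- mesh$face_sets$zmax
  r <- sqrt(nodes[, 1L]^2 + nodes[, 2L]^2)
  grounded <- left[r[left] < r_inner]
  band <- which(abs(nodes[, 3L] - zmid) <= band_frac * L / 2 + 1e-12 * L)
  band <- setdiff(band, c(left, right))

  udofs <- function(ns) as.vector(vapply(ns, function(n)
    (n - 1L) * N_DOF_NODE + 1:3, integer(3L)))
  zero <- c(udofs(left), udofs(right),
            as.vector(vapply(grounded, function(n)
      (n - 1L) * N_DOF_NODE + 4:7, integer(4L))))
  driven <- (band - 1L) * N_DOF_NODE + 1L     # u_x of band nodes
  constr <- dirichlet_constraints(mesh, zero, driven, driven_value = u_max)
  structure(list(mesh = mesh, constr = constr, u_max = u_max,
                 fixed_sets = list(left = left, right = right),
                 driven_set = band, grounded_set = grounded),
            class = "macro_model")
}

## Effective (homogenized) material wrapped as a material_tensors object so
## the element and flux routines can consume it directly.
effective_material <- function(tangents) {
  structure(list(
    C = tangents$C_bar, xi = tangents$xi_bar, mu_inv = tangents$mu_inv_bar,
    e = tangents$e_bar, kappa = tangents$kappa_bar,
    mu_v = 0, name = "effective"
  ), class = "material_tensors")
}

#' Field statistics of per-step quadrature fields
#'
#' @param model the macro [fe_model()]
#' @param fluxes list with `sigma`, `D`, `H`, `J` quadrature matrices
#' @return one summary row: volume-averaged magnitudes (`avg_*`), spatial
#'   maximum magnitudes (`max_*`), the magnitude of the volume-averaged
#'   vector fields (`mag_avg_*`) and averaged stress components
#' @export
field_statistics <- function(model, fluxes) {
  mag <- function(m) sqrt(colSums(m^2))
  stats <- list()
  for (nm in c("D", "H", "J")) {
    mg <- mag(fluxes[[nm]])
    stats[[paste0("avg_", nm)]] <- sum(model$qp_w * mg) / model$volume
    stats[[paste0("max_", nm)]] <- max(mg)
    stats[[paste0("mag_avg_", nm)]] <-
      sqrt(sum((drop(fluxes[[nm]] %*% model$qp_w) / model$volume)^2))
  }
  sig <- drop(fluxes$sigma %*% model$qp_w) / model$volume
  names(sig) <- paste0("sigma_", c("xx", "yy", "zz", "xy", "yz", "xz"))
  unlist(c(stats, as.list(sig)))
}

#' FE2 macroscale run
#'
#' Runs the transient macroscale boundary value problem with the micro RVE
#' supplying the constitutive response. In `cached` mode the five effective
#' tangents (computed once by [perturbation_tangents()]) act as a linear
#' constitutive law; in `full` mode every macro quadrature point carries its
#' own transient RVE whose volume-averaged fluxes enter the macro residual
#' directly (one micro step per macro step, committed on macro-step
#' acceptance).
#'
#' @param macro a [macro_cylinder_model()] (or compatible `macro_model`)
#' @param rve an [rve_problem()]
#' @param cfg a [time_config()] (macro time increment)
#' @param mode `"cached"` or `"full"`
#' @param tangents optional precomputed [perturbation_tangents()]
#' @param gamma gauge penalty for the macro problem
#' @return list with `summary` (per-step [field_statistics()] data frame
#'   including the load amplitude `a`), per-step averaged fluxes `avg`,
#'   `newton_iters` and the final macro `state`
#' @export
fe2_run <- function(macro, rve, cfg, mode = c("cached", "full"),
                    tangents = NULL, gamma = 1.0) {
  mode <- match.arg(mode)
  if (is.null(tangents)) tangents <- perturbation_tangents(rve)
  eff <- effective_material(tangents)
  mm <- fe_model(macro$mesh, list(effective = eff), gamma = gamma, dt = cfg$dt,
                 theta = "auto", relaxed_conduction = TRUE)
  amp <- load_amplitude(seq_len(cfg$n_steps), cfg$n_steps)
  p_hist <- matrix(amp, nrow = 1L)

  if (mode == "cached") {
    res <- transient_solve(mm, macro$constr, p_hist, cfg,
                           record = function(k, state, model) {
                             st <- qp_states(model, state$d, state$v, state$vdot)
                             field_statistics(model, qp_fluxes(model, st))
                           })
    summary <- as.data.frame(do.call(rbind, res$records))
  } else {
    res <- fe2_full_run(mm, macro$constr, rve, p_hist, cfg)
    summary <- as.data.frame(do.call(rbind, res$records))
  }
  summary$step <- seq_len(cfg$n_steps)
  summary$a <- amp
  list(summary = summary, avg = res$avg, newton_iters = res$newton_iters,
       state = res$state)
}

## Full (nested) FE2 loop with one persistent RVE per macro quadrature
## point, in defect-correction form: the macro residual is the effective
## (cached-tangent) operator residual plus the alpha-weighted difference
## between the RVE's volume-averaged fluxes and the effective-law
## prediction at the same macro state. For a linear micro response the
## correction vanishes and the two modes coincide to roundoff; with marrow
## viscosity it carries exactly the inelastic part of the micro response.
## RVE states are trial-advanced inside the iteration and committed when
## the macro step converges. Under the relaxed-conduction macroscale law
## the conduction defect is screened along with the DC current itself.
fe2_full_run <- function(mm, constr, rve, p_hist, cfg) {
  a <- cfg$alpha; dt <- cfg$dt
  am <- a$alpha_m; af <- a$alpha_f; ga <- a$gamma_a
  nqp <- mm$nqp
  solver <- transient_solver(mm, constr, cfg)
  rve_solver <- transient_solver(rve$model, rve$constr, cfg)

  state <- transient_state(mm); state$p <- numeric(constr$np)
  rve_states <- lapply(seq_len(nqp), function(q) {
    s <- transient_state(rve$model); s$p <- numeric(12L); s
  })
  zero_fl <- list(sigma = matrix(0, 6L, nqp), D = matrix(0, 3L, nqp),
                  Ddot = matrix(0, 3L, nqp), H = matrix(0, 3L, nqp),
                  J = matrix(0, 3L, nqp))
  fl_n <- zero_fl
  nsteps <- ncol(p_hist)
  avg <- vector("list", nsteps); recs <- vector("list", nsteps)
  iters <- integer(nsteps)

  for (k in seq_len(nsteps)) {
    d_n <- state$d; ud_n <- state$ud; v_n <- state$v; vd_n <- state$vdot
    d1 <- d_n + as.numeric(constr$P %*% (p_hist[, k] - state$p))
    trial <- NULL; fl_1 <- NULL
    for (it in seq_len(cfg$max_iter + 1L)) {
      Dd <- d1 - d_n
      ud1 <- ud_n + (Dd - dt * ud_n) / (ga * dt)
      ud_am <- ud_n + am * (ud1 - ud_n)
      v1 <- v_n + (ud_am - v_n) / af
      vd1 <- vd_n + (v1 - v_n - dt * vd_n) / (ga * dt)
      d_af <- d_n + af * Dd
      v_af <- v_n + af * (v1 - v_n)
      vd_am <- vd_n + am * (vd1 - vd_n)

      st1 <- qp_states(mm, d1, v1, vd1)
      eff1 <- qp_fluxes(mm, st1)          # effective-law fluxes at n+1
      trial <- vector("list", nqp)
      fl_1 <- zero_fl
      for (q in seq_len(nqp)) {
        p_q <- macro_state(st1$eps[, q], st1$E[, q], st1$B[, q])
        sq <- jwh_step(rve_states[[q]], rve$model, rve$constr, p_q, cfg,
                       rve_solver)
        trial[[q]] <- sq
        stq <- qp_states(rve$model, sq$d, sq$v, sq$vdot)
        flq <- qp_fluxes(rve$model, stq, rve_states[[q]]$eps_i)
        avq <- average_fluxes(rve$model, flq)
        fl_1$sigma[, q] <- avq$sigma; fl_1$D[, q] <- avq$D
        fl_1$Ddot[, q] <- avq$Ddot; fl_1$H[, q] <- avq$H; fl_1$J[, q] <- avq$J
      }
      ## defect fluxes: RVE response minus effective-law prediction
      dfl <- list(sigma = fl_1$sigma - eff1$sigma, D = fl_1$D - eff1$D,
                  Ddot = fl_1$Ddot - eff1$Ddot, H = fl_1$H - eff1$H)
      mixf <- function(nm, w) (1 - w) * fl_n[[nm]] + w * dfl[[nm]]
      w_sig <- mixf("sigma", af); w_D <- mixf("D", af)
      w_H <- mixf("H", af); w_Dd <- mixf("Ddot", am)
      wq <- mm$qp_w
      R <- -as.numeric(mm$M %*% vd_am) - as.numeric(mm$C %*% v_af) -
        as.numeric(mm$K %*% d_af)
      R <- R - as.numeric(Matrix::crossprod(mm$Bu, as.vector(sweep(w_sig, 2L, wq, "*"))))
      R <- R - as.numeric(Matrix::crossprod(mm$Bg, as.vector(sweep(w_D, 2L, wq, "*"))))
      R <- R + as.numeric(Matrix::crossprod(mm$NAm, as.vector(sweep(w_Dd, 2L, wq, "*"))))
      R <- R - as.numeric(Matrix::crossprod(mm$Bc, as.vector(sweep(w_H, 2L, wq, "*"))))
      Rr <- as.numeric(Matrix::crossprod(constr$T, R))
      rn <- sqrt(sum(Rr^2))
      if (it == 1L) rn0 <- rn
      if (rn < cfg$newton_tol * max(1, rn0)) { iters[k] <- it - 1L; break }
      if (it > cfg$max_iter) stop("macro Newton failed at step ", k)
      d1 <- d1 + as.numeric(constr$T %*% solver(Rr))
    }
    # commit macro and micro states
    Dd <- d1 - d_n
    ud1 <- ud_n + (Dd - dt * ud_n) / (ga * dt)
    ud_am <- ud_n + am * (ud1 - ud_n)
    v1 <- v_n + (ud_am - v_n) / af
    vd1 <- vd_n + (v1 - v_n - dt * vd_n) / (ga * dt)
    state <- list(d = d1, ud = ud1, v = v1, vdot = vd1, eps_i = state$eps_i,
                  t = state$t + dt, p = p_hist[, k])
    rve_states <- trial
    fl_n <- dfl      # committed defect fluxes for the next step's mixing
    avg[[k]] <- lapply(fl_1, function(m)
      drop(m %*% mm$qp_w) / mm$volume)
    recs[[k]] <- field_statistics(mm, fl_1)
  }
  list(state = state, avg = avg, newton_iters = iters, records = recs)
}
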
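#' JWH generalized-alpha scheme parameters
#'
#' Derives the three scheme parameters from the spectral radius at infinite
#' frequency: `alpha_m = (3 - rho)/(2 (1 + rho))`, `alpha_f = 1/(1 + rho)`,
#' `gamma_a = 1/2 + alpha_m - alpha_f`. `rho_inf = 1` gives the undamped
#' midpoint-like limit, `rho_inf = 0` asymptotic annihilation of the highest
#' modes.
#'
#' @param rho_inf spectral radius parameter in `[0, 1]`
#' @return list with `alpha_m`, `alpha_f`, `gamma_a`
#' @export
alpha_parameters <- function(rho_inf) {
  if (!is.finite(rho_inf) || rho_inf < 0 || rho_inf > 1)
    stop("rho_inf must lie in [0, 1]")
  alpha_m <- (3 - rho_inf) / (2 * (1 + rho_inf))
  alpha_f <- 1 / (1 + rho_inf)
  list(alpha_m = alpha_m, alpha_f = alpha_f,
       gamma_a = 0.5 + alpha_m - alpha_f)
}

#' Generalized tangent matrix of the JWH-alpha Newton iteration
#'
#' \deqn{S = \frac{\alpha_m^2}{\alpha_f \gamma_a^2 \Delta t^2} M
#'         + \frac{\alpha_m}{\gamma_a \Delta t} C + \alpha_f K.}
#'
#' @param M,C,K mass, damping and stiffness operators (conformable)
#' @param cfg a [time_config()]
#' @return the linear combination `S`
#' @export
effective_tangent <- function(M, C, K, cfg) {
  a <- cfg$alpha
  a$alpha_m^2 / (a$alpha_f * a$gamma_a^2 * cfg$dt^2) * M +
    a$alpha_m / (a$gamma_a * cfg$dt) * C +
    a$alpha_f * K
}

#' Time integration configuration
#'
#' @param rho_inf spectral radius parameter (default 0.5)
#' @param dt time increment in seconds
#' @param n_steps number of steps
#' @param newton_tol absolute Newton residual tolerance
#' @param max_iter Newton iteration cap per step
#' @return list of class `time_config` including the derived
#'   [alpha_parameters()]
#' @export
time_config <- function(rho_inf = 0.5, dt = 1e-3, n_steps = 100L,
                        newton_tol = 1e-8, max_iter = 100L) {
  if (dt <= 0) stop("dt must be positive")
  structure(list(rho_inf = rho_inf, dt = dt, n_steps = as.integer(n_steps),
                 newton_tol = newton_tol, max_iter = as.integer(max_iter),
                 alpha = alpha_parameters(rho_inf)), class = "time_config")
}

## Fresh transient state: full-vector solution d, auxiliary displacement
## rate ud (the scheme's d-dot), velocity v and its rate vdot, plus the
## double-buffered quadrature-point inelastic strain.
transient_state <- function(model) {
  z <- numeric(model$ndof)
  list(d = z, ud = z, v = z, vdot = z,
       eps_i = matrix(0, 6L, model$nqp), t = 0)
}

#' One JWH-alpha step of the constrained coupled system
#'
#' Newton iteration on the solution increment with the residual evaluated at
#' the scheme's intermediate points (`d` and `v` at `n + alpha_f`, `vdot` at
#' `n + alpha_m`). The update recurrences are
#' `ud_{n+1} = ud_n + (Dd - dt ud_n)/(gamma_a dt)`,
#' the compatibility `v_{n+alpha_f} = ud_{n+alpha_m}`, and the same
#' recurrence for `vdot` from `v`; together they reproduce the generalized
#' tangent of [effective_tangent()] exactly, so a linear problem converges in
#' a single correction. Prescribed DOFs follow the identical recurrences
#' with their increment fixed by the load parameters. The inelastic strain
#' is advanced once per accepted step by the explicit Euler rule evaluated
#' on the trial stress.
#'
#' @param state transient state from a previous step (or fresh)
#' @param model an [fe_model()]
#' @param constr an `fe_constraints`
#' @param p_next prescribed parameter vector at the end of the step
#' @param cfg a [time_config()]
#' @param solver cached reduced solver for the generalized tangent
#'   (from [transient_solver()])
#' @param F external load vector (zero by default)
#' @return updated state; attributes `newton_iters` and `residual_history`
#' @export
jwh_step <- function(state, model, constr, p_next, cfg, solver, F = NULL) {
  if (is.null(F)) F <- numeric(model$ndof)
  a <- cfg$alpha; dt <- cfg$dt
  am <- a$alpha_m; af <- a$alpha_f; ga <- a$gamma_a
  Tm <- constr$T
  d_n <- state$d; ud_n <- state$ud; v_n <- state$v; vd_n <- state$vdot

  Qi <- as.numeric(model$Q %*% as.vector(state$eps_i))
  p_prev <- state$p %||% numeric(constr$np)
  # initial guess: previous solution with the prescribed part updated
  d1 <- d_n + as.numeric(constr$P %*% (p_next - p_prev))
  res_hist <- numeric(0)
  iters <- 0L
  repeat {
    Dd <- d1 - d_n
    ud1 <- ud_n + (Dd - dt * ud_n) / (ga * dt)
    ud_am <- ud_n + am * (ud1 - ud_n)
    v1 <- v_n + (ud_am - v_n) / af
    vd1 <- vd_n + (v1 - v_n - dt * vd_n) / (ga * dt)
    d_af <- d_n + af * Dd
    v_af <- v_n + af * (v1 - v_n)
    vd_am <- vd_n + am * (vd1 - vd_n)
    R <- F - as.numeric(model$M %*% vd_am) - as.numeric(model$C %*% v_af) -
      as.numeric(model$K %*% d_af) + Qi
    Rr <- as.numeric(Matrix::crossprod(Tm, R))
    rn <- sqrt(sum(Rr^2))
    res_hist <- c(res_hist, rn)
    # converged: absolute tolerance, or the same tolerance relative to the
    # step's initial residual when that exceeds unity (mixed-unit residuals
    # of macroscale problems have a roundoff floor far above tiny absolutes)
    if (rn < cfg$newton_tol * max(1, res_hist[1L])) break
    if (iters >= cfg$max_iter)
      stop("Newton failed to converge: residual history ",
           paste(signif(res_hist, 4), collapse = " "))
    d1 <- d1 + as.numeric(Tm %*% solver(Rr))
    iters <- iters + 1L
  }

  # commit: advance the inelastic strain on the converged trial stress
  eps_i <- state$eps_i
  for (ph in unique(model$qp_phase)) {
    tns <- model$materials[[ph]]
    if (tns$mu_v > 0) {
      idx <- model$qp_phase == ph
      eps <- matrix(model$Bu %*% d1, 6L, model$nqp)[, idx, drop = FALSE]
      sig_tr <- tns$C %*% (eps - eps_i[, idx, drop = FALSE])
      eps_i[, idx] <- evolve_inelastic_strain(eps_i[, idx, drop = FALSE],
                                              sig_tr, tns$mu_v, dt)
    }
  }
  out <- list(d = d1, ud = ud1, v = v1, vdot = vd1, eps_i = eps_i,
              t = state$t + dt, p = p_next)
  attr(out, "newton_iters") <- iters
  attr(out, "residual_history") <- res_hist
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Cached reduced solver for the generalized tangent
#' @param model an [fe_model()]
#' @param constr an `fe_constraints`
#' @param cfg a [time_config()]
#' @return solver function (reduced RHS to reduced increment)
#' @export
transient_solver <- function(model, constr, cfg) {
  S <- effective_tangent(model$M, model$C, model$K, cfg)
  Sr <- Matrix::crossprod(constr$T, S %*% constr$T)
  make_lu_solver(Sr)
}

#' Transient solve of the constrained coupled system
#'
#' Advances the model through the prescribed parameter history with
#' [jwh_step()], starting from quiescent initial conditions (zero fields and
#' rates), and records volume-averaged fluxes each step.
#'
#' @param model an [fe_model()]
#' @param constr an `fe_constraints`
#' @param p_history `np x n_steps` matrix of prescribed parameters (column k
#'   is the target at the end of step k); a vector is recycled as a constant
#'   single-parameter history
#' @param cfg a [time_config()]
#' @param record optional `function(step, state, model)` whose results are
#'   collected in the output `records` list
#' @return list with the final `state`, per-step `avg` (list of averaged
#'   `sigma`, `D`, `Ddot`, `H`, `J`), `newton_iters`, and optional `records`
#' @export
transient_solve <- function(model, constr, p_history, cfg, record = NULL) {
  if (!is.matrix(p_history))
    p_history <- matrix(p_history, nrow = constr$np, ncol = cfg$n_steps)
  stopifnot(nrow(p_history) == constr$np)
  nsteps <- ncol(p_history)
  solver <- transient_solver(model, constr, cfg)
  state <- transient_state(model)
  state$p <- numeric(constr$np)
  avg <- vector("list", nsteps)
  recs <- if (is.null(record)) NULL else vector("list", nsteps)
  iters <- integer(nsteps)
  for (k in seq_len(nsteps)) {
    prev_eps_i <- state$eps_i
    state <- jwh_step(state, model, constr, p_history[, k], cfg, solver)
    st <- qp_states(model, state$d, state$v, state$vdot)
    fl <- qp_fluxes(model, st, prev_eps_i)
    avg[[k]] <- average_fluxes(model, fl[!vapply(fl, is.null, TRUE)])
    iters[k] <- attr(state, "newton_iters")
    if (!is.null(record)) recs[[k]] <- record(k, state, model)
  }
  list(state = state, avg = avg, newton_iters = iters, records = recs)
}
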
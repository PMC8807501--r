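## Constraint handling by master-slave elimination. The full DOF vector is
## decomposed as d = P p(t) + T dr, where P maps a small vector of
## prescribed parameters (macro state components, or a load amplitude) to
## nodal values, and T injects the reduced unknowns (free/master DOFs) back
## into the full vector, duplicating masters onto their periodic slaves.

#' Periodic constraint set for a micro RVE
#'
#' Imposes the additive micro-state split: the total nodal fields are an
#' affine contribution of the macro state plus a periodic fluctuation,
#' \deqn{u = \bar\varepsilon y + \tilde u,\quad
#'       \varphi = -\bar E \cdot y + \tilde\varphi,\quad
#'       A = \tfrac12 \bar B \times y + \tilde A,}
#' with fluctuations equal on paired opposite-face nodes and zero at the
#' eight corner nodes. The affine vector-potential part is divergence-free
#' and has curl exactly `B_bar`, so it does not load the gauge penalty.
#'
#' @param mesh a periodic `hex_mesh` with resolved `periodic_pairs`
#' @return list of class `fe_constraints` with sparse `P` (ndof x 12,
#'   parameter order `eps_bar` 6, `E_bar` 3, `B_bar` 3), sparse `T`
#'   (ndof x nreduced) and bookkeeping indices
#' @export
periodic_constraints <- function(mesh) {
  nnode <- nrow(mesh$nodes)
  ndof <- nnode * N_DOF_NODE
  pairs <- mesh$periodic_pairs
  if (is.null(pairs)) pairs <- periodic_pairs(mesh)
  fixed <- attr(pairs, "fixed_nodes")

  ## affine imposition matrix P: columns (eps 6 | E 3 | B 3)
  y <- mesh$nodes
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  addP <- function(dofs, col, val) {
    ti <<- c(ti, dofs); tj <<- c(tj, rep.int(col, length(dofs))); tx <<- c(tx, val)
  }
  ux <- field_dofs(nnode, "u")[seq(1, 3 * nnode, 3)]
  uy <- ux + 1L; uz <- ux + 2L
  # u = eps_mat %*% y with Voigt (xx,yy,zz,xy,yz,xz), tensor shears = half
  addP(ux, 1L, y[, 1L]); addP(uy, 2L, y[, 2L]); addP(uz, 3L, y[, 3L])
  addP(ux, 4L, y[, 2L] / 2); addP(uy, 4L, y[, 1L] / 2)
  addP(uy, 5L, y[, 3L] / 2); addP(uz, 5L, y[, 2L] / 2)
  addP(ux, 6L, y[, 3L] / 2); addP(uz, 6L, y[, 1L] / 2)
  ph <- field_dofs(nnode, "phi")
  for (k in 1:3) addP(ph, 6L + k, -y[, k])
  Ax <- field_dofs(nnode, "A")[seq(1, 3 * nnode, 3)]
  Ay <- Ax + 1L; Az <- Ax + 2L
  # A = (B_bar x y) / 2
  addP(Ay, 10L, -y[, 3L] / 2); addP(Az, 10L, y[, 2L] / 2)
  addP(Ax, 11L, y[, 3L] / 2);  addP(Az, 11L, -y[, 1L] / 2)
  addP(Ax, 12L, -y[, 2L] / 2); addP(Ay, 12L, y[, 1L] / 2)
  P <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, 12L))

  ## reduction matrix T on fluctuations
  master_of <- seq_len(nnode)
  master_of[pairs[, "slave"]] <- pairs[, "master"]
  keep_nodes <- setdiff(which(master_of == seq_len(nnode)), fixed)
  red_col <- integer(nnode)          # first reduced column of each kept node
  red_col[keep_nodes] <- seq(1L, by = N_DOF_NODE, length.out = length(keep_nodes))
  nred <- length(keep_nodes) * N_DOF_NODE
  rows <- integer(0); cols <- integer(0)
  for (set in list(seq_len(nnode))) {
    src <- master_of[set]
    ok <- src %in% keep_nodes & !(set %in% fixed)
    n_ok <- set[ok]; m_ok <- src[ok]
    rows <- c(rows, node_dof_ids(n_ok))
    cols <- c(cols, as.vector(vapply(m_ok, function(m) red_col[m] + 0:(N_DOF_NODE - 1L),
                                     integer(N_DOF_NODE))))
  }
  T <- Matrix::sparseMatrix(i = rows, j = cols, x = 1, dims = c(ndof, nred))

  structure(list(P = P, T = T, np = 12L, nred = nred,
                 fixed_nodes = fixed, pairs = pairs), class = "fe_constraints")
}

#' Dirichlet constraint set for a macroscale model
#'
#' @param mesh a `hex_mesh`
#' @param zero_dofs integer DOF ids clamped to zero for all time
#' @param driven_dofs integer DOF ids following the load parameter
#' @param driven_value amplitude multiplier per driven DOF (recycled)
#' @return `fe_constraints` with a single load parameter (`np = 1`)
#' @export
dirichlet_constraints <- function(mesh, zero_dofs, driven_dofs,
                                  driven_value = 1) {
  ndof <- nrow(mesh$nodes) * N_DOF_NODE
  zero_dofs <- unique(zero_dofs)
  driven_dofs <- unique(driven_dofs)
  if (length(intersect(zero_dofs, driven_dofs)))
    stop("driven DOFs overlap clamped DOFs")
  P <- Matrix::sparseMatrix(i = driven_dofs, j = rep(1L, length(driven_dofs)),
                            x = rep_len(driven_value, length(driven_dofs)),
                            dims = c(ndof, 1L))
  free <- setdiff(seq_len(ndof), c(zero_dofs, driven_dofs))
  T <- Matrix::sparseMatrix(i = free, j = seq_along(free), x = 1,
                            dims = c(ndof, length(free)))
  structure(list(P = P, T = T, np = 1L, nred = length(free),
                 fixed_dofs = zero_dofs, driven_dofs = driven_dofs),
            class = "fe_constraints")
}

#' Stationary solve of the constrained coupled system
#'
#' Solves `K d = F` for the rate-free problem under the constraint
#' decomposition `d = P p + T dr` (reduced Galerkin projection
#' `T' K T dr = T' (F - K P p)`).
#'
#' @param model an [fe_model()]
#' @param constr an `fe_constraints`
#' @param p prescribed parameter vector (length `constr$np`)
#' @param F external load vector (defaults to zero)
#' @param solver optional cached reduced-solver from [static_solver()]
#' @return full DOF solution vector
#' @export
solve_static <- function(model, constr, p, F = NULL, solver = NULL) {
  if (is.null(F)) F <- numeric(model$ndof)
  if (is.null(solver)) solver <- static_solver(model, constr)
  dpre <- as.numeric(constr$P %*% p)
  rhs <- as.numeric(Matrix::crossprod(constr$T, F - model$K %*% dpre))
  dpre + as.numeric(constr$T %*% solver(rhs))
}

#' Cached reduced stationary solver
#' @param model an [fe_model()]
#' @param constr an `fe_constraints`
#' @return function mapping a reduced RHS to the reduced solution
#' @export
static_solver <- function(model, constr) {
  Kr <- Matrix::crossprod(constr$T, model$K %*% constr$T)
  make_lu_solver(Kr)
}
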
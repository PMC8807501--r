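## Global assembly of the coupled 7-field system
##
## An `fe_model` bundles, for one mesh and material set:
##   * the assembled sparse M, C, K of the transient system
##     R = F - M vdot - C v - K d (+ inelastic-strain term),
##   * stacked quadrature-point operators (symmetric gradient, gradient,
##     curl, divergence, interpolation) acting on the full DOF vector, used
##     for flux evaluation and volume averaging,
##   * the map Q sending quadrature-point inelastic strains to the internal
##     force they induce.
## M carries only the A-A (permittivity mass) block and K has no u-A
## coupling; these structural facts are consequences of the block
## definitions and are asserted in the test suite.

#' Assemble the coupled finite element model
#'
#' @param mesh a `hex_mesh`; if `mesh$phase` is `NULL` all elements use
#'   `materials$bone` (single-material mesh)
#' @param materials named list of [build_tensors()] results, one per phase
#'   tag occurring in the mesh (e.g. `bone`, `marrow`)
#' @param gamma divergence gauge penalty on the magnetic vector potential
#' @param dt time increment (s) entering the viscous consistent tangent
#' @param nquad Gauss points per direction
#' @param theta gauge-fixing mass coefficient on the vector potential (see
#'   [element_matrices()]); `"auto"` selects `gamma / L^2` from the domain
#'   bounding-box diagonal `L` (appropriate for bounded macro domains),
#'   `0` leaves the A-block exactly as the block definitions state
#'   (appropriate for periodic RVEs)
#' @return object of class `fe_model`
#' @export
fe_model <- function(mesh, materials, gamma = 1.0, dt = 1e-3, nquad = 2L,
                     theta = 0, relaxed_conduction = FALSE) {
  if (identical(theta, "auto"))
    theta <- gamma / sum((mesh$bbox[2L, ] - mesh$bbox[1L, ])^2)
  nelem <- nrow(mesh$conn)
  nnode <- nrow(mesh$nodes)
  ndof <- nnode * N_DOF_NODE
  phase <- mesh$phase
  if (is.null(phase)) phase <- rep(names(materials)[1L], nelem)
  slc <- elem_dof_slices()
  gp <- gauss_points_hex(nquad)
  nqp_e <- length(gp$w)
  nqp <- nelem * nqp_e

  tri <- function() list(i = vector("list", nelem), j = vector("list", nelem),
                         x = vector("list", nelem))
  KT <- tri(); CT <- tri(); MT <- tri(); QT <- tri()
  opsT <- list(Bu = tri(), Bg = tri(), Bc = tri(), Bd = tri(), NAm = tri())

  wq <- numeric(nqp)
  cache <- new.env(parent = emptyenv())
  volume <- 0

  for (e in seq_len(nelem)) {
    en <- mesh$conn[e, ]
    X <- mesh$nodes[en, , drop = FALSE]
    tns <- materials[[phase[e]]]
    if (is.null(tns)) stop("no material for phase '", phase[e], "'")

    # axis-aligned box elements (the RVE grid) share cached matrices
    dims <- apply(X, 2L, function(v) max(v) - min(v))
    is_box <- all(abs(sweep(X, 2L, X[1L, ]) -
                        ((hex_local_nodes() + 1) / 2) %*% base::diag(dims)) < 1e-12 * max(dims))
    key <- if (is_box) paste(phase[e], paste(signif(dims, 12L), collapse = "|")) else NA
    ed <- if (!is.na(key) && !is.null(cache[[key]])) cache[[key]] else {
      blk <- element_matrices(X, tns, gamma = gamma, dt = dt, nquad = nquad,
                              theta = theta,
                              relaxed_conduction = relaxed_conduction)
      Ke <- matrix(0, 56, 56); Ce <- matrix(0, 56, 56); Me <- matrix(0, 56, 56)
      Ke[slc$u, slc$u] <- blk$Kuu;   Ke[slc$u, slc$phi] <- blk$Kup
      Ke[slc$phi, slc$u] <- blk$Kpu; Ke[slc$phi, slc$phi] <- blk$Kpp
      Ke[slc$A, slc$A] <- blk$KAA;   Ke[slc$A, slc$phi] <- blk$KAp
      Ce[slc$u, slc$A] <- blk$CuA;   Ce[slc$A, slc$u] <- blk$CAu
      Ce[slc$phi, slc$A] <- blk$CpA; Ce[slc$A, slc$phi] <- blk$CAp
      Ce[slc$A, slc$A] <- blk$CAA
      Me[slc$A, slc$A] <- blk$MAA
      ops <- lapply(seq_len(nqp_e), function(q) {
        op <- operator_matrices(X, gp$xi[q, ])
        op$w <- op$detJ * gp$w[q]
        op
      })
      # stacked quadrature values (column-major per qp) for fast assembly
      stk <- function(get) as.numeric(unlist(lapply(ops, get)))
      Qe <- if (tns$mu_v > 0)
        stk(function(op) op$w * crossprod(op$B_u, tangent_stiffness(tns, dt)))
      else NULL
      val <- list(Ke = as.vector(Ke), Ce = as.vector(Ce), Me = as.vector(Me),
                  w = vapply(ops, `[[`, numeric(1L), "w"),
                  Bu = stk(function(op) op$B_u), Bg = stk(function(op) op$B_grad),
                  Bc = stk(function(op) op$B_curl), Bd = stk(function(op) op$B_div),
                  NAm = stk(function(op) op$N_A), Qe = Qe,
                  volume = blk$volume)
      if (!is.na(key)) cache[[key]] <- val
      val
    }

    gd <- node_dof_ids(en)
    ii <- rep(gd, times = 56L); jj <- rep(gd, each = 56L)
    KT$i[[e]] <- ii; KT$j[[e]] <- jj; KT$x[[e]] <- ed$Ke
    CT$i[[e]] <- ii; CT$j[[e]] <- jj; CT$x[[e]] <- ed$Ce
    MT$i[[e]] <- ii; MT$j[[e]] <- jj; MT$x[[e]] <- ed$Me
    volume <- volume + ed$volume

    udofs <- gd[slc$u]; pdofs <- gd[slc$phi]; Adofs <- gd[slc$A]
    qbase <- (e - 1L) * nqp_e
    wq[qbase + seq_len(nqp_e)] <- ed$w
    # row/col index patterns over all qps of the element, column-major
    idx <- function(nr, ncol_, dofs, rowblk) {
      rows <- rep(rowblk * (rep(seq_len(nqp_e), each = nr * ncol_) - 1L), 1L) +
        rep(rep(seq_len(nr), times = ncol_), times = nqp_e) + (qbase * rowblk)
      cols <- rep(rep(dofs, each = nr), times = nqp_e)
      list(i = rows, j = cols)
    }
    bu <- idx(6L, 24L, udofs, 6L)
    bg <- idx(3L, 8L, pdofs, 3L)
    bc <- idx(3L, 24L, Adofs, 3L)
    bd <- idx(1L, 24L, Adofs, 1L)
    opsT$Bu$i[[e]] <- bu$i; opsT$Bu$j[[e]] <- bu$j; opsT$Bu$x[[e]] <- ed$Bu
    opsT$Bg$i[[e]] <- bg$i; opsT$Bg$j[[e]] <- bg$j; opsT$Bg$x[[e]] <- ed$Bg
    opsT$Bc$i[[e]] <- bc$i; opsT$Bc$j[[e]] <- bc$j; opsT$Bc$x[[e]] <- ed$Bc
    opsT$Bd$i[[e]] <- bd$i; opsT$Bd$j[[e]] <- bd$j; opsT$Bd$x[[e]] <- ed$Bd
    opsT$NAm$i[[e]] <- bc$i; opsT$NAm$j[[e]] <- bc$j; opsT$NAm$x[[e]] <- ed$NAm
    if (!is.null(ed$Qe)) {
      # Q block per qp is 24 x 6: rows are u DOFs, cols are qp strain slots
      QT$i[[e]] <- rep(rep(udofs, times = 6L), times = nqp_e)
      QT$j[[e]] <- rep((qbase + rep(seq_len(nqp_e), each = 144L) - 1L) * 6L, 1L) +
        rep(rep(1:6, each = 24L), times = nqp_e)
      QT$x[[e]] <- ed$Qe
    }
  }

  sp <- function(tr, nr, nc) Matrix::drop0(Matrix::sparseMatrix(
    i = as.integer(unlist(tr$i)), j = as.integer(unlist(tr$j)),
    x = as.numeric(unlist(tr$x)), dims = c(nr, nc)))

  structure(list(
    mesh = mesh, materials = materials, gamma = gamma, dt = dt, theta = theta,
    relaxed_conduction = relaxed_conduction,
    ndof = ndof, nqp = nqp, volume = volume,
    qp_phase = rep(phase, each = nqp_e), qp_elem = rep(seq_len(nelem), each = nqp_e),
    qp_w = wq,
    K = sp(KT, ndof, ndof), C = sp(CT, ndof, ndof), M = sp(MT, ndof, ndof),
    Q = sp(QT, ndof, 6L * nqp),
    Bu = sp(opsT$Bu, 6L * nqp, ndof), Bg = sp(opsT$Bg, 3L * nqp, ndof),
    Bc = sp(opsT$Bc, 3L * nqp, ndof), Bd = sp(opsT$Bd, nqp, ndof),
    NAm = sp(opsT$NAm, 3L * nqp, ndof)
  ), class = "fe_model")
}

## DOF ids of a given field over all nodes: field in {"u","phi","A"}
field_dofs <- function(nnode, field) {
  off <- switch(field, u = 1:3, phi = 4L, A = 5:7)
  as.vector(outer(off, (seq_len(nnode) - 1L) * N_DOF_NODE, "+"))
}

#' Quadrature-point states from nodal fields
#'
#' Evaluates strain, electric field and magnetic flux density (and their
#' rates where requested) at every quadrature point: `eps = B_u d`,
#' `E = -grad(phi) - Adot`, `B = curl A`.
#'
#' @param model an [fe_model()]
#' @param d full nodal solution vector
#' @param v full nodal rate vector (`NULL` for rate-free states)
#' @param vdot full nodal second-rate vector (for `Edot`)
#' @return list of 6 x nqp / 3 x nqp matrices `eps`, `E`, `B` and, when the
#'   rates are supplied, `epsdot` and `Edot`
#' @export
qp_states <- function(model, d, v = NULL, vdot = NULL) {
  nqp <- model$nqp
  out <- list(
    eps = matrix(model$Bu %*% d, 6L, nqp),
    E = matrix(-(model$Bg %*% d) - if (is.null(v)) 0 else model$NAm %*% v, 3L, nqp),
    B = matrix(model$Bc %*% d, 3L, nqp)
  )
  if (!is.null(v)) {
    out$epsdot <- matrix(model$Bu %*% v, 6L, nqp)
    out$Edot <- matrix(-(model$Bg %*% v) -
                         if (is.null(vdot)) 0 else model$NAm %*% vdot, 3L, nqp)
    # inductive part of E alone (-Adot): drives the conduction current in
    # the relaxed-conductor limit
    out$E_ind <- matrix(-(model$NAm %*% v), 3L, nqp)
  }
  out
}

#' Quadrature-point fluxes from states
#'
#' Applies the per-phase constitutive law at every quadrature point (bone:
#' piezoelectric elastic; marrow: viscoelastic conducting with the inelastic
#' strain frozen at its step-n value, i.e. the per-step linearized law).
#'
#' @param model an [fe_model()]
#' @param st state list from [qp_states()]
#' @param eps_i 6 x nqp inelastic strain (step-n values)
#' @return list of matrices `sigma` (6 x nqp), `D`, `H`, `J` and, when rate
#'   states are present, `Ddot` (3 x nqp)
#' @export
qp_fluxes <- function(model, st, eps_i = NULL) {
  nqp <- model$nqp
  if (is.null(eps_i)) eps_i <- matrix(0, 6L, nqp)
  sigma <- matrix(0, 6L, nqp); D <- matrix(0, 3L, nqp)
  H <- matrix(0, 3L, nqp); J <- matrix(0, 3L, nqp)
  Ddot <- if (!is.null(st$Edot)) matrix(0, 3L, nqp) else NULL
  for (ph in unique(model$qp_phase)) {
    idx <- model$qp_phase == ph
    tns <- model$materials[[ph]]
    Ct <- tangent_stiffness(tns, model$dt)
    sigma[, idx] <- Ct %*% (st$eps[, idx, drop = FALSE] - eps_i[, idx, drop = FALSE]) -
      t(tns$e) %*% st$E[, idx, drop = FALSE]
    D[, idx] <- tns$e %*% st$eps[, idx, drop = FALSE] +
      tns$xi %*% st$E[, idx, drop = FALSE]
    H[, idx] <- tns$mu_inv %*% st$B[, idx, drop = FALSE]
    E_J <- if (isTRUE(model$relaxed_conduction) && !is.null(st$E_ind))
      st$E_ind else st$E
    J[, idx] <- tns$kappa %*% E_J[, idx, drop = FALSE]
    if (!is.null(Ddot))
      Ddot[, idx] <- tns$e %*% st$epsdot[, idx, drop = FALSE] +
        tns$xi %*% st$Edot[, idx, drop = FALSE]
  }
  list(sigma = sigma, D = D, H = H, J = J, Ddot = Ddot)
}

#' Volume averages of quadrature-point fields
#'
#' @param model an [fe_model()]
#' @param fields list of k x nqp matrices (or a single matrix)
#' @return list of k-vectors (or a single vector): volume-weighted averages
#' @export
average_fluxes <- function(model, fields) {
  avg1 <- function(m) drop(m %*% model$qp_w) / model$volume
  if (is.matrix(fields)) avg1(fields) else lapply(fields, avg1)
}

## Diagonally scaled sparse LU solver factory. The coupled tangent mixes
## stiffness (~1e10), permittivity (~1e-11) and penalty (~1) blocks; the
## symmetric two-sided scaling keeps the factorization well conditioned.
make_lu_solver <- function(A) {
  dg <- abs(Matrix::diag(A))
  dinv <- 1 / sqrt(pmax(dg, max(dg) * 1e-300))
  Dm <- Matrix::Diagonal(x = dinv)
  As <- Dm %*% A %*% Dm
  fac <- Matrix::lu(As)
  ## tol = 0: the A-subsystem carries discrete-harmonic gauge modes whose
  ## only stiffness is the (physically tiny) permittivity mass, so the
  ## scaled tangent is legitimately very ill-conditioned; those modes are
  ## barely excited by the residual and the LU solve handles them stably.
  function(b) dinv * as.numeric(Matrix::solve(fac, dinv * b, tol = 0))
}
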
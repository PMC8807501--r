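## Trilinear hexahedral element with 7 DOFs per node (u_x, u_y, u_z, phi,
## A_x, A_y, A_z). Per-node DOF order and node-major global numbering are
## fixed here; every assembly routine relies on this layout.

N_DOF_NODE <- 7L

node_dof_ids <- function(nodes) {
  # global DOF ids of the given nodes, node-major, 7 per node
  as.vector(t(outer(nodes - 1L, rep(1L, N_DOF_NODE)) * N_DOF_NODE +
                matrix(1:N_DOF_NODE, length(nodes), N_DOF_NODE, byrow = TRUE)))
}

## Block slices of the 56 element DOFs (8 nodes x 7)
elem_dof_slices <- function() {
  all <- matrix(seq_len(8L * N_DOF_NODE), nrow = N_DOF_NODE)
  list(u = as.vector(all[1:3, ]), phi = all[4L, ], A = as.vector(all[5:7, ]))
}

#' Trilinear shape functions of the 8-node hexahedron
#'
#' @param xi local coordinates in the reference cube `[-1, 1]^3`
#' @return list with `N` (8-vector) and `dN` (8x3 local derivatives)
#' @export
shape_hex <- function(xi) {
  ln <- hex_local_nodes()
  a <- 1 + ln[, 1L] * xi[1L]
  b <- 1 + ln[, 2L] * xi[2L]
  c_ <- 1 + ln[, 3L] * xi[3L]
  list(
    N = a * b * c_ / 8,
    dN = cbind(ln[, 1L] * b * c_, a * ln[, 2L] * c_, a * b * ln[, 3L]) / 8
  )
}

#' Tensor-product Gauss quadrature on the reference cube
#'
#' @param n points per direction (2 is exact for all trilinear bilinear
#'   forms on parallelepiped elements and is the scheme used throughout)
#' @return list with `xi` (n^3 x 3 points) and `w` (weights)
#' @export
gauss_points_hex <- function(n = 2L) {
  gl <- switch(as.character(n),
    "1" = list(x = 0, w = 2),
    "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
    "3" = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9),
    "4" = {
      a <- sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5)); b <- sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))
      wa <- (18 + sqrt(30)) / 36; wb <- (18 - sqrt(30)) / 36
      list(x = c(-b, -a, a, b), w = c(wb, wa, wa, wb))
    },
    stop("unsupported quadrature order"))
  g <- expand.grid(x = gl$x, y = gl$x, z = gl$x)
  w <- apply(expand.grid(gl$w, gl$w, gl$w), 1L, prod)
  list(xi = as.matrix(g), w = w)
}

#' Discrete operator matrices of the coupled element at one local point
#'
#' Builds the symmetric-gradient (6x24), gradient (3x8), curl (3x24) and
#' divergence (1x24) operators together with the interpolation matrices,
#' from the trilinear shape-function derivatives mapped through the element
#' Jacobian. Voigt order xx, yy, zz, xy, yz, xz with engineering shears.
#'
#' @param X 8x3 matrix of element node coordinates
#' @param xi local coordinates in the reference cube
#' @return list with `B_u`, `B_grad`, `B_curl`, `B_div`, `N_u` (3x24),
#'   `N_phi` (1x8), `N_A` (3x24) and `detJ`
#' @export
operator_matrices <- function(X, xi) {
  sh <- shape_hex(xi)
  J <- crossprod(sh$dN, X)            # J[k,l] = d x_l / d xi_k
  detJ <- det(J)
  if (detJ <= 0) stop("degenerate element Jacobian (detJ <= 0)")
  dN <- sh$dN %*% t(solve(J))         # dN[i,l] = d N_i / d x_l
  dimnames(dN) <- NULL
  N <- sh$N

  B_u <- matrix(0, 6, 24)
  B_curl <- matrix(0, 3, 24)
  B_div <- matrix(0, 1, 24)
  N_u <- matrix(0, 3, 24)
  for (i in 1:8) {
    c0 <- 3L * (i - 1L)
    dx <- dN[i, 1L]; dy <- dN[i, 2L]; dz <- dN[i, 3L]
    B_u[1L, c0 + 1L] <- dx
    B_u[2L, c0 + 2L] <- dy
    B_u[3L, c0 + 3L] <- dz
    B_u[4L, c0 + 1L] <- dy; B_u[4L, c0 + 2L] <- dx
    B_u[5L, c0 + 2L] <- dz; B_u[5L, c0 + 3L] <- dy
    B_u[6L, c0 + 1L] <- dz; B_u[6L, c0 + 3L] <- dx
    B_curl[1L, c0 + 2L] <- -dz; B_curl[1L, c0 + 3L] <- dy
    B_curl[2L, c0 + 1L] <- dz;  B_curl[2L, c0 + 3L] <- -dx
    B_curl[3L, c0 + 1L] <- -dy; B_curl[3L, c0 + 2L] <- dx
    B_div[1L, c0 + 1:3] <- c(dx, dy, dz)
    N_u[1L, c0 + 1L] <- N[i]; N_u[2L, c0 + 2L] <- N[i]; N_u[3L, c0 + 3L] <- N[i]
  }
  list(B_u = B_u, B_grad = t(dN), B_curl = B_curl, B_div = B_div,
       N_u = N_u, N_phi = matrix(N, 1L), N_A = N_u, detJ = detJ)
}

#' Element matrices of the coupled 7-field hexahedron
#'
#' Computes all nonzero blocks of the element stiffness, damping and mass
#' matrices of the coupled system by Gauss quadrature: the mechanical block
#' with the consistent tangent, the piezoelectric coupling blocks, the
#' (negative-definite) permittivity block, the curl-curl block with the
#' divergence gauge penalty `gamma`, the conduction blocks tying the vector
#' potential to the scalar potential, the permittivity-rate and
#' piezoelectric-rate damping blocks and the permittivity mass block.
#'
#' @param X 8x3 element node coordinates
#' @param tensors phase [build_tensors()] result (or effective tensors)
#' @param gamma divergence gauge penalty
#' @param dt time increment entering the viscous tangent
#' @param nquad quadrature points per direction
#' @param theta gauge-fixing mass coefficient on the vector potential
#'   (`theta * int A . dA dV` added to the A-A stiffness block); zero for
#'   periodic micro problems, `gamma / L^2` on bounded macro domains where
#'   discrete-harmonic A-modes would otherwise be unresolved
#' @param relaxed_conduction if `TRUE`, the irrotational conduction current
#'   is treated as screened by relaxed free charge (the quasi-static
#'   conductor limit, relaxation time `xi/kappa`): the `K_Aphi` block is
#'   omitted so only the inductive current `-kappa Adot` sources the
#'   vector potential. Appropriate for bounded macroscale domains; periodic
#'   micro RVEs use the unmodified equations
#' @return list of blocks `Kuu` (24x24), `Kup` (24x8), `Kpu`, `Kpp` (8x8),
#'   `KAA` (24x24), `KAp` (24x8), `CuA` (24x24), `CAu`, `CpA` (8x24),
#'   `CAp` (24x8), `CAA`, `MAA` and the element `volume`
#' @export
element_matrices <- function(X, tensors, gamma = 1.0, dt = 1e-3, nquad = 2L,
                             theta = 0, relaxed_conduction = FALSE) {
  gp <- gauss_points_hex(nquad)
  Ct <- tangent_stiffness(tensors, dt)
  e <- tensors$e; xi_t <- tensors$xi; mu_inv <- tensors$mu_inv
  kap <- tensors$kappa
  z24 <- matrix(0, 24, 24); z248 <- matrix(0, 24, 8)
  blk <- list(Kuu = z24, Kup = z248, Kpu = t(z248), Kpp = matrix(0, 8, 8),
              KAA = z24, KAp = z248, CuA = z24, CAu = z24,
              CpA = t(z248), CAp = z248, CAA = z24, MAA = z24, volume = 0)
  for (q in seq_along(gp$w)) {
    op <- operator_matrices(X, gp$xi[q, ])
    w <- op$detJ * gp$w[q]
    Bu <- op$B_u; Bg <- op$B_grad; Bc <- op$B_curl; Bd <- op$B_div; NA_ <- op$N_A
    blk$Kuu <- blk$Kuu + w * crossprod(Bu, Ct %*% Bu)
    blk$Kup <- blk$Kup + w * crossprod(Bu, t(e) %*% Bg)
    blk$Kpu <- blk$Kpu + w * crossprod(Bg, e %*% Bu)
    blk$Kpp <- blk$Kpp - w * crossprod(Bg, xi_t %*% Bg)
    blk$KAA <- blk$KAA + w * (crossprod(Bc, mu_inv %*% Bc) + gamma * crossprod(Bd) +
                                theta * crossprod(NA_))
    if (!relaxed_conduction) blk$KAp <- blk$KAp + w * crossprod(NA_, kap %*% Bg)
    blk$CuA <- blk$CuA + w * crossprod(Bu, t(e) %*% NA_)
    blk$CAu <- blk$CAu - w * crossprod(NA_, e %*% Bu)
    blk$CpA <- blk$CpA - w * crossprod(Bg, xi_t %*% NA_)
    blk$CAp <- blk$CAp + w * crossprod(NA_, xi_t %*% Bg)
    blk$CAA <- blk$CAA + w * crossprod(NA_, kap %*% NA_)
    blk$MAA <- blk$MAA + w * crossprod(NA_, xi_t %*% NA_)
    blk$volume <- blk$volume + w
  }
  blk
}
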
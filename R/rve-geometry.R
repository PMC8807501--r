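#' Cortical bone volume fraction of the parametric RVE
#'
#' The periodic representative volume element (RVE) of cancellous bone is a
#' cube of edge length \eqn{2a+b} containing three orthogonal square rods of
#' cortical bone of cross-section \eqn{b \times b} crossing at the center,
#' embedded in bone marrow. The cortical volume fraction follows from
#' inclusion-exclusion of the three rods:
#' \deqn{\rho_b = \frac{6ab^2 + b^3}{(2a+b)^3}.}
#'
#' @param a outer segment length (mm or any consistent unit), `a > 0`
#' @param b central segment length (rod thickness), `b >= 0`
#' @return cortical bone volume fraction in `[0, 1)`
#' @examples
#' cortical_volume_fraction(0.32, 0.36)  # healthy bone, ~0.295
#' cortical_volume_fraction(0.43, 0.14)  # degenerated bone, ~0.053
#' @export
cortical_volume_fraction <- function(a, b) {
  if (any(a <= 0)) stop("segment length 'a' must be positive")
  if (any(b < 0)) stop("segment length 'b' must be non-negative")
  (6 * a * b^2 + b^3) / (2 * a + b)^3
}

#' RVE lengths parameters
#'
#' Bundles the geometric parameters of the two-phase bone RVE. Lengths are
#' given in millimeters (the natural scale of trabecular microstructure) and
#' converted to meters internally; all mesh coordinates are SI.
#'
#' @param a_mm outer (marrow) segment length in mm
#' @param b_mm central (cortical rod) segment length in mm
#' @param elements_per_segment elements per axis segment; 2 gives the coarse
#'   6-element-per-direction RVE, 4 the fine 12-element one
#' @return object of class `rve_params` with fields `a`, `b` (m),
#'   `elements_per_segment`, `edge_length` (m) and `rho_b`
#' @export
rve_params <- function(a_mm = 0.32, b_mm = 0.36, elements_per_segment = 2) {
  if (a_mm <= 0 || b_mm <= 0) stop("segment lengths must be positive")
  if (elements_per_segment < 1 || elements_per_segment != round(elements_per_segment))
    stop("elements_per_segment must be a positive integer")
  a <- a_mm * 1e-3
  b <- b_mm * 1e-3
  structure(list(
    a = a, b = b,
    elements_per_segment = as.integer(elements_per_segment),
    edge_length = 2 * a + b,
    rho_b = cortical_volume_fraction(a, b)
  ), class = "rve_params")
}

## Local node ordering of the 8-node hexahedron: counterclockwise bottom face
## (-,-,-), (+,-,-), (+,+,-), (-,+,-) then top face in the same sense. All
## element routines (shape functions, quadrature, assembly) rely on it.
hex_local_nodes <- function() {
  cbind(
    x = c(-1, 1, 1, -1, -1, 1, 1, -1),
    y = c(-1, -1, 1, 1, -1, -1, 1, 1),
    z = c(-1, -1, -1, -1, 1, 1, 1, 1)
  )
}

## Structured hexahedral grid from per-axis breakpoints. Returns node
## coordinates ((nx+1)(ny+1)(nz+1) x 3) and connectivity (nelem x 8).
structured_hex_grid <- function(xs, ys, zs) {
  nx <- length(xs) - 1L; ny <- length(ys) - 1L; nz <- length(zs) - 1L
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (length(xs)) * ((j - 1L) + (length(ys)) * (k - 1L))
  ijk <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  i <- ijk$i; j <- ijk$j; k <- ijk$k
  conn <- cbind(
    nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
    nid(i, j, k + 1L), nid(i + 1L, j, k + 1L), nid(i + 1L, j + 1L, k + 1L),
    nid(i, j + 1L, k + 1L)
  )
  list(nodes = nodes, conn = conn, dims = c(nx, ny, nz))
}

## Breakpoints of one RVE axis: segments [a, b, a], each split into n equal
## elements. Phase interfaces therefore coincide with element faces.
rve_axis_breaks <- function(a, b, n) {
  c(seq(0, a, length.out = n + 1L),
    a + seq(0, b, length.out = n + 1L)[-1L],
    (a + b) + seq(0, a, length.out = n + 1L)[-1L])
}

#' Build the periodic two-phase bone RVE mesh
#'
#' Generates a structured hexahedral mesh of the cube \eqn{[0, 2a+b]^3} whose
#' axes are partitioned into segments `[a, b, a]`, each subdivided into
#' `elements_per_segment` equal elements. An element belongs to the cortical
#' bone phase iff at least two of its three segment indices fall in the
#' middle (`b`) segment, which reproduces the three orthogonal cortical rods
#' of the RVE; all remaining elements are bone marrow.
#'
#' @param params an [rve_params()] object
#' @return object of class `hex_mesh` with node coordinates (m),
#'   connectivity, per-element `phase` (`"bone"`/`"marrow"`), named boundary
#'   `face_sets`, `corner_nodes`, and resolved `periodic_pairs`
#' @seealso [periodic_pairs()], [cortical_volume_fraction()]
#' @export
build_rve_mesh <- function(params) {
  stopifnot(inherits(params, "rve_params"))
  n <- params$elements_per_segment
  brk <- rve_axis_breaks(params$a, params$b, n)
  g <- structured_hex_grid(brk, brk, brk)

  # segment index (1=a, 2=b, 3=a) of each element along each axis
  seg_of <- function(eidx) (eidx - 1L) %/% n + 1L
  ne1 <- g$dims[1L]
  ijk <- expand.grid(i = seq_len(ne1), j = seq_len(ne1), k = seq_len(ne1))
  mid <- cbind(seg_of(ijk$i) == 2L, seg_of(ijk$j) == 2L, seg_of(ijk$k) == 2L)
  phase <- ifelse(rowSums(mid) >= 2L, "bone", "marrow")

  mesh <- new_hex_mesh(g$nodes, g$conn, phase)
  mesh$params <- params
  mesh$periodic_pairs <- periodic_pairs(mesh)
  mesh
}

## Constructor shared by the RVE and macro meshes: computes boundary face
## sets and corner nodes from the bounding box.
new_hex_mesh <- function(nodes, conn, phase = NULL) {
  lo <- apply(nodes, 2L, min); hi <- apply(nodes, 2L, max)
  tol <- 1e-9 * max(hi - lo)
  face_sets <- list(
    xmin = which(abs(nodes[, 1L] - lo[1L]) < tol),
    xmax = which(abs(nodes[, 1L] - hi[1L]) < tol),
    ymin = which(abs(nodes[, 2L] - lo[2L]) < tol),
    ymax = which(abs(nodes[, 2L] - hi[2L]) < tol),
    zmin = which(abs(nodes[, 3L] - lo[3L]) < tol),
    zmax = which(abs(nodes[, 3L] - hi[3L]) < tol)
  )
  on_x <- abs(nodes[, 1L] - lo[1L]) < tol | abs(nodes[, 1L] - hi[1L]) < tol
  on_y <- abs(nodes[, 2L] - lo[2L]) < tol | abs(nodes[, 2L] - hi[2L]) < tol
  on_z <- abs(nodes[, 3L] - lo[3L]) < tol | abs(nodes[, 3L] - hi[3L]) < tol
  corners <- which(on_x & on_y & on_z)
  structure(list(
    nodes = nodes, conn = conn, phase = phase,
    face_sets = face_sets, corner_nodes = corners,
    bbox = rbind(lo, hi)
  ), class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat("hex_mesh:", nrow(x$nodes), "nodes,", nrow(x$conn), "elements\n")
  if (!is.null(x$phase)) {
    vf <- element_volumes(x)
    f <- sum(vf[x$phase == "bone"]) / sum(vf)
    cat(sprintf("  phases: %d bone / %d marrow (bone volume fraction %.4f)\n",
                sum(x$phase == "bone"), sum(x$phase == "marrow"), f))
  }
  invisible(x)
}

#' Element volumes of a hexahedral mesh
#'
#' Exact for trilinear hexahedra via 2x2x2 Gauss quadrature of the Jacobian
#' determinant.
#'
#' @param mesh a `hex_mesh`
#' @return numeric vector of element volumes
#' @export
element_volumes <- function(mesh) {
  gp <- gauss_points_hex(2L)
  vols <- numeric(nrow(mesh$conn))
  dN <- lapply(seq_len(nrow(gp$xi)), function(q) shape_hex(gp$xi[q, ])$dN)
  for (e in seq_len(nrow(mesh$conn))) {
    X <- mesh$nodes[mesh$conn[e, ], , drop = FALSE]
    v <- 0
    for (q in seq_along(dN)) v <- v + det(crossprod(dN[[q]], X)) * gp$w[q]
    vols[e] <- v
  }
  vols
}

#' Resolve periodic node pairings of a geometrically periodic mesh
#'
#' Matches boundary nodes across the three opposite-face pairs of the
#' bounding box by brute-force coordinate comparison, then resolves chains
#' (nodes shared by several face pairs, i.e. edge nodes) by union-find so
#' that every constrained node points to exactly one ultimate master. The
#' eight corner nodes are excluded: all their degrees of freedom are fixed to
#' suppress rigid-body and constant-potential modes.
#'
#' @param mesh a `hex_mesh` whose opposite boundary faces have matching node
#'   layouts
#' @param tol matching tolerance relative to the edge length
#' @return two-column integer matrix `(slave, master)`; attribute
#'   `fixed_nodes` holds the corner node ids
#' @export
periodic_pairs <- function(mesh, tol = 1e-12) {
  nodes <- mesh$nodes
  lo <- mesh$bbox[1L, ]; hi <- mesh$bbox[2L, ]
  L <- hi - lo
  eps <- max(L) * max(tol, 1e-14)

  parent <- seq_len(nrow(nodes))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }

  for (ax in 1:3) {
    lo_set <- mesh$face_sets[[2L * ax - 1L]]
    hi_set <- mesh$face_sets[[2L * ax]]
    if (length(lo_set) != length(hi_set))
      stop("opposite faces have differing node counts along axis ", ax)
    other <- setdiff(1:3, ax)
    key <- function(set) paste(round(nodes[set, other[1L]] / eps),
                               round(nodes[set, other[2L]] / eps))
    m <- match(key(hi_set), key(lo_set))
    if (anyNA(m)) stop("opposite-face node layouts do not match along axis ", ax)
    for (s in seq_along(hi_set)) {
      ra <- find(hi_set[s]); rb <- find(lo_set[m[s]])
      # root with smaller id becomes the representative
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nrow(nodes)), find, integer(1L))
  constrained <- setdiff(which(roots != seq_len(nrow(nodes))), mesh$corner_nodes)
  pairs <- cbind(slave = constrained, master = roots[constrained])
  # chains ending at a corner: the corner is the fixed master
  structure(pairs, fixed_nodes = mesh$corner_nodes)
}
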
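#' Isotropic linear-elastic material
#'
#' @param young_modulus Young's modulus E in MPa (> 0).
#' @param poisson_ratio Poisson's ratio nu, in (0, 0.5).
#' @return An object of class `material` with E, nu and the Lame constants
#'   `lambda`, `mu` (MPa).
#' @export
material <- function(young_modulus, poisson_ratio) {
  m <- list(
    young_modulus = young_modulus,
    poisson_ratio = poisson_ratio,
    lambda = young_modulus * poisson_ratio /
      ((1 + poisson_ratio) * (1 - 2 * poisson_ratio)),
    mu = young_modulus / (2 * (1 + poisson_ratio))
  )
  class(m) <- "material"
  validate_material(m)
  m
}

validate_material <- function(m) {
  if (!is.numeric(m$young_modulus) || m$young_modulus <= 0) {
    stop("material: Young's modulus must be positive (MPa)")
  }
  if (!is.numeric(m$poisson_ratio) || m$poisson_ratio <= 0 || m$poisson_ratio >= 0.5) {
    stop("material: Poisson's ratio must lie in (0, 0.5)")
  }
  invisible(m)
}

# constant shape-function gradients G[m, a, p] (dN_a/dx_p) and volumes for
# all tets; x = x1 + D xi with D columns (x2-x1, x3-x1, x4-x1), so
# grad N_{1+j} = row j of D^{-1} and grad N_1 = -sum of the others
tet_gradients <- function(nodes, tets) {
  M <- nrow(tets)
  a <- nodes[tets[, 1], , drop = FALSE]
  d1 <- nodes[tets[, 2], , drop = FALSE] - a
  d2 <- nodes[tets[, 3], , drop = FALSE] - a
  d3 <- nodes[tets[, 4], , drop = FALSE] - a
  det3 <- d1[, 1] * (d2[, 2] * d3[, 3] - d2[, 3] * d3[, 2]) -
    d1[, 2] * (d2[, 1] * d3[, 3] - d2[, 3] * d3[, 1]) +
    d1[, 3] * (d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1])
  if (any(abs(det3) < .Machine$double.eps)) stop("degenerate tetrahedron")
  # rows of inverse of D = [d1 d2 d3] (columns), via adjugate / det
  inv <- array(0, c(M, 3, 3))
  inv[, 1, 1] <- (d2[, 2] * d3[, 3] - d2[, 3] * d3[, 2]) / det3
  inv[, 1, 2] <- (d2[, 3] * d3[, 1] - d2[, 1] * d3[, 3]) / det3
  inv[, 1, 3] <- (d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1]) / det3
  inv[, 2, 1] <- (d1[, 3] * d3[, 2] - d1[, 2] * d3[, 3]) / det3
  inv[, 2, 2] <- (d1[, 1] * d3[, 3] - d1[, 3] * d3[, 1]) / det3
  inv[, 2, 3] <- (d1[, 2] * d3[, 1] - d1[, 1] * d3[, 2]) / det3
  inv[, 3, 1] <- (d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2]) / det3
  inv[, 3, 2] <- (d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3]) / det3
  inv[, 3, 3] <- (d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) / det3
  G <- array(0, c(M, 4, 3))
  G[, 2, ] <- inv[, 1, ]
  G[, 3, ] <- inv[, 2, ]
  G[, 4, ] <- inv[, 3, ]
  G[, 1, ] <- -(G[, 2, ] + G[, 3, ] + G[, 4, ])
  list(G = G, volume = det3 / 6)
}

#' Element stiffness matrix of a 4-node tetrahedron
#'
#' Constant-strain tetrahedron: `K[(a,p),(b,q)] = V (lambda Ga_p Gb_q +
#' mu Ga_q Gb_p + mu delta_pq Ga.Gb)` with constant shape-function
#' gradients G.  DOF ordering is (node1 x,y,z, node2 x,y,z, ...).
#'
#' @param tet_coords 4 x 3 matrix of vertex coordinates (mm), positively
#'   oriented.
#' @param mat A [material()].
#' @return Symmetric positive-semidefinite 12 x 12 matrix (N/mm) with six
#'   rigid-body zero-energy modes.
#' @export
element_stiffness <- function(tet_coords, mat) {
  tet_coords <- as.matrix(tet_coords)
  stopifnot(nrow(tet_coords) == 4L, ncol(tet_coords) == 3L)
  gr <- tet_gradients(tet_coords, matrix(1:4, 1))
  if (gr$volume <= 0) stop("element_stiffness: degenerate or inverted tetrahedron")
  G <- gr$G[1, , ]
  V <- gr$volume
  lambda <- mat$lambda
  mu <- mat$mu
  K <- matrix(0, 12, 12)
  for (a in 1:4) {
    for (b in 1:4) {
      block <- V * (lambda * outer(G[a, ], G[b, ]) +
        mu * outer(G[b, ], G[a, ]) +
        mu * sum(G[a, ] * G[b, ]) * diag(3))
      K[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)] <- block
    }
  }
  K
}

# per-tet Lame constants from the per-part material list
part_lame <- function(mesh, materials) {
  lambda <- mu <- numeric(nrow(mesh$tets))
  for (p in unique(mesh$part)) {
    m <- materials[[p]]
    if (is.null(m)) stop(sprintf("no material given for part '%s'", p))
    validate_material(m)
    lambda[mesh$part == p] <- m$lambda
    mu[mesh$part == p] <- m$mu
  }
  list(lambda = lambda, mu = mu)
}

#' Assemble the global stiffness matrix
#'
#' Vectorized triplet assembly over all elements; duplicate (i, j) entries
#' are summed by the sparse constructor.
#'
#' @param mesh A [tet_mesh()].
#' @param materials Named list of [material()] per part
#'   (`list(plate = ..., mucosa = ...)`).
#' @return Sparse symmetric stiffness matrix (3N x 3N, N/mm).
#' @export
assemble_stiffness <- function(mesh, materials) {
  gr <- tet_gradients(mesh$nodes, mesh$tets)
  G <- gr$G
  V <- gr$volume
  lam <- part_lame(mesh, materials)
  M <- nrow(mesh$tets)
  n_dof <- 3L * nrow(mesh$nodes)

  dot_ab <- vector("list", 16L)
  for (a in 1:4) {
    for (b in 1:4) dot_ab[[(a - 1L) * 4L + b]] <- rowSums(G[, a, ] * G[, b, ])
  }

  nblk <- 144L
  ii <- jj <- vector("list", nblk)
  xx <- vector("list", nblk)
  blk <- 0L
  for (a in 1:4) {
    na <- mesh$tets[, a]
    for (b in 1:4) {
      nb <- mesh$tets[, b]
      dab <- dot_ab[[(a - 1L) * 4L + b]]
      for (p in 1:3) {
        for (q in 1:3) {
          blk <- blk + 1L
          val <- V * (lam$lambda * G[, a, p] * G[, b, q] +
            lam$mu * G[, a, q] * G[, b, p])
          if (p == q) val <- val + V * lam$mu * dab
          ii[[blk]] <- 3L * (na - 1L) + p
          jj[[blk]] <- 3L * (nb - 1L) + q
          xx[[blk]] <- val
        }
      }
    }
  }
  K <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n_dof, n_dof)
  )
  Matrix::forceSymmetric(K, uplo = "U")
}

#' Boundary conditions for the elastic solve
#'
#' Internally general (per-DOF prescribed values), with helpers for the
#' common cases.  The bonded palate study fixes the bone surface in all
#' three components and applies the bite load on the plate's oral surface.
#'
#' @param fixed_dofs Integer vector of global DOF indices
#'   (`3 * (node - 1) + component`).
#' @param fixed_values Prescribed displacement at each fixed DOF (mm);
#'   recycled, default 0.
#' @param load Numeric load vector of length 3N (N), or NULL for no load.
#' @return Object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(fixed_dofs, fixed_values = 0, load = NULL) {
  fixed_dofs <- as.integer(fixed_dofs)
  if (length(fixed_dofs) == 0L) stop("boundary_conditions: fixed DOF set must be non-empty")
  if (anyDuplicated(fixed_dofs)) {
    keep <- !duplicated(fixed_dofs)
    fixed_values <- rep_len(fixed_values, length(fixed_dofs))[keep]
    fixed_dofs <- fixed_dofs[keep]
  } else {
    fixed_values <- rep_len(fixed_values, length(fixed_dofs))
  }
  structure(
    list(fixed_dofs = fixed_dofs, fixed_values = fixed_values, load = load),
    class = "boundary_conditions"
  )
}

#' @rdname boundary_conditions
#' @param nodes Integer vector of node indices.
#' @param components Which components to fix (subset of 1:3 = x, y, z).
#' @return `fix_nodes()`: integer vector of global DOF indices.
#' @export
fix_nodes <- function(nodes, components = 1:3) {
  as.integer(outer(3L * (as.integer(nodes) - 1L), as.integer(components), `+`))
}

#' Distribute the bite force over a load patch
#'
#' Spreads `total_force` over the nodes of a surface node set lying within
#' `patch_radius` of the patch center, weighted by tributary area (each
#' surface triangle contributes a third of its area to each vertex), so an
#' infinite radius reproduces uniform pressure exactly.  Nodal components
#' sum to `total_force` exactly in the load direction.
#'
#' @param mesh A [tet_mesh()].
#' @param total_force Total applied force in N (default 111, the pain-onset
#'   bite force).
#' @param patch_radius Patch radius in mm; `Inf` loads the whole surface.
#' @param surface Name of the node set carrying the load (default
#'   `"plate_oral"`).
#' @param center Footprint (x, y) center of the patch; default the centroid
#'   of the surface node set (the plate center).
#' @param direction Unit load direction; default `c(0, 0, 1)`, compressing
#'   the mucosa against the fixed bone surface.
#' @return [boundary_conditions()]-compatible load vector (length 3N).
#' @export
make_load <- function(mesh, total_force = 111, patch_radius = 3,
                      surface = "plate_oral", center = NULL,
                      direction = c(0, 0, 1)) {
  surf_nodes <- mesh$node_sets[[surface]]
  if (is.null(surf_nodes)) stop(sprintf("make_load: mesh has no node set '%s'", surface))
  xy <- mesh$nodes[surf_nodes, 1:2, drop = FALSE]
  if (is.null(center)) center <- colMeans(xy)
  r <- sqrt((xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2)
  in_patch <- surf_nodes[r <= patch_radius]
  if (length(in_patch) == 0L) {
    stop("make_load: empty load patch (no surface node within patch_radius)")
  }
  if (length(in_patch) == 1L) {
    warning("make_load: single-node load patch; expect a local stress concentration")
    w <- 1
  } else {
    bf <- boundary_faces(mesh)
    on_surf <- matrix(bf %in% in_patch, nrow = nrow(bf))
    tri <- bf[rowSums(on_surf) == 3L, , drop = FALSE]
    if (nrow(tri) == 0L) {
      w <- rep(1, length(in_patch))  # isolated nodes: equal weights
    } else {
      p1 <- mesh$nodes[tri[, 1], , drop = FALSE]
      e1 <- mesh$nodes[tri[, 2], , drop = FALSE] - p1
      e2 <- mesh$nodes[tri[, 3], , drop = FALSE] - p1
      cr <- cbind(
        e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
      )
      area <- 0.5 * sqrt(rowSums(cr^2))
      acc <- numeric(nrow(mesh$nodes))
      for (k in 1:3) {
        tab <- tapply(area / 3, tri[, k], sum)
        acc[as.integer(names(tab))] <- acc[as.integer(names(tab))] + tab
      }
      w <- acc[in_patch]
      if (sum(w) <= 0) w <- rep(1, length(in_patch))
    }
  }
  w <- w / sum(w)
  load <- numeric(3L * nrow(mesh$nodes))
  for (p in 1:3) {
    if (direction[p] != 0) {
      load[3L * (in_patch - 1L) + p] <- total_force * direction[p] * w
    }
  }
  load
}

#' Solve the linear-elastic system
#'
#' Eliminates prescribed DOFs by row/column partitioning (exact constraints,
#' clean reaction recovery) and solves the remaining sparse SPD system by
#' direct Cholesky factorization.  The relative residual of the reduced
#' system is checked against 1e-8 and reactions are recovered as
#' `K u - f` on the constrained DOFs.
#'
#' @param mesh A [tet_mesh()].
#' @param materials Named list of [material()] per part.
#' @param bcs A [boundary_conditions()].
#' @return Object of class `displacement_field`: `u` (N x 3 mm),
#'   `reactions` (length-3N vector, N), `fixed_dofs`, `applied` load vector,
#'   `residual` (relative).
#' @export
solve_elasticity <- function(mesh, materials, bcs) {
  stopifnot(inherits(bcs, "boundary_conditions"))
  n_dof <- 3L * nrow(mesh$nodes)
  K <- assemble_stiffness(mesh, materials)
  f <- bcs$load %||% numeric(n_dof)
  if (length(f) != n_dof) stop("solve_elasticity: load vector length mismatch")

  fixed <- bcs$fixed_dofs
  u <- numeric(n_dof)
  u[fixed] <- bcs$fixed_values
  free <- setdiff(seq_len(n_dof), fixed)

  Kff <- K[free, free, drop = FALSE]
  rhs <- f[free] - as.numeric(K[free, fixed, drop = FALSE] %*% u[fixed])
  fac <- tryCatch(
    suppressWarnings(Matrix::Cholesky(Kff, LDL = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fac)) {
    diagnose_singular(mesh, fixed)
    stop("solve_elasticity: singular system (insufficient constraints)")
  }
  uf <- as.numeric(Matrix::solve(fac, rhs, system = "A"))
  u[free] <- uf

  rhs_norm <- sqrt(sum(rhs^2))
  res <- sqrt(sum((as.numeric(Kff %*% uf) - rhs)^2))
  residual <- if (rhs_norm > 0) res / rhs_norm else res
  if (residual > 1e-8) {
    stop(sprintf("solve_elasticity: relative residual %.3e exceeds 1e-8", residual))
  }

  reactions <- numeric(n_dof)
  reactions[fixed] <- as.numeric(K[fixed, , drop = FALSE] %*% u) - f[fixed]

  structure(
    list(
      u = matrix(u, ncol = 3L, byrow = TRUE),
      reactions = reactions,
      fixed_dofs = fixed,
      applied = f,
      residual = residual
    ),
    class = "displacement_field"
  )
}

# name the floating components when the reduced system is singular
diagnose_singular <- function(mesh, fixed_dofs) {
  fixed_nodes <- unique((fixed_dofs - 1L) %/% 3L + 1L)
  comp <- node_components(mesh)
  floating <- setdiff(unique(comp), unique(comp[fixed_nodes]))
  if (length(floating)) {
    parts <- vapply(floating, function(cid) {
      nodes_in <- which(comp == cid)
      in_comp <- rowSums(matrix(mesh$tets %in% nodes_in, nrow = nrow(mesh$tets))) > 0
      paste(sort(unique(mesh$part[in_comp])), collapse = "+")
    }, character(1))
    stop(sprintf(
      "solve_elasticity: unconstrained rigid-body modes: %d mesh component(s) without fixed nodes (parts: %s)",
      length(floating), paste(parts, collapse = ", ")
    ))
  }
  invisible(NULL)
}

# connected components of the node graph induced by shared tets
# (vectorized label propagation; converges in O(mesh diameter) sweeps)
node_components <- function(mesh) {
  n <- nrow(mesh$nodes)
  lab <- seq_len(n)
  tt <- mesh$tets
  ea <- c(tt[, 1], tt[, 1], tt[, 1], tt[, 2], tt[, 2], tt[, 3])
  eb <- c(tt[, 2], tt[, 3], tt[, 4], tt[, 3], tt[, 4], tt[, 4])
  repeat {
    m <- pmin(lab[ea], lab[eb])
    new <- lab
    upd <- tapply(m, ea, min)
    idx <- as.integer(names(upd))
    new[idx] <- pmin(new[idx], upd)
    upd <- tapply(m, eb, min)
    idx <- as.integer(names(upd))
    new[idx] <- pmin(new[idx], upd)
    # path compression: relabel through the representative
    new <- new[new]
    if (identical(new, lab)) break
    lab <- new
  }
  match(lab, sort(unique(lab)))
}

#' Recover element stresses and von Mises values
#'
#' Piecewise-constant (per-tet) small-strain stress from the displacement
#' field: `sigma = lambda tr(eps) I + 2 mu eps`, with the von Mises scalar
#' `sqrt(3/2 s:s)` of the deviatoric part `s`.
#'
#' @param mesh A [tet_mesh()].
#' @param materials Named list of [material()] per part.
#' @param disp A `displacement_field` from [solve_elasticity()], or an
#'   N x 3 displacement matrix.
#' @return Object of class `stress_field`: `sigma` (M x 6 Voigt
#'   xx, yy, zz, xy, yz, zx, MPa), `von_mises` (length M, MPa), `part`.
#' @export
recover_stress <- function(mesh, materials, disp) {
  u <- if (inherits(disp, "displacement_field")) disp$u else as.matrix(disp)
  stopifnot(nrow(u) == nrow(mesh$nodes), ncol(u) == 3L)
  gr <- tet_gradients(mesh$nodes, mesh$tets)
  G <- gr$G
  lam <- part_lame(mesh, materials)
  M <- nrow(mesh$tets)
  eps <- matrix(0, M, 6L)  # xx yy zz xy yz zx (tensor components)
  voigt <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(2, 3), c(3, 1))
  U <- array(0, c(M, 4, 3))
  for (a in 1:4) U[, a, ] <- u[mesh$tets[, a], , drop = FALSE]
  for (v in 1:6) {
    p <- voigt[v, 1]
    q <- voigt[v, 2]
    acc <- numeric(M)
    for (a in 1:4) {
      acc <- acc + 0.5 * (G[, a, p] * U[, a, q] + G[, a, q] * U[, a, p])
    }
    eps[, v] <- acc
  }
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  sigma <- 2 * lam$mu * eps
  sigma[, 1:3] <- sigma[, 1:3] + lam$lambda * tr
  colnames(sigma) <- c("xx", "yy", "zz", "xy", "yz", "zx")
  structure(
    list(sigma = sigma, von_mises = von_mises(sigma), part = mesh$part),
    class = "stress_field"
  )
}

#' Von Mises equivalent stress
#'
#' @param sigma M x 6 matrix of Voigt stress components
#'   (xx, yy, zz, xy, yz, zx).
#' @return Non-negative numeric vector (MPa); zero for hydrostatic states.
#' @export
von_mises <- function(sigma) {
  sigma <- rbind(sigma)
  sqrt(pmax(0,
    0.5 * ((sigma[, 1] - sigma[, 2])^2 +
      (sigma[, 2] - sigma[, 3])^2 +
      (sigma[, 3] - sigma[, 1])^2) +
      3 * (sigma[, 4]^2 + sigma[, 5]^2 + sigma[, 6]^2)
  ))
}
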
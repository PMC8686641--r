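# independent element-stiffness oracle: classical strain-displacement /
# constitutive product K = V B^T D B, with shape-function gradients from a
# direct 4x4 solve (not the adjugate route used by the implementation)
oracle_element_stiffness <- function(coords, E, nu) {
  A <- rbind(1, t(coords))          # N(x) = solve(A) %*% c(1, x)
  G <- solve(A)[, 2:4, drop = FALSE]
  V <- abs(det(A)) / 6
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- G[a, 1]
    B[2, c0 + 2] <- G[a, 2]
    B[3, c0 + 3] <- G[a, 3]
    B[4, c0 + 1] <- G[a, 2]; B[4, c0 + 2] <- G[a, 1]
    B[5, c0 + 2] <- G[a, 3]; B[5, c0 + 3] <- G[a, 2]
    B[6, c0 + 1] <- G[a, 3]; B[6, c0 + 3] <- G[a, 1]
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  V * t(B) %*% D %*% B
}

test_that("element stiffness matches the independent B^T D B oracle", {
  ref <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  K <- element_stiffness(ref, material(1, 0.25))
  expect_equal(K, oracle_element_stiffness(ref, 1, 0.25), tolerance = 1e-12)

  set.seed(19)
  for (i in 1:5) {
    co <- ref + matrix(runif(12, -0.2, 0.2), 4, 3)
    if (det(rbind(co[2, ] - co[1, ], co[3, ] - co[1, ], co[4, ] - co[1, ])) < 0) {
      co <- co[c(1, 3, 2, 4), ]
    }
    E <- runif(1, 1, 3000)
    nu <- runif(1, 0.1, 0.45)
    expect_equal(element_stiffness(co, material(E, nu)),
      oracle_element_stiffness(co, E, nu),
      tolerance = 1e-10
    )
  }
})

test_that("element stiffness is symmetric PSD with six rigid-body modes", {
  set.seed(4)
  co <- matrix(c(0, 0, 0, 2, 0, 0, 0, 3, 0, 0.5, 0.5, 1.5), 4, 3, byrow = TRUE)
  K <- element_stiffness(co, material(2650, 0.3))
  expect_identical(K, t(K))
  # translations and infinitesimal rotations are zero-energy
  rots <- list(
    function(p) c(1, 0, 0), function(p) c(0, 1, 0), function(p) c(0, 0, 1),
    function(p) c(0, -p[3], p[2]), function(p) c(p[3], 0, -p[1]),
    function(p) c(-p[2], p[1], 0)
  )
  for (r in rots) {
    u <- as.vector(apply(co, 1, r))
    expect_lt(max(abs(K %*% u)) / max(abs(K)), 1e-10)
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(ev < max(ev) * 1e-10), 6L)
  # degenerate (flat) tets are rejected
  flat <- co
  flat[4, ] <- (flat[1, ] + flat[2, ] + flat[3, ]) / 3
  expect_error(element_stiffness(flat, material(1, 0.3)), "degenerate")
})

test_that("uniaxial compression of a resin block matches the closed form", {
  E <- 2650
  nu <- 0.3
  p <- 1
  m <- mesh_box(10, 10, 10, 2.5)
  mats <- list(mucosa = material(E, nu))
  fixed <- c(
    fix_nodes(m$node_sets$zmin, 3),
    fix_nodes(m$node_sets$xmin, 1),
    fix_nodes(m$node_sets$ymin, 2)
  )
  load <- make_load(m,
    total_force = -p * 100, patch_radius = Inf,
    surface = "zmax", direction = c(0, 0, 1)
  )
  sol <- solve_elasticity(m, mats, boundary_conditions(fixed, 0, load))
  st <- recover_stress(m, mats, sol)
  expect_equal(st$sigma[, "zz"], rep(-p, nrow(m$tets)), tolerance = 1e-8)
  expect_equal(st$von_mises, rep(p, nrow(m$tets)), tolerance = 1e-8)
  expect_equal(
    sol$u[m$node_sets$zmax, 3],
    rep(-p * 10 / E, length(m$node_sets$zmax)),
    tolerance = 1e-8
  )
})

test_that("patch test: prescribed linear fields are reproduced in the interior", {
  a <- c(0.1, -0.2, 0.05)
  B <- matrix(c(
    1e-3, 2e-4, -1e-4,
    5e-4, -8e-4, 3e-4,
    -2e-4, 1e-4, 6e-4
  ), 3, 3, byrow = TRUE)
  meshes <- list(
    mesh_box(4, 3, 2, 1),
    mesh_layered(flat_geometry(mesh_edge = 4))  # distorted bilayer grid
  )
  for (mesh in meshes) {
    mat <- material(100, 0.3)
    mats <- list(mucosa = mat, plate = mat)
    exact <- linear_field(mesh$nodes, a, B)
    bn <- boundary_nodes(mesh)
    fixed <- fix_nodes(bn)
    vals <- as.vector(exact[bn, ])
    sol <- solve_elasticity(mesh, mats, boundary_conditions(fixed, vals))
    err <- max(abs(sol$u - exact)) / max(abs(exact))
    expect_lt(err, 1e-10)
  }
})

test_that("zero load gives zero displacement", {
  m <- mesh_box(2, 2, 2, 1)
  sol <- solve_elasticity(
    m, list(mucosa = material(10, 0.3)),
    boundary_conditions(fix_nodes(m$node_sets$zmin))
  )
  expect_identical(sol$u, matrix(0, nrow(m$nodes), 3))
})

test_that("bite load distributes over the patch and sums exactly", {
  cfg <- palate_config(mesh_edge = 3)
  mesh <- mesh_layered(build_geometry(cfg, sample_thickness_map(cfg)))
  load <- make_load(mesh, total_force = 111, patch_radius = 3)
  lz <- load[seq(3, length(load), 3)]
  expect_lt(abs(sum(lz) - 111), 1e-10)
  expect_identical(sum(load[seq(1, length(load), 3)]), 0)
  # support inside the patch only
  loaded <- which(lz != 0)
  r <- sqrt(mesh$nodes[loaded, 1]^2 + (mesh$nodes[loaded, 2] - cfg$arch_length / 2)^2)
  expect_true(all(r <= 3 + 1e-9))
  expect_true(all(loaded %in% mesh$node_sets$plate_oral))

  on_node <- mesh$nodes[mesh$node_sets$plate_oral[5], 1:2]
  expect_warning(
    make_load(mesh, 50, patch_radius = 1e-6, center = on_node),
    "single-node"
  )
  m2 <- mesh_box(1, 1, 1, 1)
  expect_error(
    make_load(m2, 1, patch_radius = -1, surface = "zmax"),
    "empty load patch"
  )
})

test_that("global equilibrium holds for arbitrary loads", {
  cfg <- palate_config(mesh_edge = 3, seed = 2L)
  mesh <- mesh_layered(build_geometry(cfg, sample_thickness_map(cfg)))
  mats <- list(plate = material(2650, 0.3), mucosa = material(8, 0.37))
  set.seed(8)
  load <- numeric(3 * nrow(mesh$nodes))
  pick <- sample(mesh$node_sets$plate_oral, 20)
  load[fix_nodes(pick, 1:3)] <- runif(60, -2, 2)
  sol <- solve_elasticity(
    mesh, mats,
    boundary_conditions(fix_nodes(mesh$node_sets$bone_surface), 0, load)
  )
  for (p in 1:3) {
    dofs <- seq(p, length(load), 3)
    imbalance <- abs(sum(sol$reactions[dofs]) + sum(load[dofs]))
    expect_lt(imbalance / sum(abs(load)), 1e-6)
  }
})

test_that("strain energy is positive for non-rigid deformation", {
  m <- mesh_box(2, 1, 1, 1)
  K <- assemble_stiffness(m, list(mucosa = material(5, 0.4)))
  set.seed(3)
  for (i in 1:5) {
    u <- rnorm(3 * nrow(m$nodes))
    u <- u - mean(u)  # not a pure translation either way
    expect_gt(as.numeric(t(u) %*% K %*% u), 0)
  }
})

test_that("von Mises invariants: uniaxial, hydrostatic and shear states", {
  expect_equal(von_mises(cbind(-3, 0, 0, 0, 0, 0)), 3, ignore_attr = TRUE)
  expect_equal(von_mises(cbind(5, 5, 5, 0, 0, 0)), 0, ignore_attr = TRUE)
  expect_equal(von_mises(cbind(0, 0, 0, 2, 0, 0)), 2 * sqrt(3), ignore_attr = TRUE)
  expect_equal(von_mises(cbind(0, 0, 0, 0, 1.5, 0)), 1.5 * sqrt(3), ignore_attr = TRUE)
})

test_that("insufficient constraints are diagnosed with the floating part", {
  m <- mesh_box(2, 2, 2, 1)
  load <- numeric(3 * nrow(m$nodes))
  load[3] <- 1
  # constrain a single node: rotations about it remain unconstrained
  err <- tryCatch(
    solve_elasticity(
      m, list(mucosa = material(1, 0.3)),
      boundary_conditions(fix_nodes(m$node_sets$zmin[1]), 0, load)
    ),
    error = function(e) conditionMessage(e)
  )
  expect_match(err, "singular|unconstrained")
})

test_that("probe-point stress converges under uniform refinement", {
  # bilayer slab under a central patch load; element stress at a fixed
  # interior probe must change by a decreasing amount as the mesh refines
  probe <- c(0, 10, -1)  # mid-mucosa under the load
  vm_at_probe <- function(edge) {
    geom <- flat_geometry(thickness = 2, mesh_edge = edge)
    mesh <- mesh_layered(geom, edge)
    mats <- list(plate = material(2650, 0.3), mucosa = material(8, 0.37))
    load <- make_load(mesh, 50, patch_radius = 4)
    sol <- solve_elasticity(
      mesh, mats,
      boundary_conditions(fix_nodes(mesh$node_sets$bone_surface), 0, load)
    )
    st <- recover_stress(mesh, mats, sol)
    cent <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
      mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
    d2 <- colSums((t(cent) - probe)^2)
    st$von_mises[which.min(d2)]
  }
  v <- vapply(c(2, 1, 0.5), vm_at_probe, numeric(1))
  expect_lt(abs(v[3] - v[2]), abs(v[2] - v[1]))
})
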
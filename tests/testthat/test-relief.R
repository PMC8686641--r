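test_that("region selection brackets: zero selects all, above-max selects none", {
  geom <- flat_geometry(mesh_edge = 4)
  mesh <- mesh_layered(geom)
  set.seed(21)
  vm <- runif(nrow(mesh$tets), 0, 0.2)
  st <- fake_stress(vm, mesh$part)
  expect_identical(
    select_relief_region(st, mesh, 0)$facet_ids,
    seq_len(nrow(mesh$facets))
  )
  empty <- select_relief_region(st, mesh, max(vm) + 0.01)
  expect_length(empty$facet_ids, 0L)
  expect_identical(empty$area, 0)
})

test_that("relief masks are nested across borderlines and match the facet oracle", {
  geom <- flat_geometry(arch_length = 12, arch_half_width = 6, mesh_edge = 3)
  mesh <- mesh_layered(geom)
  for (seed in 1:3) {
    set.seed(seed)
    st <- fake_stress(runif(nrow(mesh$tets), 0, 0.2), mesh$part)
    oracle <- oracle_facet_max(st, mesh)
    prev <- NULL
    for (b in c(0.04, 0.06, 0.08, 0.10, 0.14)) {
      mask <- select_relief_region(st, mesh, b)
      expect_identical(mask$facet_ids, which(oracle >= b))
      if (!is.null(prev)) expect_true(all(mask$facet_ids %in% prev))
      prev <- mask$facet_ids
    }
  }
})

test_that("empty relief is the identity: bit-identical re-solve", {
  cfg <- small_study_config()
  mesh <- mesh_layered(build_geometry(cfg$palate, sample_thickness_map(cfg$palate)))
  mats <- cfg$materials
  bcs <- boundary_conditions(
    fix_nodes(mesh$node_sets$bone_surface), 0,
    make_load(mesh, cfg$bite_force, cfg$patch_radius)
  )
  sol0 <- solve_elasticity(mesh, mats, bcs)
  st0 <- recover_stress(mesh, mats, sol0)
  region <- select_relief_region(st0, mesh, max(st0$von_mises) + 1)
  relieved <- apply_relief(mesh, region, 0.25)
  expect_identical(relieved, mesh)
  sol1 <- solve_elasticity(relieved, mats, bcs)
  expect_identical(sol1$u, sol0$u)
})

test_that("decoupling removes all stiffness coupling across the relieved region", {
  cfg <- small_study_config()
  mesh <- mesh_layered(build_geometry(cfg$palate, sample_thickness_map(cfg$palate)))
  mats <- cfg$materials
  bcs <- boundary_conditions(
    fix_nodes(mesh$node_sets$bone_surface), 0,
    make_load(mesh, cfg$bite_force, cfg$patch_radius)
  )
  st0 <- recover_stress(mesh, mats, solve_elasticity(mesh, mats, bcs))
  region <- select_relief_region(st0, mesh, 0.06)
  expect_gt(length(region$facet_ids), 0L)
  relieved <- apply_relief(mesh, region, 0.25)

  pairs <- relieved$relief$pairs
  expect_identical(relieved$nodes[pairs$dup, ], relieved$nodes[pairs$orig, ])
  # no tet mixes a mucosa-side original with the plate part or vice versa
  pl <- relieved$part == "plate"
  expect_false(any(relieved$tets[pl, ] %in% pairs$orig))
  expect_false(any(relieved$tets[!pl, ] %in% pairs$dup))
  # therefore interface tractions across the region are exactly zero:
  # the stiffness block coupling the two sides vanishes identically
  K <- assemble_stiffness(relieved, mats)
  blk <- K[fix_nodes(pairs$orig), fix_nodes(pairs$dup), drop = FALSE]
  expect_identical(Matrix::nnzero(blk), 0L)
  # relieved facets are flagged unbonded
  expect_true(all(!relieved$facets$bonded[region$facet_ids]))
})

test_that("relieving the full interface leaves the plate unconstrained", {
  cfg <- small_study_config()
  mesh <- mesh_layered(build_geometry(cfg$palate, sample_thickness_map(cfg$palate)))
  all_facets <- region_mask_all <- select_relief_region(
    fake_stress(rep(1, nrow(mesh$tets)), mesh$part), mesh, 0
  )
  relieved <- apply_relief(mesh, all_facets, 0.25)
  bcs <- boundary_conditions(
    fix_nodes(relieved$node_sets$bone_surface), 0,
    make_load(relieved, cfg$bite_force, cfg$patch_radius)
  )
  expect_error(
    solve_elasticity(relieved, cfg$materials, bcs),
    "unconstrained|singular"
  )
})

test_that("mid-palatal strip region has the right area and symmetry", {
  cfg <- flat_config(arch_length = 45, arch_half_width = 22, mesh_edge = 2)
  mesh <- mesh_layered(build_geometry(cfg, rep(2, 14)))
  region <- build_mid_palatal_region(mesh, 10)
  strip_area <- 10 * cfg$arch_length
  row_area <- 2 * cfg$mesh_edge * cfg$arch_length  # one facet row each side
  expect_lt(abs(region$area - strip_area), row_area)
  # mirror symmetry of the mask (consistent-diagonal triangulations pair
  # triangles under in-cell rotation, so symmetry holds for the region,
  # not triangle-by-triangle)
  cx <- mesh$facets$cx[region$facet_ids]
  area <- mesh$facets$area[region$facet_ids]
  expect_identical(sum(cx < 0), sum(cx > 0))
  expect_equal(sum(area[cx < 0]), sum(area[cx > 0]))
  expect_equal(sort(round(abs(cx[cx < 0]), 9)), sort(round(cx[cx > 0], 9)))

  expect_error(build_mid_palatal_region(mesh, 100), "exceeds the footprint")
  expect_warning(thin <- build_mid_palatal_region(mesh, 1e-4), "smaller than one facet")
  expect_gt(length(thin$facet_ids), 0L)
})

test_that("gap-closure check flags plate approach beyond the relief depth", {
  geom <- flat_geometry(mesh_edge = 4)
  mesh <- mesh_layered(geom)
  region <- build_mid_palatal_region(mesh, 8)
  relieved <- apply_relief(mesh, region, 0.25)
  u <- matrix(0, nrow(relieved$nodes), 3)
  ok <- check_gap_closure(relieved, u)
  expect_false(attr(ok, "any_closed"))
  # push the plate-side duplicates up beyond the gap
  u[relieved$relief$pairs$dup, 3] <- 0.3
  bad <- check_gap_closure(relieved, u)
  expect_true(attr(bad, "any_closed"))
  expect_identical(sum(bad$closed), nrow(relieved$relief$pairs))
})

test_that("the study driver runs the configured scenario sequence", {
  cfg <- small_study_config()
  rep <- run_study(cfg)
  expect_s3_class(rep, "study_report")
  expect_identical(
    names(rep$scenarios),
    c(
      "no_relief", "borderline_0.04", "borderline_0.06", "borderline_0.08",
      "borderline_0.10", "borderline_0.14", "mid_palatal"
    )
  )
  expect_identical(nrow(rep$ratios), 7L)
  # no-relief row is exactly 100 wherever the baseline volume is nonzero
  base_cum <- rep$scenarios$no_relief$distribution$cumulative
  row0 <- as.numeric(rep$ratios[rep$ratios$scenario == "no_relief", -1])
  expect_identical(row0[base_cum > 0], rep(100, sum(base_cum > 0)))
  expect_true(all(is.na(row0[base_cum == 0])))

  # relieved footprint area non-increasing in the borderline
  areas <- vapply(rep$scenarios, `[[`, numeric(1), "region_area")
  expect_true(all(diff(areas[2:6]) <= 0))

  cfg2 <- small_study_config(borderlines = numeric(0))
  expect_identical(names(run_study(cfg2)$scenarios), c("no_relief", "mid_palatal"))
})

test_that("a fixed seed reproduces the study bit-for-bit", {
  cfg <- small_study_config(seed = 9L)
  r1 <- run_study(cfg)
  r2 <- run_study(cfg)
  expect_identical(r1$ratios, r2$ratios)
  expect_identical(
    r1$scenarios$mid_palatal$solution$u,
    r2$scenarios$mid_palatal$solution$u
  )
})
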
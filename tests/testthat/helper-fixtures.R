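# Shared fixtures, built in code at test time.

# flat bilayer slab: analytic limit of the geometry family
flat_config <- function(arch_length = 20, arch_half_width = 10,
                        thickness = 2, plate_thickness = 1.5,
                        mesh_edge = 2, seed = 1L) {
  palate_config(
    arch_length = arch_length,
    arch_half_width = arch_half_width,
    dome_height = 0,
    plate_thickness = plate_thickness,
    thickness_bounds = matrix(rep(thickness, 28), ncol = 2),
    raphe_thinning = 0,
    mesh_edge = mesh_edge,
    seed = seed
  )
}

flat_geometry <- function(...) {
  cfg <- flat_config(...)
  build_geometry(cfg, rep(cfg$thickness_bounds[1, 1], 14))
}

# small full-featured study configuration for fast unit tests of the driver
small_study_config <- function(seed = 1L, ...) {
  study_config(
    palate = palate_config(mesh_edge = 3, seed = seed),
    seed = seed,
    ...
  )
}

# default-conditions study at the coarsened analysis resolution, computed
# once and shared across acceptance checks
acceptance_study <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      cfg <- study_config(palate = palate_config(mesh_edge = 1.5), seed = seed)
      cache[[key]] <- run_study(cfg)
    }
    cache[[key]]
  }
})

# synthetic per-element stress field (for metric/region tests)
fake_stress <- function(von_mises, part) {
  structure(
    list(
      sigma = matrix(0, length(von_mises), 6),
      von_mises = von_mises,
      part = part
    ),
    class = "stress_field"
  )
}

# independent facet-selection oracle: per-facet max over mucosa tets
# touching any facet node, by explicit loops
oracle_facet_max <- function(stress, mesh) {
  vapply(seq_len(nrow(mesh$facets)), function(fid) {
    fnodes <- as.integer(mesh$facets[fid, c("n1", "n2", "n3")])
    best <- -Inf
    for (ti in seq_len(nrow(mesh$tets))) {
      if (mesh$part[ti] == "mucosa" && any(mesh$tets[ti, ] %in% fnodes)) {
        best <- max(best, stress$von_mises[ti])
      }
    }
    best
  }, numeric(1))
}

# independent per-element accumulation oracle for volume distributions
oracle_distribution <- function(stress, mesh, thresholds) {
  vols <- tet_volumes(mesh)
  cum <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    acc <- 0
    for (ti in seq_len(nrow(mesh$tets))) {
      if (mesh$part[ti] == "mucosa" && stress$von_mises[ti] >= thresholds[i]) {
        acc <- acc + vols[ti]
      }
    }
    cum[i] <- acc
  }
  cum
}

# linear displacement field u = a + B x, evaluated at mesh nodes
linear_field <- function(nodes, a, B) {
  sweep(nodes %*% t(B), 2, -a)
}
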
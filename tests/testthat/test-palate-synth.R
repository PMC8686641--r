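test_that("thickness sampling honours the segment layout, bounds and seed", {
  cfg <- palate_config(seed = 7L)
  tm <- sample_thickness_map(cfg)
  expect_length(tm, 14L)
  expect_true(all(tm >= cfg$thickness_bounds[, 1] & tm <= cfg$thickness_bounds[, 2]))

  # degenerate bounds pin every thickness
  cfg2 <- palate_config(thickness_bounds = matrix(rep(2, 28), ncol = 2))
  expect_equal(unclass(sample_thickness_map(cfg2)), rep(2, 14), ignore_attr = TRUE)

  # determinism: same config + seed gives identical maps, new seed differs
  expect_identical(sample_thickness_map(cfg, 7L), sample_thickness_map(cfg, 7L))
  expect_false(identical(sample_thickness_map(cfg, 7L), sample_thickness_map(cfg, 8L)))

  # sampling must not disturb the session RNG stream
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(sample_thickness_map(cfg, 99L))
  expect_identical(runif(1), before)
})

test_that("config validation rejects malformed layouts and bounds", {
  expect_error(palate_config(n_rows = 5), "14 segments")
  bad <- default_thickness_bounds()
  bad[3, ] <- c(4, 2)
  expect_error(palate_config(thickness_bounds = bad), "min > max")
  expect_error(palate_config(mesh_edge = 0), "mesh_edge")
  expect_error(palate_config(raphe_thinning = 1), "raphe_thinning")
})

test_that("flat-slab geometry is two parallel layers of exact thickness", {
  geom <- flat_geometry(thickness = 2, plate_thickness = 1.5)
  x <- runif(50, -10, 10)
  y <- runif(50, 0, 20)
  expect_equal(geom$z_bone(x, y), rep(0, 50))
  expect_equal(geom$z_bone(x, y) - geom$z_interface(x, y), rep(2, 50))
  expect_equal(geom$z_interface(x, y) - geom$z_oral(x, y), rep(1.5, 50))
})

test_that("segment-center thickness is recovered from the blended field", {
  cfg <- palate_config(seed = 3L)
  tm <- sample_thickness_map(cfg)
  geom <- build_geometry(cfg, tm)
  lay <- segment_layout(cfg)
  got <- geom$thickness(lay$x_center, lay$y_center)
  expect_equal(got, unclass(tm), tolerance = 0.01, ignore_attr = TRUE)

  # without the raphe groove, recovery is exact
  cfg0 <- palate_config(seed = 3L, raphe_thinning = 0)
  geom0 <- build_geometry(cfg0, tm)
  expect_equal(geom0$thickness(lay$x_center, lay$y_center), unclass(tm),
    ignore_attr = TRUE
  )
})

test_that("mirror-symmetric thickness maps give mirror-symmetric geometry", {
  cfg <- palate_config(seed = 5L)
  tm <- sample_thickness_map(cfg)
  sym <- tm
  sym[seq(2, 14, 2)] <- sym[seq(1, 13, 2)]  # right copies left
  geom <- build_geometry(cfg, sym)
  x <- runif(100, 0, cfg$arch_half_width)
  y <- runif(100, 0, cfg$arch_length)
  for (f in c("z_bone", "z_interface", "z_oral", "thickness")) {
    expect_lt(max(abs(geom[[f]](x, y) - geom[[f]](-x, y))), 1e-9)
  }
})

test_that("geometry generation is deterministic in (config, seed)", {
  cfg <- palate_config(seed = 11L)
  g1 <- build_geometry(cfg, sample_thickness_map(cfg))
  g2 <- build_geometry(cfg, sample_thickness_map(cfg))
  x <- seq(-20, 20, length.out = 31)
  y <- seq(1, 44, length.out = 31)
  expect_identical(g1$thickness(x, y), g2$thickness(x, y))
  expect_identical(g1$z_oral(x, y), g2$z_oral(x, y))
})

test_that("segment lookup maps footprint points to the 7x2 grid", {
  cfg <- palate_config()
  geom <- build_geometry(cfg, sample_thickness_map(cfg))
  lay <- segment_layout(cfg)
  expect_identical(
    geom$segment_at(lay$x_center, lay$y_center),
    lay$segment
  )
  # left/right split at the midline
  expect_identical(geom$segment_at(-0.1, 1), 1L)
  expect_identical(geom$segment_at(0.1, 1), 2L)
})

test_that("out-of-bounds or non-positive thickness maps are rejected", {
  cfg <- palate_config()
  tm <- sample_thickness_map(cfg)
  tm[5] <- -1
  expect_error(build_geometry(cfg, tm), "positive")
  tm2 <- sample_thickness_map(cfg)
  tm2[1] <- cfg$thickness_bounds[1, 2] + 1
  expect_error(build_geometry(cfg, tm2), "bounds")
})

test_that("study configs round-trip through YAML", {
  cfg <- study_config(
    palate = palate_config(mesh_edge = 2, seed = 4L),
    borderlines = c(0.05, 0.09),
    bite_force = 100
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, path)
  back <- read_study_config(path)
  expect_equal(back$borderlines, cfg$borderlines)
  expect_equal(back$bite_force, cfg$bite_force)
  expect_equal(back$palate$thickness_bounds, cfg$palate$thickness_bounds,
    ignore_attr = TRUE
  )
  expect_equal(back$materials$mucosa$young_modulus, cfg$materials$mucosa$young_modulus)
})
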
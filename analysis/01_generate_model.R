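#!/usr/bin/env Rscript

# Step 1 — build the synthetic palate model.
#
# Samples the 14-segment mucosal thickness map, assembles the layered
# geometry (resin plate bonded to a rigid-backed mucosa layer with a thin
# midline raphe band), and meshes it with the structured conforming
# tetrahedral mesher.  Writes the labelled mesh and the sampled thickness
# map under results/model/.

library(palaterelief)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
mesh_edge <- if (length(args) > 1) as.numeric(args[2]) else 1.5

outdir <- "results/model"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- palate_config(mesh_edge = mesh_edge, seed = seed)
thickness <- sample_thickness_map(cfg)
geometry <- build_geometry(cfg, thickness)
mesh <- mesh_layered(geometry)

print(geometry)
print(mesh)
message(sprintf(
  "mucosa volume %.0f mm^3, plate volume %.0f mm^3, interface %.0f mm^2",
  sum(tet_volumes(mesh)[mesh$part == "mucosa"]),
  sum(tet_volumes(mesh)[mesh$part == "plate"]),
  sum(mesh$facets$area)
))

write_mesh(mesh, file.path(outdir, "palate_mesh.vtu"))
utils::write.csv(
  data.frame(segment_layout(cfg), thickness_mm = as.numeric(thickness)),
  file.path(outdir, "thickness_map.csv"),
  row.names = FALSE
)
write_study_config(
  study_config(palate = cfg, seed = seed),
  file.path(outdir, "study_config.yaml")
)
message("model written to ", outdir)
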
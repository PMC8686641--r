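#!/usr/bin/env Rscript

# Step 2 — stress in the no-relief (fully bonded) model.
#
# Applies the 111 N bite load vertically onto the plate center, solves the
# bonded bilayer, and summarizes the mucosal von Mises field that all
# relief decisions derive from.  The analyzed stress interval 0.02-0.20 MPa
# brackets the generated field.  Writes the baseline field map and its
# stress-volume distribution under results/baseline/.

library(palaterelief)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

outdir <- "results/baseline"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- study_config(palate = palate_config(mesh_edge = 1.5), seed = seed)
thickness <- sample_thickness_map(cfg$palate)
mesh <- mesh_layered(build_geometry(cfg$palate, thickness))

load <- make_load(mesh, cfg$bite_force, cfg$patch_radius)
sol <- solve_elasticity(
  mesh, cfg$materials,
  boundary_conditions(fix_nodes(mesh$node_sets$bone_surface), 0, load)
)
stress <- recover_stress(mesh, cfg$materials, sol)
vm <- stress$von_mises[mesh$part == "mucosa"]
message(sprintf(
  "mucosal von Mises: median %.4f MPa, 95th pct %.4f MPa, peak %.4f MPa",
  stats::median(vm), stats::quantile(vm, 0.95), max(vm)
))

d <- stress_volume_distribution(stress, mesh, cfg$thresholds)
utils::write.csv(
  data.frame(
    threshold_mpa = d$thresholds, volume_mm3 = d$cumulative,
    total_mucosa_mm3 = d$total
  ),
  file.path(outdir, "baseline_distribution.csv"),
  row.names = FALSE
)
write_mesh(mesh, file.path(outdir, "baseline_field.vtu"),
  cell_data = list(von_mises = stress$von_mises)
)
message("baseline written to ", outdir)
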
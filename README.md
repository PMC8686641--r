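# palaterelief

Simulation pipeline for designing **relief** in palatal plates: where, and
how much, should a denture plate be hollowed out so that the
denture-supporting mucosa underneath carries load without pain?

Conventional practice places a standard relief strip along the palate
midline, chosen by the dentist's judgement.  An alternative is
*selective* relief: solve the stress field of the fully bonded
("no-relief") plate first, then relieve exactly the regions where mucosal
von Mises stress exceeds a chosen cutoff — the **borderline**.  This
package implements that workflow end-to-end as reproducible R code and
quantifies each strategy by how it changes the volume of highly stressed
mucosa relative to the no-relief baseline.

The pipeline:

1. **Synthetic palate model** — a parametric stand-in for a CT-derived
   subject: a stiff resin plate (E = 2650 MPa, ν = 0.3) bonded to a
   rigid-backed mucosa layer whose thickness varies over 14 segments
   (7 anterior–posterior rows × left/right), with a thin midline raphe
   band.  All dimensions, bounds and the sampling seed are configurable.
2. **Meshing** — structured, conforming tetrahedral mesh of the bilayer
   (hexahedral cells split into 6 tets with a consistent diagonal rule),
   so the bonded plate–mucosa interface is realized by shared nodes.
   ASCII VTU input/output.
3. **Elasticity** — small-strain isotropic linear-elastic solve on 4-node
   (constant-strain) tetrahedra; sparse Cholesky after exact constraint
   elimination; bite force 111 N distributed over a patch at the plate
   center; bone surface fully constrained.  Per-element stress recovery
   and von Mises equivalent stress √(3/2 · s : s).
4. **Relief** — borderline-thresholded regions selected from the
   *no-relief* field (single pass), or the conventional 10 mm mid-palatal
   strip; relief of depth 0.25 mm realized by decoupling the bonded
   interface (node duplication; an open 0.25 mm gap transmits no force in
   a linear model, and a post-solve check verifies the gap stays open).
5. **Metrics** — for thresholds *t* = 0.02…0.20 MPa, the mucosa volume
   with von Mises stress ≥ *t*, and the ratio
   100 · V_relief(≥ t) / V_no-relief(≥ t).

## Worked example

```r
library(palaterelief)
cfg <- study_config(palate = palate_config(mesh_edge = 1.5), seed = 1)
report <- run_study(cfg)
print(report)
```

```
Relief study: 7 scenarios on 21600 tets (4805 nodes), bite force 111 N
Distribution-volume ratios (no-relief = 100%):
        scenario pct_at_0.02 pct_at_0.04 pct_at_0.06 pct_at_0.08 pct_at_0.10
       no_relief       100.0       100.0       100.0       100.0       100.0
 borderline_0.04       181.8       513.6       792.5       811.8       660.3
 borderline_0.06       189.6       461.3       521.6       438.8       323.3
 borderline_0.08       190.7       386.6       417.2       327.0       219.1
 borderline_0.10       188.1       347.0       359.1       274.8       182.7
 borderline_0.14       177.6       286.6       274.8       197.5       151.7
     mid_palatal       191.8       537.6       792.6       786.9       690.9
 pct_at_0.12 pct_at_0.14 pct_at_0.16 pct_at_0.18 pct_at_0.20
      100.00      100.00      100.00      100.00     100.000
      491.46      347.94      265.82      196.19     162.390
      189.17      101.11       59.22       22.94      11.342
      116.15       69.74       34.57       13.76       8.281
      101.38       56.51       33.90       15.45       8.486
       99.92       58.61       37.84       18.78       7.997
      541.41      372.38      310.26      251.34     182.116
```

Reading the last column (volume stressed at ≥ 0.20 MPa, the upper end of
the analyzed interval): *excessive* selective relief (borderline
0.04 MPa) and the *conventional* mid-palatal strip both concentrate load
at their margins and **grow** the highly stressed volume (162% and 182%
of baseline), while *conservative* selective relief (borderline
0.14 MPa) removes only the small high-stress zone and shrinks it to 8%.
Intermediate thresholds show the largest redistribution.  Each row is one
scenario; `render_report(report, "outdir")` writes the ratio table, both
distribution representations, per-scenario VTU von Mises maps and a plot.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_generate_model.R` (synthetic palate + mesh),
`02_baseline_stress.R` (no-relief field), `03_relief_study.R` (all seven
scenarios), `04_summary_tables.R` (headline comparison), writing under
`results/`.

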
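# mtlseg

Multi-template segmentation of the three mesiotemporal-lobe (MTL)
structures — hippocampus (HP), amygdala (AM) and entorhinal cortex (EC) —
from T1-like 3D volumes, with a synthetic phantom cohort generator and an
evaluation harness for atrophy detection.

Accurate MTL volumetry underpins the assessment of temporal lobe epilepsy
and other conditions in which these structures atrophy. Multi-template
("multi-atlas") methods segment a new scan by selecting the most similar
exemplars from a library of labelled templates, deforming them onto the
scan, and fusing them into one consensus segmentation. `mtlseg` implements
a hybrid surface/volume variant of this idea:

* **Hybrid template selection.** Templates are ranked by
  `O_total = O_volume + w_surface · O_surface`, combining a masked volume
  similarity (cross-correlation or NMI) with a surface term comparing
  vertex-wise texture features — 3 normalized-intensity, 3
  relative-intensity and 3 gradient features per vertex, sampled on 3/5/7 mm
  spherical neighborhoods split by the structure boundary — between the
  template ("true") and the test image ("estimated"):
  `O_surface = −(1/9V) Σ_v Σ_f |F_vf − F̂_vf| / σ_vf`.
* **Boundary-weighted non-linear registration.** A free-form
  control-lattice deformation maximizes
  `O_vol,reg + w_surf,reg · O_surf,reg − λ · O_smooth`, where `O_surf,reg`
  is the correlation of boundary-contrast RI features on the deforming
  template surface, optimized node-wise by derivative-free Nelder-Mead.
* **Global-to-local weighted shape averaging.** A simplex weight vector
  over the `n_b` best warped templates is optimized against the test
  image's features, then refined per-vertex on nested icosahedron sampling
  levels (42 → 2562 sampling vertices), and the fused surface is rasterized
  into the output label volume.

Surfaces are corresponded across subjects by radial sampling of each
(star-shaped) structure onto a shared icosphere, so vertex `v` denotes the
same anatomical location in every template.

Because no template library of real MRI is distributed with the package,
a first-class synthetic module generates phantom cohorts — three adjacent
star-shaped structures with population shape variability, tissue contrast,
noise, and a patient subgroup with volumetric atrophy — with exact ground
truth for every subject.

## Worked example

```r
library(mtlseg)

co  <- make_cohort(cohort_spec(n_templates = 8, n_test_controls = 1, seed = 11))
cfg <- segment_config(selection = selection_config(n_a = 5, n_b = 3))
s   <- co$tests[[1]]
res <- segment_mtl(s$volume, co$library, cfg, truth = s$label)
res$stage_report
```

```
# A tibble: 5 × 6
  stage             similarity dice_hp dice_am dice_ec mean_dice
  <chr>                  <dbl>   <dbl>   <dbl>   <dbl>     <dbl>
1 initial_subset         -4.55   0.719   0.800   0.738     0.752
2 registration           NA      0.956   0.953   0.869     0.926
3 restricted_subset      -4.86   0.954   0.953   0.881     0.930
4 global_weighting       -8.15   0.975   0.979   0.886     0.946
5 local_weighting        -7.56   0.973   0.980   0.875     0.943
```

The report tracks accuracy through the pipeline: the five selected
templates overlap the truth at Dice 0.75 on average before registration and
0.93 after (per-template Dice for the template-set stages); the weighted
consensus surface reaches Dice 0.94. The `similarity` column carries each
stage's own selection/fusion score. Final per-structure overlap and volumes:

```r
dice(s$label, res$label)
#    HP    AM    EC
# 0.973 0.980 0.875
label_volumes(res$label)   # mm^3
#   HP   AM   EC
# 1485  895 1027
```

EC is the least accurate structure — by design its phantom analogue has the
weakest tissue contrast, mirroring the clinical difficulty of the
entorhinal boundary.

A thin command-line front end (`inst/cli/mtlseg.R`) exposes
`simulate`, `segment` and `evaluate` over NIfTI volumes and OBJ surface
bundles; label codebook 0 = background, 1 = HP, 2 = AM, 3 = EC.

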
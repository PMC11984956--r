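# centriolr

Quantification pipelines for fluorescence imaging of the centriole's
distal appendages and early ciliogenesis.

Distal appendages are the ninefold-symmetric blades at the distal end of
the mother centriole that dock the preciliary vesicle and license primary
cilium assembly. Studies of this machinery lean on a recurring set of
bespoke quantifications: per-centrosome fluorescence intensity with robust
outlier handling, peak-to-peak diameters of the protein rings seen by
super-resolution microscopy, post-processing of two-colour 3D
single-molecule localization (SMLM) data, categorical scoring of assays
(ciliation, vesicle recruitment, CP110 removal), and replicate-aware
("nested") statistics. `centriolr` implements these as tested, reusable R
functions — tibble-in, tibble-out, pipe-friendly — together with
synthetic-data generators that carry exact ground truth, so every stage is
verifiable without microscope data.

## What is implemented

| Area | Functions |
| --- | --- |
| Synthetic data | `sim_centrosome_field()`, `sim_cilium_field()`, `sim_ring_image()`, `sim_smlm_scene()`, `sim_nested_dataset()` |
| Intensity quantification | `rolling_ball_subtract()`, `threshold_mask()`, `combine_and_merge_masks()`, `analyze_particles()`, `quantify_centrosomal_intensity()`, `quantify_ciliary_intensity()` |
| Assay scoring | `measure_cilium_length()`, `score_ciliation()`, `score_vesicle_positivity()`, `score_cp110()` |
| Ring geometry | `max_project()`, `peak_to_peak_diameter()`, `molecular_ruler()` |
| SMLM post-processing | `track_fiducial_and_fit_drift()`, `apply_drift_correction()`, `filter_quality()`, `estimate_affine()`, `apply_affine()`, `refine_registration_3dcc()`, `isolate_cluster()`, `cluster_axis_fit()`, `vesicle_candidate_filter()`, `com_offset()`, `distance_to_structure()` |
| Statistics | `welch_t()`, `fisher_exact_2x2()`, `nested_t()`, `nested_anova_dunnett()`, `rout_outliers()` |
| I/O and display | `write_field_tiff()`, `read_field_tiff()`, `write_locs_csv()`, `read_locs_csv()`, `autoplot()` methods, `plot_locs()`, `tidy()`/`glance()` methods |

Two models at the core, in the field's notation:

* **Peak-to-peak ring diameter.** On a max-projected top view, intensity
  profiles through the ring centre at 0/45/90/135 degrees each yield two
  opposing peaks (local maxima with 3-point parabolic sub-pixel
  refinement); the diameter is the mean of the four peak-to-peak
  distances.
* **Molecular ruler.** An epitope's maximal radial offset along an
  extended protein is `L = n_helical x 0.15 nm + n_disordered x 0.4 nm +
  n_IgG x 8 nm` (helical rise per residue, contour length per residue,
  IgG length). For a 400-residue coiled coil plus a 40-residue disordered
  stretch, `L = 76 nm`.

The nested tests compare *replicate means* (cells within a replicate are
not independent); Dunnett's many-to-one adjustment is computed by seeded
Monte-Carlo sampling of the max-|t| null. ROUT outlier flagging is the
constant-model specialization of robust-regression outlier removal at a
chosen false-discovery rate.

## Worked example

```r
library(centriolr)

# a synthetic two-channel field with 6 centrosomes, then the full pipeline
f <- sim_centrosome_field(n_centrosomes = 6, seed = 17)
quantify_centrosomal_intensity(f$field)
#> # A tibble: 6 x 8
#>   particle_id  x_px  y_px area_px2 circularity intensity_ref intensity_poi outlier
#> 1           1  124.  33.4       54           1        26388.        47512. FALSE
#> 2           2  212.  43.4       56           1        23967.        64444. FALSE
#> 3           3  220.  69.5       56           1        35287.        45319. FALSE
#> 4           4  141.  75.5       53           1        36549.        54378. FALSE
#> 5           7  190. 101.        67           1        58287.        72066. FALSE
#> 6           8  143. 144.        72           1        38458.        94307. FALSE
```

Each row is one detected centrosome: centroid (px), footprint area,
circularity, integrated background-subtracted intensity in the reference
(centrosome marker) and protein-of-interest channels, and the ROUT flag
(no outliers here). Ring measurement on a noise-free synthetic outer ring:

```r
ring <- sim_ring_image(diameter_nm = 513.4)  # ninefold, 40 nm px, 120 nm PSF
peak_to_peak_diameter(ring$field)
#> <ring_measurement> mean peak-to-peak diameter 494.6 nm (4 angles)
```

The ~19 nm shortfall against the generating truth is the PSF-plus-
discrete-blade bias of the peak-to-peak convention — within half a pixel,
the measurement's working tolerance. And the statistics layer:

```r
fisher_exact_2x2(1, 17, 16, 25)   # vesicle-positive centrioles, KO vs control
#> # A tibble: 1 x 3
#>   p_value odds_ratio method
#> 1  0.0113     0.0919 fisher_exact_2x2

molecular_ruler(400, 40, 0)
#> [1] 76
```

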
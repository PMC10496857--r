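# muellerpol

Pixel-wise decomposition of transmission Mueller-matrix images of thin
birefringent tissue sections, plus a forward simulator of layered
tissue stacks for validating every stage against ground truth.

## The problem

Imaging Mueller polarimetry measures, at every pixel, the 4x4 real
matrix **M** that maps input to output Stokes vectors (I, Q, U, V).
For fibrous tissue such as brain white matter, three derived maps
carry the biology: the **net scalar retardance** R_t (how much aligned
fiber the light crossed), the **azimuth of the optical axis** theta
(the in-plane fiber direction, 180-degree periodic), and the
**depolarization** alpha_t (scattering-induced loss of polarization
degree). When two fiber layers cross within the probed volume, the
retardance of the stack drops - two identical layers crossed at 90
degrees compensate exactly to R_t = 0 - and the azimuth map loses its
preferential orientation. These signatures matter to anyone reading
polarimetric maps of white matter, where crossing tracts can mimic the
anisotropy loss caused by disease.

`muellerpol` implements the full analysis chain used in this setting:

* **Cloude filtering** — project a measured M onto the physically
  realizable set by clamping negative eigenvalues of its Hermitian
  coherency matrix H = (1/4) Σ m_ij (σ_i ⊗ σ_j*).
* **Differential decomposition** — the matrix logarithm L = ln M split
  under the Minkowski metric G = diag(1, -1, -1, -1) into a polarizing
  generator m_m = (L - G Lᵀ G)/2 and a depolarizing generator
  m_u = (L + G Lᵀ G)/2, with
  R_t = sqrt(p4² + p5² + p6²), alpha_t = |α1 + α2 + α3|/3,
  theta = ½ atan2(p5, p4).
* **Lu–Chipman polar decomposition** — M = M_Δ M_R M_D (diattenuator,
  retarder, depolarizer in sequence), with
  R_t = arccos[tr(M_R)/2 - 1], alpha_t = 1 - (|a|+|b|+|c|)/3, and the
  azimuth from the retardance vector of M_R.
* **Map statistics** — per-image box-whisker summaries (Tukey 1.5 IQR),
  azimuth summaries with a retardance noise floor, sparse quiver
  exports, and cross-method difference maps.
* **Forward simulator** — seeded scenes of one- and two-layer
  birefringent, depolarizing stripes with spatial heterogeneity,
  holes, and detector noise, returning ground truth alongside the
  image.

The methods vignette (`vignettes/mueller-polarimetry.Rmd`) documents
the conventions, the numerical choices, and what the simulator does
and does not emulate.

## Worked example

Simulate the single-section scene (10 um layer, median retardance
18 degrees, fibers at 90 degrees, 10% holes, noise at the instrument
floor), decompose it with both methods, and summarize:

```r
library(muellerpol)

pre <- scenario_presets("single")
pre$noise$seed <- 7L
scene <- generate_image(pre$stack, pre$noise, shape = c(64, 64))

dec <- decompose_image(scene$image, method = "both")
boxwhisker_summary(dec$differential$rt_deg, dec$mask, "retardance_deg")
#>         map_name n_valid median    q1   q3 whisker_low whisker_high n_outliers
#> 1 retardance_deg    3643  18.23 16.53 20.2       11.03        25.69         92

azimuth_summary(dec$differential$theta_deg, dec$differential$rt_deg,
                dec$mask, floor_deg = 3)
#>      map_name n_valid median    q1    q3 whisker_low whisker_high n_outliers
#> 1 azimuth_deg    3640  90.41 86.48 94.13       75.01        105.4         94

compare_methods(dec$differential, dec$lu_chipman, dec$mask)$stats
#>   max_abs_delta_rt_deg max_abs_delta_theta_deg depol_rank_cor    n
#> 1                0.363                   0.229              1 3643
```

The recovered retardance median (18.2 degrees) and azimuth median
(90.4 degrees) match the generator inputs; the 453 pixels missing from
`n_valid` are hole pixels flagged below the 3-degree noise floor. The
two decompositions differ by well under half a degree on this noisy
scene (and by ~1e-13 degrees on noiseless input); their depolarization
maps rank pixels identically.

File-based workflows go through `write_mueller_image()` /
`run_pipeline()`, which read and write multi-page float32 TIFF (16
bands, m11..m44, JSON metadata in the ImageDescription) plus CSV
summaries, or through the subcommand script
`inst/cli/muellerpol.R` (`simulate`, `filter`, `decompose`, `stats`,
`quiver`, `compare`, `run`).

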
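# organoidqpi

Label-free characterization of neural organoids from quantitative oblique
back-illumination microscopy (qOBM), in R.

Neural organoids — including disease models such as Tuberous Sclerosis
Complex (TSC) organoids — are usually assessed by destructive endpoint
histology. qOBM instead recovers quantitative phase, and from it
refractive index (RI), from four oblique epi-illumination frames, so the
same organoid can be followed for weeks. This package implements the full
analysis chain for such studies:

* **Phase reconstruction** — differential phase contrast (DPC) from
  opposing-source frame pairs, then Tikhonov-regularized deconvolution
  with an antisymmetric phase transfer function
  `H(k) = i g (ŝ·k̂) A(|k|)`;
* **RI conversion and segmentation** — `Δn = λΔφ / (2π Δz)` with medium
  index `n_m = 1.3440`, and segmentation of high-RI material
  (`n ≥ 1.46`: lipid droplets, membranes, nucleic material), tracked as
  an area fraction per organoid over time;
* **Morphometrics** — whole-organoid area, equivalent diameter,
  circularity `4πA/P²`, solidity, moment-ellipse aspect ratio; rosette
  and lumen circularity and lumen centeredness;
* **Tile features** — 50 µm tiles scored by Haralick texture, fractal /
  granulometric pattern responses (including 4–8 µm curvilinear and
  34–38 µm² circular pattern scores), Fourier band powers and
  autocorrelation;
* **Feature selection and statistics** — mRMR, neighborhood component
  analysis and chi-square rankings with a top-150 consensus; Welch
  t-tests and two-tailed variance F-tests per week;
* **Histology** — Oil-Red-O quantification by optical-density conversion,
  FastRed/FastBlue color deconvolution and particle counting;
* **Synthetic phantoms** — a ground-truth organoid-section generator
  (rosettes + lumens, fissures lined by directional cells, lipid
  droplets) and a two-group longitudinal cohort simulator, so the whole
  pipeline is testable without microscope data.

## Worked example

```r
library(organoidqpi)

ph  <- generate_organoid_phantom(phantom_spec(droplet_area_fraction = 0.05, seed = 7))
raw <- simulate_qobm_acquisition(ph, acquisition_spec(snr_db = 20), seed = 7)
rec <- reconstruct_phase(compute_dpc(raw), phase_transfer_model(), recon_config())
seg <- segment_high_ri(phase_to_ri(rec), organoid_mask(ph))
ph$droplet_fraction   # 0.04975728  (ground truth placed by the generator)
seg$area_fraction     # 0.04686257  (recovered through imaging at 20 dB SNR)
```

The segmented fraction tracks the generator's ground truth within ~6%
relative here; the automated checks require ±20% across fractions
0.01–0.10 under noise.

A full simulated study — 6 control + 6 experimental organoids over 4
weeks with a differentiation-medium switch after week 2 — runs end to
end with:

```r
res <- run_pipeline(run_config(seed = 11), output_dir = "run1")
subset(res$analyze$per_week, feature == "curve_pattern_4_8um",
       select = c(week, phase, mean_control, mean_experimental, t_p))
#>    week phase mean_control mean_experimental          t_p
#> 4     1   pre  0.009757823        0.01012245 0.3360702115
#> 9     2   pre  0.010955102        0.01100408 0.9198366134
#> 14    3  post  0.011858503        0.01290884 0.1277248237
#> 19    4  post  0.012348299        0.01704490 0.0007129619
```

The 4–8 µm curvilinear pattern score (the signature of the elongated
directional cells flanking fissures) separates the groups only after the
medium switch: controls lose the phenotype while experimental organoids
retain it, and the final-week Welch test is significant at p < 0.01.
The high-RI fraction shows the complementary lipid trend
(`res$segment$summary`): both groups grow, the experimental group
faster.

A thin CLI lives at `inst/exec/oqpi.R` (`run` and `shear` subcommands).

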
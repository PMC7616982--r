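# skullpct

Pseudo-CT synthesis from MR images and acoustic evaluation for
transcranial ultrasound stimulation (TUS) planning.

Model-based TUS planning needs the skull's acoustic properties, which
are conventionally mapped from a head CT. When a CT is unavailable —
the usual situation in healthy-volunteer neuroscience — a *pseudo-CT*
(pCT) in Hounsfield units (HU) can be synthesised from MR instead.
`skullpct` implements the full chain:

* **Classical ZTE conversion (cCT)** — soft-tissue-peak normalisation
  of a zero-echo-time bone image, skull segmentation by the fixed
  intensity band [0.2, 0.75], and the calibrated linear bone mapping
  `CT = -2085 · ZTE + 2329` (HU), with soft tissue at 42 HU and air at
  −1000 HU. Calibration is a total-least-squares (first principal
  component) line fit.
* **Learned mappings (zCT / tCT)** — a slice-stack U-Net regression
  (5 levels, 3×3 convolutions with ReLU then batch-norm, skip
  connections, 11-slice input stacks, masked L1 loss, Adam with
  reduce-on-plateau), implemented from first principles with a C++
  convolution core, runnable at miniature scale on one CPU.
* **Acoustic property maps** — four-class tissue segmentation,
  monotone HU→density conversion, the skull sound-speed law
  `c = 1.33 ρ + 167` (m/s), constant skull attenuation.
* **Wave solvers** — the O'Neil closed-form bowl solution, a
  Rayleigh–Sommerfeld integral for the 4-element annular array
  (ROC 63.2 mm, outer apertures 32.8/46/55.9/64 mm, 500 kHz), and an
  internal 2D k-space pseudospectral continuous-wave solver with PML
  for heterogeneous skull slices.
* **Metrics** — MAE/RMSE image errors over head and skull masks, and
  focal metrics (peak pressure, peak position, −6 dB focal volume)
  with CT-vs-pCT comparison records and Table-style summaries.
* **Synthetic phantoms** — paired CT/ZTE/T1w ellipsoidal-skull head
  phantoms with ground-truth masks, seeded and fully deterministic,
  standing in for the non-distributable clinical cohort.

## Worked example

Generate a phantom, run the classical conversion, and compare the
pseudo-CT against the ground-truth CT:

```r
library(skullpct)

spec <- phantom_spec(grid_shape = c(96, 112, 104), voxel_spacing_mm = 2,
                     noise_sd = list(ct = 0, zte = 0, t1w = 0))
ph <- generate_phantom(spec)

res <- classical_pct(ph$zte, ph$head)
res$mapping
#> <hu_mapping> CT = -2085 * ZTE + 2329

skull <- skull_mask_from_ct(ph$ct, ph$head)
image_metrics(res$pct, ph$ct, skull, region = "skull")
#> # A tibble: 1 × 4
#>   region mae_hu rmse_hu n_voxels
#>   <chr>   <dbl>   <dbl>    <int>
#> 1 skull  0.270   0.280    55836
```

A skull MAE well below 1 HU on a noiseless phantom confirms the
conversion inverts the phantom's bone mapping essentially exactly
(the tiny residual comes from interpolation in the soft-tissue-peak
normalisation).

Simulate the array's free field in water and measure the focus:

```r
ff <- free_field_focus(transducer_spec())
c(width = ff$width_mm, length = ff$length_mm)
#>    width   length
#> 4.042395 25.18629
```

i.e. a −6 dB focal spot about 4.0 mm wide and 25.2 mm long, matching
the device's published free-field focus (3.9 mm × 24 mm) to within a
few percent.

The cohort-level experiments (`run_image_experiment()`,
`run_acoustic_experiment()`) chain phantoms → pseudo-CTs → medium maps
→ 2D field simulations → focal comparisons, with per-subject exclusion
logging. A command-line front end is installed as `exec/skullpct`
(subcommands `phantom`, `convert`, `medium`, `simulate`, `evaluate`).

See the methods vignette (`vignettes/skullpct-methods.Rmd`) for the
models, assumptions, parameter choices and limitations.

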
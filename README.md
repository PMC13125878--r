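# cardiomotion

Decoupled quantification of cardiac, respiratory, and hysteresis motion
of cardiac substructures from phase-binned volumetric imaging, with
internal organ-at-risk volume (IRV) derivation and dosimetric
evaluation — for medical physicists and methods researchers working on
cardiac sparing in thoracic radiotherapy.

## What it does

Free-breathing volumetric acquisitions can be retrospectively sorted
into cardiac phases (end-diastole ED, end-systole ES) × respiratory
states (end-exhale EE, active exhale AEx, active inhale AIn, end-inhale
EI), yielding one binary mask per substructure per bin. From such a
phase grid, `cardiomotion` computes:

- **Binning** — phase-based cardiac sorting from trigger times
  (bin = ⌊N·(t−t_k)/(t_{k+1}−t_k)⌋) and amplitude-based respiratory
  sorting with a 10%/80%/10% percentile split of the baseline-corrected
  bellows waveform, AIn/AEx by slope sign.
- **Excursion metrics** — cardiac motion = ED→ES displacement averaged
  within respiratory states; respiratory motion = EE→EI averaged within
  cardiac phases; hysteresis = AEx→AIn averaged within cardiac phases.
  Centroid components (RL/AP/SI, mm) with vector = mean of per-state
  norms √(RL²+AP²+SI²); signed bounding-box face shifts for the six
  faces; directed surface distances d_a = min_{b∈B} ‖a−b‖ summarized as
  MDA (mean) and HD95 (95th percentile); strict >5 mm exceedance flags
  and cohort counts.
- **IRV margins** — per direction, the maximal outward bounding-box
  face shift over the phase pairs, floored at 0; cardiorespiratory =
  cardiac + respiratory per face; expansion by an axis-aligned
  Minkowski box (ceiling voxelization).
- **Dosimetry** — trilinear dose sampling at mask voxel centers,
  cumulative DVH, and D_0.03cc (minimum dose of the hottest 0.03 cc,
  fractional-voxel interpolation); ΔD_0.03cc between reference and IRV
  is provably ≥ 0.
- **Statistics** — Kruskal–Wallis (tie-corrected) + Dunn post-hoc with
  Bonferroni over pairs, across 8 metrics per grouping and motion type;
  a battery is overall significant when ≥ 4/8 metrics have p < 0.05.
  Built-in groupings: physiological classes, right vs left heart, base
  vs apex, RCA vs right chambers, LCA vs left chambers.
- **Synthetic phantom** — geometric substructures (spheres, tubes,
  ellipsoids) on a 96³ × 1.56 mm grid moving with a prescribed cardiac
  (raised-cosine ED→ES) plus respiratory (elliptical loop EE→EI with
  perpendicular hysteresis offset) model, exact ground-truth tables,
  surrogate bellows/trigger signals, and synthetic dose grids — so the
  whole pipeline is testable without any imaging data.

Masks and dose grids are read/written as NIfTI-1 (`.nii`/`.nii.gz`,
RAS+ = RL/AP/SI enforced from the affine); signals and all results are
CSV with units in headers; runs are driven by a YAML/JSON config with
an explicit seed.

## Worked example

```r
library(cardiomotion)

spec  <- default_phantom()   # "LV" sphere + "RCA" tube, 96^3 @ 1.56 mm
model <- motion_model(cardiac_amp = c(-5.5, 3.8, -3.6),  # mm, ED -> ES
                      resp_amp    = c(0, 1, -4),         # mm, EE -> EI
                      hysteresis  = 4)                   # mm loop width
grid <- render_phase_grid(spec, model, subject = "S01")

cardiac_motion(grid, "RCA")$displacement
#> <displacement> RL -5.53  AP +3.80  SI -3.58  |v| 7.60 mm
respiratory_motion(grid, "RCA")$displacement
#> <displacement> RL -0.02  AP +1.09  SI -4.04  |v| 4.18 mm
hysteresis_motion(grid, "RCA")$displacement
#> <displacement> RL -0.22  AP -3.68  SI -1.11  |v| 3.86 mm

derive_margins(grid, "RCA", "cardiorespiratory")
#> <margin_set> cardiorespiratory (mm outward)
#>     right      left  anterior posterior  superior  inferior
#>      0.00      4.68      6.24      0.00      0.00      7.80

ref  <- grid$masks$RCA$ED$EE
irv  <- expand_structure(ref, derive_margins(grid, "RCA", "cardiorespiratory"))
dose <- render_dose(spec, "linear_gradient", level = 30,
                    gradient = c(0, 0, 0.8), ref_point = c(74, 74, 74))
delta_d(ref, irv, dose)
#> $d_ref 38.19   $d_irv 39.44   $delta 1.25   (Gy)

distance_metrics(surface_distances(grid$masks$RCA$ED$EE, grid$masks$RCA$ES$EE))
#> mda 2.17 mm, hd95 5.62 mm (n = 245 surface points)
```

The recovered cardiac displacement (−5.53, +3.80, −3.58) mm matches the
injected (−5.5, 3.8, −3.6) mm to well within half a voxel — the
decoupling averages out the respiratory term exactly, up to
rasterization. The vector 7.60 mm here equals the norm of the
components because motion is identical in every respiratory state; with
state-varying motion the reported vector is the mean of per-state norms
and exceeds the norm of the mean components. The cardiorespiratory
margins are the per-face sums of the cardiac and respiratory outward
shifts, quantized up to whole 1.56 mm voxels; expanding the reference
contour by them moves its hottest 0.03 cc from 38.19 Gy to 39.44 Gy on
the synthetic gradient field (ΔD_0.03cc = +1.25 Gy, necessarily ≥ 0).

An end-to-end run (`phantom cohort → metrics → >5 mm counts → margins →
IRVs → DVH/D_0.03cc → stats`, all outputs + resolved config + log):

```r
run_full(default_run_config(seed = 1), out_dir = "out")
```

or from the shell: `inst/cli/cardiomotion full --seed 1 --out out`.

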
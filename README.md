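# kneeslope

Musculoskeletal analysis of how posterior tibial slope (PTS) — the sagittal
tilt of the tibial component — alters joint mechanics after total knee
arthroplasty (TKA).

## Who this is for

Biomechanists and implant engineers who want a desk-scale, fully synthetic,
fully reproducible pipeline for slope sensitivity studies: no CT segmentation,
no gait-lab data, no proprietary implant CAD.  The package builds a
parametric, highly congruent implanted knee; calibrates its soft tissue;
solves, frame by frame through a functional activity, the coupled problem of
muscle recruitment and secondary joint kinematics; and sweeps the implantation
slope to quantify how every contact, ligament and muscle outcome responds.

## The model in brief

* **Contact** — elastic foundation: local pressure from local penetration of
  a deformable layer of depth *h* on a rigid backing, `p = K d / h` (or the
  logarithmic variant), `K = E(1-ν)/((1+ν)(1-2ν))`; penetration measured by
  compiled ray casting on triangle meshes.  Verified against the closed form
  `F = π K R δ² / h` for a sphere on a plane.
* **Ligaments** — ten bundles (sMCL, dMCL, LCL, POL, pCAP, PFL, ITB, mPFL,
  lPFL, patellar tendon) of tension-only Blankevoort strands
  (`f = k ε²/(4ε_l)` below `2ε_l`, linear beyond), with every strand's slack
  length calibrated so its strain at full extension is exactly 2%.
* **Muscles** — six knee-crossing actuators (vasti, rectus femoris via the
  patella; hamstrings and gastrocnemius heads), rigid tendon, `F = a·Fmax`,
  tendon-excursion moment arms with cylinder wrapping.
* **Solver** — knee flexion is prescribed; the eleven secondary coordinates
  (five tibiofemoral, six patellofemoral) plus the activation multiplier of
  the minimum-effort (`min Σa²`) redundancy problem are solved as one
  quasi-static root problem per frame.
* **Sweep** — the inlay is re-implanted virtually from −5° to +19° of slope
  in 2° steps around a 7° baseline (slack lengths frozen), and Spearman rank
  correlations are computed between slope and the peaks and ranges of every
  outcome metric.

## A worked example

```r
library(kneeslope)

model <- calibrate_model(knee_model())
sim   <- simulate_activity(model, generate_walking_profile())
print(sim)
#> knee_simulation: walking, 50 frames, 100% converged
#>   peak F_Total P-D: 3.13 BW | peak flexion: 54.9 deg
#>   worst residuals: flexion 0.0223 N m, secondary 0.99 x tolerance
```

The peak axial tibiofemoral force of ~3.1 body weight sits in the physiologic
band for level walking; the residual lines confirm every frame closed its
moment balance to 0.05 N m and its secondary equilibrium to 0.5 N / 0.05 N m.

```r
sweep <- run_pts_sweep(model, generate_walking_profile(), sweep_alignments(7, 12, 2))
print(sweep)
#> pts_sweep: walking, 13 alignments (-5 to 19 deg, baseline 7)
#>   convergence: 100% (worst alignment)
#>   Spearman rho vs PTS (key metrics):
#>     CoP_med_AP_at_peak2_mm   -1.000
#>     CoP_lat_AP_at_peak2_mm   -1.000
#>     ap_at_extension_mm       -1.000
#>     peak_quadriceps_N        -0.824
#>     peak_F_ap_anterior_tibia_BW +1.000
#>     peak_PF_F_BW             -1.000
```

Reading the coefficients: as the slope increases, both compartments' centres
of pressure (sampled at the late-stance force peak) and the femoral resting
position move posteriorly (ρ = −1, strictly monotone), the anterior shear
transmitted to the tibial component grows, and the peak quadriceps and
patellofemoral forces fall — the extensor mechanism becomes more efficient
as the femur settles further back.
`plot(sweep)` draws the four key trends; `write_report(sweep, dir)` writes
`metrics.csv`, `sensitivity.csv`, per-alignment frame tables and a config
snapshot, byte-identical across re-runs.

The methods vignette (`vignettes/pts-knee-mechanics.Rmd`) documents the
model, its assumptions, every tunable parameter, and what the synthetic
inputs can and cannot demonstrate.

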
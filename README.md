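# mpcest

Quantitative glucoCEST MRI with T2 confound removal.

Dynamic glucose-enhanced (DGE) MRI tracks the uptake of unlabeled D-glucose
through chemical exchange saturation transfer (CEST): hydroxyl protons
exchanging with water at ~+1.2 ppm attenuate the water signal under
off-resonance saturation. The catch is that glucose also *shortens* tissue T2
(transverse relaxivity ≈ 0.053 s⁻¹ mM⁻¹ at 7 T), and T2 contaminates the DGE
readout twice: a shorter T2 broadens the water line, increasing spillover
during saturation, and it accelerates signal decay during the multi-echo
readout. Left uncorrected, a T2 drop inflates single-offset DGE and deflates
MTR-asymmetry DGE.

`mpcest` implements the full quantification stack for separating the two
effects, aimed at CEST methodologists and preclinical imaging groups:

- **`bmc_sim`** — a multi-pool Bloch–McConnell Z-spectrum simulator (exact
  matrix-exponential propagation of the rectangular-pulse generator) plus the
  analytical rotating-frame model
  `S_ss = cos²θ·R1 / R1ρ`, `R1ρ = R_eff + Σ R_ST,pool`,
  with `R_eff = cos²θ·R1 + sin²θ·R2` and additive per-pool exchange terms.
- **`relaxometry`** — voxel-wise mono-exponential fitting
  `S(TE) = PD·exp(−TE/T2)` of multi-echo stacks, yielding T2 and
  saturation-weighted PD maps; PD-based Z-spectra remove the readout-decay
  confound (their saturation dip is measurably narrower).
- **`dge_quant`** — Z-spectrum normalization `S = Z/Z0`, single-offset DGE
  `100·(S_baseline − S(t))/S_baseline`, MTR-asymmetry DGE
  `100·(MTRasym(t) − baseline)`, and the MRS helper
  `Δ[Glc] = (3/5)·R_Glc/tCr·[tCr]`.
- **`t2_correction`** — simulation-calibrated correction: a linear background
  model `S_bg = S⁰ + k·ΔT2` for single-offset DGE, and a quadratic model
  `a·ΔT2² + b·ΔT2 + c` for the scaled-down MTR-asymmetry background
  (`MTRasym ≈ S_bg²·R_glucose/(cos²θ·R1)`), applied with co-acquired dynamic
  T2 maps; plus Pearson decoupling reports.
- **`synthetic_data`** — digital six-tube glucose phantoms (10–310 mM) and
  dynamic uptake experiments with exactly coupled glucose/T2 time courses,
  multi-echo readout and seeded Rician noise.
- **`io_cli`** — NIfTI-1 + JSON-sidecar image I/O, CSV/YAML/JSON tables and
  configs, and a `mpcest` command line (`simulate`, `phantom`, `dynamic`,
  `fit`, `calibrate`, `correct`, `report`).

## Worked example

Calibrate a tumor-regime correction model and correct a simulated DGE
experiment whose T2 falls from 47.5 to 44.0 ms during uptake (the plateau
concentration implied by that excursion is 31.6 mM):

```r
library(mpcest)

pulse  <- saturation_pulse(b1 = 2, t_sat = 2, offset = 1.2)   # 2 uT, 2 s, 7 T
t2_ref <- preset_t2_ref("tumor")                              # 47.5 ms
plateau <- plateau_for_t2(t2_ref, 44.0)                       # 31.6 mM

grid  <- seq(t2_ref - 5, t2_ref + 5, length.out = 21)
model <- calibrate_linear(tissue_pools("tumor"), pulse, grid, t2_ref,
                          glucose_ref = plateau)
model <- calibrate_quadratic(tissue_pools("tumor", plateau), pulse, grid,
                             t2_ref, model = model)
model
#> <correction model>
#>   t2_ref = 47.5 ms, S0 = 0.3003
#>   linear:    k = 4.5709e-03 /ms  (R^2 = 0.9997)
#>   quadratic: a = -9.6437e-07 /ms^2, b = 2.6630e-04 /ms, c = -3.1107e-08

proto <- dynamic_protocol(n_frames = 40, n_baseline = 10, plateau = plateau,
                          noise = "none")
sim <- simulate_dge_experiment(proto, "tumor", seed = 1)

io_p <- which(proto$offsets == 1.2); io_n <- which(proto$offsets == -1.2)
series <- dge_series(proto$time, sim$truth$s[io_p, ], 1:10,
                     mtr_asym = sim$truth$s[io_n, ] - sim$truth$s[io_p, ])
series <- mtr_asym_dge(single_offset_dge(series))
t2dyn  <- dynamic_t2(proto$time, sim$truth$t2_ms, 1:10)
series <- correct_mtr_asym(correct_single_offset(series, t2dyn, model),
                           t2dyn, model)

plat <- 35:40
mean(series$dge[plat]);       mean(series$dge_corrected[plat])
#> 10.67   5.41        # T2 drop inflated the single-offset DGE ~2x
mean(series$dge_asym[plat]);  mean(series$dge_asym_corrected[plat])
#> 0.93    1.02        # ... and deflated the MTR_asym DGE
```

`k > 0` says the background signal at +1.2 ppm rises ~0.46% per ms of T2; the
quadratic coefficients encode how the background's scaled-down effect moves
the asymmetry. Re-running the experiment with T2 pinned at baseline gives the
glucose-only reference: 5.86% (single-offset) and 1.02% (MTR_asym). The
uncorrected curves miss those by +82% and −9%; the corrected ones land within
8% and 0.2%.

The same pipeline from the shell:

```sh
mpcest calibrate --preset tumor --out model.json
mpcest dynamic   --seed 7 --out run/
mpcest correct   --series series.csv --t2 t2.csv --model model.json \
                 --baseline 10 --out corrected.csv
mpcest report    --series corrected.csv --t2 t2.csv --baseline 10 \
                 --out decoupling.csv
```

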
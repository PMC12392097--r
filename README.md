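# flickmorph

Comparative biomechanics of the fish **head flick** — the rapid lateral
(yaw) head rotation substrate-biting reef fishes use to tear attached prey
free. The package asks how control-surface morphology shapes flick
kinematics in hinged two-segment physical models: the head's moment of
inertia (MOI) should set flick speed (at constant spring torque,
`tau = I * alpha`), and the ratio of head MOI to the MOI of the *lateral
profile* (body + dorsal, anal, caudal fins) should set how much the body
recoils, since angular momentum balances across the hinge:

```
I_head * w_head = I_lateral * w_body
=> body displacement = (I_head / I_lateral) * 45 degrees
```

It is aimed at functional morphologists and biomechanists who want a
tested, reproducible version of this analysis chain:

* **MOI engine** — strip decomposition of silhouette polygons
  (`I = sum m_i r_i^2`, exact polygon clips, second-order convergent),
  with an independent pixel-integration oracle;
* **flick simulator** — latch-released, constant-torque yaw dynamics of a
  hinged head on a body (RK4), optional quadratic drag, emitting 4-landmark
  trajectories at 250 fps;
* **kinematics extraction** — head-body and earthbound body angles from
  landmarks, interpolated 45 degree crossing, per-trial speed and body
  displacement, species-level averaging;
* **synthetic morphology** — pure-birth phylogenies, correlated
  Ornstein-Uhlenbeck trait evolution, parametric silhouettes normalised to
  a 30 cm^2 head area;
* **statistics** — closed-form OLS of kinematics on MOI, and a
  phylogenetically corrected Pearson correlation under an OU model
  (GLS-whitened, per-trait maximum-likelihood signal strength).

Everything is tibble-in/tibble-out with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(flickmorph)

study <- generate_study(seed = 1)   # 17 species, 6-10 trials each
study
#> <study_dataset> 17 species, 142 trials
#>   head MOI 2358-3433 g cm^2; lateral MOI 134436-580835 g cm^2
#>   mean speeds 769-926 deg/s; displacements 0.53-1.81 deg

models <- run_study_models(study)
models$ols_speed
#> <flick_ols> mean_speed_degps ~ head_moi (n = 17)
#>   slope -0.1431 +- 0.00358, intercept 1255; adj R^2 0.990
#>   F(1, 15) = 1.6e+03, p = 1.2e-16
models$ols_displacement
#> <flick_ols> mean_displacement_deg ~ relative_moi (n = 17)
#>   slope 88.51 +- 0.697, intercept 0.01174; adj R^2 0.999
#>   F(1, 15) = 1.61e+04, p = 3.73e-24
correlation_table(models)
#> # A tibble: 3 x 9
#>   pair        x          y              r  p.value     n alpha_x alpha_y method
#> 1 caudal_body log_caudal log_body   0.975 3.17e-11    17  0.959    0.754 ou_gls
#> 2 anal_dorsal log_anal   log_dorsal 0.965 3.90e-10    17  0.0704   0.558 ou_gls
#> 3 head_body   log_head   log_body   0.572 1.64e- 2    17  3.66     0.754 ou_gls
```

Reading: heavier heads flick more slowly (negative slope of speed on head
MOI, here -0.14 deg/s per g cm^2 across a 2358-3433 g cm^2 head-MOI range at
fixed 30 cm^2 head area), and models with a larger head-to-lateral MOI ratio
recoil more (positive displacement slope, close to the drag-inflated
momentum-balance line). The correlation table gives phylogenetically
corrected correlations among log surface MOIs, with each trait's fitted OU
signal strength (per unit tree height).

Single models work the same way:

```r
m <- reference_model()
summarize_model(m)
#> <moi_result> reference
#>   head MOI 2637.0 g cm^2 (hinge axis); lateral MOI 255442.6 g cm^2 (COM axis)
#>   relative MOI 0.0103; pelvic fin 3047.7 g cm^2 (excluded from lateral)
autoplot(m)                          # silhouette with hinge and COM
p <- flick_params(torque = 1e6, head_moi = 2000, lateral_moi = 4e5)
trial <- simulate_flick(p, m)        # drag-free: t_end = sqrt(2*theta*I/tau)
extract_kinematics(trial)
```

The end-to-end pipeline, with every intermediate artifact written to disk
(Newick tree, trait CSV, silhouette JSONs, trial CSV bundles, MOI table,
statistical report, manifest):

```r
run_pipeline(study_config(seed = 1), "study_out")
```

or from a shell via the thin wrapper
`Rscript inst/cli/flickmorph.R all --config study.yaml --out study_out`
(per-stage subcommands `generate`, `moi`, `extract`, `stats` re-run single
stages from a study directory).

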
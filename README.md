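# curtainr

Simulation and quantitative analysis of single-molecule **ssDNA curtain**
experiments on translocating motor proteins.

In these assays, long (≥50 knt) single-stranded DNA molecules are tethered
at their biotinylated 5′ ends to lipid-bilayer diffusion barriers, extended
by flow, coated with fluorescent RPA or with recombinase (RAD51/DMC1)
filaments, and imaged by TIRF microscopy at 1 frame per 10 s. An
antirecombinase motor protein binds the coated ssDNA and translocates 3′→5′,
either clearing the fluorescent coat behind it or leaving a fluorescent RPA
trail as it strips recombinase. Kymographs along each molecule record the
motion; the quantities of interest are the translocation **velocity**
(Gaussian fit to 15 nt/s-binned velocities, reported as μ ± σ in nt/s), the
**processivity** (half-life of the single-exponential fit to the survival
curve of run distances, in nt, with bootstrap 95% CI), **exchange rates** of
filament assembly/disassembly (*I = A·e^(−kt)* and *I = A·(1 − e^(−kt))*),
the **stoichiometry** of the translocating complex (photobleaching step
counts), **biolayer interferometry** (BLI) dissociation kinetics (fast+slow
biexponential), and the classification of collisions with heteroduplex DNA
joints (direct recruitment vs. translocation; stall / disrupt / bypass).

The package is aimed at single-molecule biophysicists who want a tested,
reproducible implementation of this analysis chain — and a synthetic-data
generator that emulates the experiments with logged ground truth, so every
stage can be validated without any raw data download.

## What's inside

| Stage | Functions |
| --- | --- |
| Simulation | `motor_model()`, `imaging_model()`, `simulate_translocation_events()`, `render_kymograph()`, `simulate_photobleach_trace()`, `simulate_exchange_curve()`, `simulate_bli_sensorgram()`, `simulate_collision_movie()`, `simulate_end_traces()` |
| Tracking | `extract_kymograph()`, `detect_front()`, `track_puncta()`, `segment_translocation()`, `px_to_nt()` |
| Kinetics | `fit_velocity_distribution()`, `survival_curve()`, `fit_processivity()`, `fit_exchange_rate()`, `monomers_per_second()` |
| Photobleaching | `count_steps()`, `classify_cohort()` |
| BLI | `segment_phases()`, `normalize_and_subtract()`, `fit_biphasic()` |
| Collisions | `locate_joint()`, `classify_encounter()`, `tally_outcomes()`, `score_end_foci()` |
| Orchestration | `curtain_preset()`, `analyze_preset_experiment()`, `run_config()`, `cmd_simulate()`, `cmd_analyze()`, `cmd_report()` |

Fitted objects have `tidy()`/`glance()` methods and `autoplot()` figures
(histogram + Gaussian, survival + fit, trace + steps, kymograph rasters).

## Worked example

Simulate the RAD51-stripping condition at its published sample size
(152 binding events on 150 knt molecules, 20 min movies), render noisy
kymographs, track the RPA-GFP exchange fronts, and fit velocity and
processivity:

```r
library(curtainr)

fit <- analyze_preset_experiment("fig4DE", seed = 1, n_boot = 1000)
fit
#> <experiment_fit> preset fig4DE: v = 57.1 +/- 18.4 nt/s (N = 120), half-life = 8737 nt (95% CI 7261-10791)

glance(fit)
#>   preset velocity_mu velocity_sigma half_life half_life_lo half_life_hi n_events n_uncensored monomers_per_s seed
#> 1 fig4DE       57.14          18.39      8737         7261        10791      120          111          19.05    1

round(monomers_per_second(fit$velocity_fit$mu), 1)
#> [1] 19
round(monomers_per_event(fit$survival_fit$half_life))
#> [1] 2912
```

The preset's ground truth is 59 ± 17 nt/s and a 9500 nt half-life: the
recovered 57.1 nt/s sits inside the Gaussian fit's confidence interval and
9500 nt inside the bootstrap 95% CI. Of 152 simulated binding events, 120
pass the detection gates (≥3 frames, ≥1450 nt displacement) and 111 are
uncensored and enter the survival fit. At one RAD51 monomer per 3 nt the
fitted velocity corresponds to ~19 monomers removed per second.

`autoplot(fit$velocity_fit)` and `autoplot(fit$survival_fit)` draw the
publication-style histogram and survival panels.

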
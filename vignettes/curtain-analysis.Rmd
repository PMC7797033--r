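---
title: "Models and methods behind curtainr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind curtainr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curtainr)
```

curtainr simulates and analyses single-molecule ssDNA-curtain experiments on
translocating motor proteins — antirecombinases that move 3'→5' along
protein-coated single-stranded DNA, stripping RPA, RAD51 or DMC1 as they go.
This vignette documents the generative models, the estimators, the numerical
choices, and what the package's tests do and do not demonstrate.

## The motor model

A `motor_model()` is described by four kinetic quantities:

* **Velocity.** Each motor draws a single velocity from a Gaussian
  `N(velocity_mean, velocity_sd)` truncated at zero, and keeps it for its
  whole run. The truncation is our choice — a Gaussian puts mass at negative
  velocities which have no physical meaning for a unidirectional motor — and
  so is the constancy within a run: single-molecule kymographs of this class
  of enzymes look linear at 10 s resolution, but nothing in the package's
  validation distinguishes constant velocity from a within-run random walk
  with matching mean, because all estimators operate on linear fits.
* **Run length.** Exponential with scale `processivity_halflife / log(2)`,
  i.e. parameterised directly by the half-life that a single-exponential
  survival fit reports. The median of the draw equals the half-life, so the
  fitted processivity of a large uncensored sample recovers the parameter
  with no conversion.
* **Binding.** Poisson in time with rate `binding_rate` per knt per second,
  uniform in position along the lattice. Runs are censored where they hit
  the tethered 5' end (coordinate 0) or the end of the movie; both are
  flagged with the reason in the ground-truth log.
* **Coat mode.** `clearing` removes the fluorescent coat behind the motor
  (dark trail on a bright molecule); `exchange` deposits a fluorescent coat
  behind it (bright trail on a dark molecule). A GFP-tagged motor
  additionally renders as a diffraction-limited punctum in its own channel.

## The imaging model

Defaults follow the standard acquisition geometry for ssDNA curtains:
1 frame per 10 s with 100 ms integration (the laser is shuttered between
frames, so each frame is an independent snapshot), 725 nt per pixel along
the extended ssDNA, and a Gaussian PSF of 1 pixel sigma — the ~254 nm
optical resolution expressed on the pixel grid. Pixel values are
`brightness x PSF-blurred coverage`, with Poisson shot noise at
`photon_gain` expected photons per unit brightness plus Gaussian read
noise; setting both noise parameters to zero (`noise_free()`) renders
exactly, which is what the oracle tests exploit.

## Tracking

**Fronts.** For unlabeled motors the observable is the moving boundary of
the cleared (or deposited) coat. Each frame's profile is smoothed (1 px
Gaussian), normalised to the coat plateau, and the front taken where the
profile crosses half the plateau, refined by linear interpolation. The
half-plateau threshold is the unique height at which a PSF-blurred step
crosses exactly at the true edge position. Two systematic corrections
matter:

* *Narrow tracts.* While a nascent tract is narrower than a few PSF widths,
  its two blurred edges overlap and both half-plateau crossings sit inside
  the true edges. `detect_front()` inverts the box-convolved-with-Gaussian
  edge model per frame (given the measured tract width) and pushes both
  crossings back out. Without this correction, velocities of short runs
  (4–6 frames) are inflated by 3–5%.
* *Monotonicity.* Fronts cannot retreat — the motor is unidirectional and
  the coat does not reform in these assays — so an isotonic regression pass
  projects the trajectory onto the non-retreating cone. Frames with no
  crossing (fully coated before binding, or fully cleared) are reported
  missing, never interpolated.

**Puncta.** Labeled motors and heteroduplex joints are tracked as
intensity-weighted centroids around local maxima that exceed a noise gate,
linked across frames by nearest-neighbour assignment with a 5 px jump gate
and tolerance for 3-frame gaps. The noise SD is estimated *temporally* — the
MAD of frame-to-frame pixel differences over the whole kymograph, divided by
sqrt(2). A spatial estimate fails in both of this package's regimes: on a
dark motor channel the background is clipped at zero and a spatial MAD
collapses, while on a 21-pixel end-trace strip the punctum itself
contaminates every upper quantile. Near-static structure contributes almost
nothing to frame differences, so the temporal estimate is clean in both.

**Segmentation.** A trajectory becomes a translocation event if it moves.
The moving interval runs from the first valid point to the first point of
the final plateau (0.3 px jitter gate); velocity is the regression slope of
the interior points — the first and last moving points are excluded as
partial/distorted frames, plus an adaptive trim while the leading residual
exceeds 0.07 px — converted at 725 nt/px. Acceptance gates: at least 3
frames, at least 1450 nt (2 px) displacement, at least 10 nt/s, and
movement toward the 5' end. Below these gates an "event" is within the
optical/temporal resolution floor and is rejected (an empty result, not an
error). Distance is measured as the *tract extent* (static origin edge
minus final front) when front tracking is used, which is immune to the
half-frame truncation at binding; for punctum tracking, where no origin
edge exists, half a frame-interval of travel is added because binding is
uniform within the frame interval (mean loss `v * dt / 2`).

## Velocity and processivity estimators

Velocities are binned at 15 nt/s (bins anchored at 0) and the counts fitted
to `A exp(-(v - mu)^2 / (2 sigma^2))` by unweighted least squares; the
reported value is `mu +/- sigma`. Two properties of this estimator are
worth knowing: it is consistent for `mu`, but the binning inflates the
fitted width to about `sqrt(sigma^2 + bw^2/12)` (a Sheppard-type
correction that the presentation convention does not apply), about +2% at
`bw = 15`, `sigma = 15`. With all velocities identical the fit is
degenerate and raises an error, as does input below 10 events.

Processivity is the half-life of the least-squares fit of
`S(d) = exp(-lambda (d - d_min))` to the empirical survival of uncensored
run distances. Numerical and statistical choices:

* Amplitude is fixed at 1: the survival of a distance sample starts at 1 by
  construction, and freeing the amplitude only dilutes the decay constant.
* The optimisation runs on `log(lambda)` with tolerance 1e-10. `lambda` is
  of order 1e-4 per nt — *smaller than `optimize()`'s default absolute
  tolerance* — so a linear-scale optimisation silently quantises the fit.
* `d_min` is the detection threshold of the event filter (1450 nt in the
  pipeline). Events shorter than the threshold are unobservable, so the
  observed sample is left-truncated; by the memorylessness of the
  exponential, shifting the model by `d_min` makes the fit exact for the
  truncated law. Fitting without the offset overestimates the half-life by
  +20–30% at these parameter values.
* Confidence intervals are percentile bootstrap over resampled distances
  (default 1000 resamples, seeded). Censored events are excluded by
  default; they carry information only through a censoring-aware estimator,
  which is deliberately out of scope.

## The figure presets and what recovery shows

`curtain_preset()` encodes eight published experimental conditions as
ground truth (velocity mean/sd in nt/s, processivity half-life in nt, event
count): 68 ± 19 / 7900 / 54; 59 ± 17 / 9500 / 152; 58 ± 32 / 10300 / 174;
28 ± 12 / 5200 / 77; 54 ± 22 / 9500 / 67; 49 ± 16 / 6100 / 44;
53 ± 28 / 4600 / 41; 54 ± 23 / 6300 / 69. The recovery experiments simulate
each condition at its published N, render noisy kymographs, track, and fit.

Preset simulations run on 150 knt molecules with binding confined to a
300 s injection window of a 1200 s movie. Both are deliberate: ssDNA
substrates from rolling-circle replication are "at least" ~50 knt and
routinely much longer, and a bolus injection concentrates binding early.
On a 50 knt lattice with uniform binding, ~23% of runs with an 11 knt mean
would hit the 5' end; excluding those censored runs biases the fitted
half-life by about −23%, and including them biases it down too. At 150 knt
the censored fraction is ~7% and the residual bias ~−3%, small against the
sampling noise. This is a property of the estimator applied to finite
molecules, not of the motor model, and the same selection effect operates
on real data.

What passing recovery shows: the full pipeline (render → track → segment →
fit) is unbiased to within a few percent at realistic noise, and its
scatter matches the `halflife/sqrt(N)` floor of the survival estimator —
at N = 54 the per-experiment SD of the fitted half-life is ~15%, which is
why the recovery criterion is containment in the bootstrap 95% CI rather
than a tight band. What it does not show: robustness to features the
generator does not emulate — stage drift, neighbouring molecules in the
ROI, heterogeneous coat density, photobleaching of the coat, or pausing
motors.

## Photobleaching step counting

Traces are fit piecewise-constant by penalised binary segmentation: a split
is accepted when it reduces the residual sum of squares by more than
`penalty_scale * sigma^2 * log(n)`, with `sigma` the robust noise SD
(`mad(diff(y))/sqrt(2)`). Level changes smaller than 3 robust SD are merged
away; remaining downward changes are bleaching steps, upward changes
(blinking, rebinding) are flagged but never counted. Detected counts are
non-increasing in the penalty. On noise-free traces the detector equals
exhaustive enumeration of level changes; at SNR 5 it recovers the exact
count in ≥95% of traces. Two bleaching events inside one sampling interval
are physically one step — the 22-trace fixture cohort therefore redraws
bleach times until all gaps are resolvable, because its purpose is an exact
class tally (3 single / 19 multi, 86.4% multimeric).

## BLI sensorgrams

Sensorgrams follow the five-step protocol (baseline, DNA loading, wash,
protein association, dissociation); `segment_phases()` labels samples by a
schedule of phase start times and refuses schedules outside the sampled
span. The dissociation phase decays as a fast + slow biexponential of the
signal at dissociation start: the fast component models motor-dependent
recombinase removal, the slow one peptide-only destabilisation.
"Normalised to the starting point" is ambiguous between division and
subtraction; the default is division (fraction of start, in %), with an
`offset` mode (nm change) in which subtracting a flat control is exactly a
no-op. Control subtraction happens after normalisation. `fit_biphasic()`
uses curve peeling for starting values, enforces `fast_k > slow_k` by
relabeling, collapses to a single exponential when one amplitude is
negligible (<1% of the total), and falls back by AIC with a warning when
the two rates are within a factor of 3. No published rate constants are
attached to these fits; they are characterisation tools.

## Heteroduplex collisions

A stationary joint punctum sits in the second channel; encounters are
classified kinematically. Pathway: `direct` if the motor first appears
within 1 px (~725 nt, the optical resolution) of the joint, else
`translocation`. Outcomes: `stall` if post-contact motor displacement stays
under 2 px; `disrupt` (direct only) if the joint punctum moves >2 px and
its positions correlate with the motor's above 0.8; `bypass`
(translocation only) if the motor passes the joint by >2 px while the
joint persists in place; everything else — including joints released at
contact — is `other`. Trajectories with fewer than 3 post-contact frames
are indeterminate and excluded with a log message. The fixture cohort
realises the published category counts exactly, including the events the
published percentages leave unassigned (2 direct, 1 translocation), which
live in `other`; fractions at every level therefore sum to 100%.

## Reproducibility

Every stochastic entry point takes a `seed`; identical seed and
configuration give bit-identical event logs, rendered kymographs, traces
and bootstrap CIs. `cmd_simulate()` writes a manifest with the resolved
configuration, the seed, and an MD5 checksum per output file. Sizes used
by the test-suite recovery runs are the published Ns (54–152 events, 22
traces, 152 movies, 241 end strips), with 500–1000 bootstrap resamples.

## Known limitations

* No Brownian fluctuation of the extended ssDNA, no stage drift, no
  flow variation; kymographs are geometrically ideal.
* One motor per molecule in the preset pipeline (the dilute regime);
  multi-motor trajectories render correctly but the front detector follows
  only the lowest-coordinate front.
* Censoring-aware survival estimation (Kaplan–Meier or hazard models) is
  out of scope; the exclusion rule plus `d_min` offset is the documented
  estimator.
* The Gaussian histogram fit reports the binning-inflated width by
  convention.
* Classification of collisions is purely kinematic; no strand-invasion
  chemistry is modelled.
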
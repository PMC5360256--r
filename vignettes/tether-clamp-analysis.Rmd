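---
title: "Analysing AFM force-clamp recordings of vesicle-membrane tethers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing AFM force-clamp recordings of vesicle-membrane tethers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tetherclamp)
```

## The measurement

Secretory vesicles attach to the plasma membrane through protein tethers
before they dock and fuse. `tetherclamp` analyses the combined
AFM/TIRF experiment that probes these tethers mechanically: an AFM
cantilever is pressed onto a membrane sheet carrying GFP-labelled vesicles
(approach, then push), binds a vesicle non-specifically, and is then
retracted under force-clamp control at four successively larger pull forces,
each held for 12.5 s. When a tether element yields, the cantilever relaxes
upward — a spike in the deflection voltage `v_defl` — and the z servo must
extend by the released length to restore the clamped force, producing a step
in the height trace `z_servo`. Simultaneous TIRF imaging of the vesicle
provides an independent height readout: the evanescent excitation decays as
`I(z) = I0 * exp(-z / d_TIRF)`, so intensity changes convert into height
changes via `dz = -d_TIRF * log((I_f - I_bg) / (I_i - I_bg))`.

The package implements the complete analysis: cantilever calibration,
event detection and sizing, event taxonomy, segment quality control, and the
summary statistics, together with a seeded synthetic-recording generator
that provides ground truth for every stage (no raw recordings of this kind
are publicly deposited).

## Sign conventions and force conversion

The deflection voltage increases when the cantilever bends away from the
surface. The free cantilever defines the baseline (0 V at zero servo
height); pressing on the surface pushes the tip up (voltage rises, force is
a push, reported negative), while a clamped pull bends the tip down
(setpoint voltage below baseline, force positive):

`F [pN] = -1000 * k [N/m] * D [nm/V] * (V_setpoint - V_baseline)`.

Two baselines enter: `v_contact` (free level just before contact) and
`v_end` (free level after final release). Their two force estimates are
averaged; half their spread, combined in quadrature with the baseline noise
term `k*D*sd`, defines `sigma_F`. This makes explicit that the dominant
force uncertainty comes from whether the cantilever was truly free when the
baselines were measured. When only one baseline exists the segment is
flagged rather than silently defaulted.

Deflection drifts slightly with servo height; the drift (V/um) is estimated
by regressing `v_defl` on `z` over out-of-contact episodes (the approach
phase in simulated recordings) and subtracted before any detection. The
pipeline corrects drift first and detects afterwards; correction can be
skipped by passing a zero drift.

## Event detection

Tether-release transients have the morphology of amperometric spikes — a
step-like rise and a single-exponential relaxation — and are detected the
same way:

1. residuals against the clamp baseline (the setpoint) are thresholded at
   4 robust noise SDs (noise estimated from median absolute successive
   differences, insensitive to the transients themselves);
2. above-threshold runs are grouped into events; an event ends only when
   the trace has returned to within 2 SD of baseline for a sustained
   stretch (50 ms) or the next peak is more than 3 decay constants away —
   overlapping transients thus merge into *complex* events, mirroring how
   overlapping releases appear in real traces;
3. the rising flank is fitted linearly (its baseline intercept defines
   `t_start`), the falling flank log-linearly (`tau`; `t_end` is where the
   fitted decay re-enters one noise SD of baseline);
4. the extension is measured from the servo trace by least-squares lines
   over 200-ms windows before `t_start` and after `t_end`, evaluated at the
   midpoint — exact on noiseless piecewise-linear traces, and robust to
   baseline creep. Windows truncated by neighbouring events are flagged.

Events are then typed: `R` (rapid) if they begin before the segment's
setpoint was first attained (the piezo is still moving, so no reliable
extension can be measured), `F` (full dissociation) if the deflection stays
at the free-cantilever level from just after the peak to the end of the
segment, `FC` otherwise. Sizes follow the short/extended taxonomy: `S`
(unitary, < 50 nm), `E` (unitary, >= 50 nm), `C_S`/`C_E` for complex
events, with the 50-nm tie assigned to the extended class because the short
class is defined by a strict inequality. The detection threshold, merge
factor and window lengths are exposed as parameters; the source analysis
delegated them to external spike-analysis software without printing values,
so the defaults here (4 SD, 3 tau, 200 ms) were chosen once as standard
practice for this spike morphology.

## Segment quality control

Clamp segments enter the statistics only after the selection cascade, in
this order: segments that never reached their target setpoint; `F` > 1000
pN; `F` < -200 pN; `sigma_F` > 200 pN; `F` < 0 (push forces); and type-U
segments (tip plainly holding nothing: no events after setpoint attainment,
no events in any later segment, and every deflection rise paired with servo
travel of ~1 um or more). Boundary values survive (the force rules are
strict inequalities) and `F = 0` survives with a warning flag. Each
excluded segment is attributed to the first rule it fails, counts are
reported after every rule, and re-running the cascade on its survivors is a
no-op. A diagnostic (not a filter) counts event-bearing segments in the
push range, supporting the removal of push-force segments.

## Statistics

* Binned event proportions (`P_FC` per 10-min bin of time after cell
  lysis) carry exact central Clopper-Pearson 68% binomial intervals, and
  their trend is assessed by *unweighted* ordinary least squares on the bin
  means.
* Event rates are Poisson: `rate = n/T`, `se = sqrt(n)/T`.
* Two rates are compared by the exact conditional test: given
  `N = n1 + n2`, `n1 ~ Binomial(N, T1/(T1+T2))` under the null; the
  two-sided p-value doubles the smaller tail (capped at 1). The doubled-tail
  convention was chosen because it reproduces the reference comparisons this
  analysis is validated against; it is exactly testable by enumeration.
* Step-size histograms use 2.5-nm bins centred from -8.75 to 48.75 nm
  (half-open intervals; negative bins absorb measurement noise) and are
  summarised by an unweighted least-squares Gaussian, whose covariance
  supplies the SE of the peak position.
* The unfolding calculators encode the polypeptide arithmetic: 0.365
  nm/residue unfolded contour minus 0.15 nm/residue helical rise gives
  0.215 nm/residue; helices of 25-40 residues yield 5.4-8.6 nm; the 6,216
  residues of the eight exocyst subunits give a ~2.3 um maximal contour.

## The synthetic-recording generator

`simulate_recording()` emulates the acquisition protocol: a coarse approach
(140 ms/point, ~150 nm/s), a 5-s push, and four 12.5-s clamps at 100-400 pN
with 0.2-s setpoint ramps, sampled at 1 kHz (the acquisition rate of the
original clamp phase is not documented; 1 kHz resolves the 20-80 ms decay
constants comfortably). Defaults: spring constant 0.03 N/m and deflection
sensitivity 50 nm/V (mid-range of the calibrated instruments), drift -0.05
V/um, deflection noise 2 mV.

Events are Poisson in time (0.24 events/s short, matching the most active
condition; long events at 0.02/s with log-uniform magnitudes 50-2000 nm).
Each release adds `dz/D * exp(-t/tau)` to the deflection — saturating at
the free-cantilever level, so large releases show a plateau before the
exponential tail — while the servo extends by `dz` with the same time
constant after a 10-ms response delay. Full-dissociation events drop the
deflection to the free level and rail the servo; rapid events are placed on
the setpoint ramps. The TIRF renderer draws the tip vesicle as a Gaussian
spot whose 3x3-ROI mean equals the evanescent-model intensity at the
vesicle's current height, plus static background vesicles and optional
Poisson shot noise, with frame numbers encoded in the `fnum` trace as
`frame/1000`.

Short-event magnitudes are drawn from Gaussian(4.5, 3.1) nm *truncated at
zero*, since a tether extension is physically positive. This matters when
interpreting recovery results: the truncated population has mean 4.97 nm,
and a least-squares Gaussian fitted to its histogram peaks 0.2-0.5 nm above
the nominal 4.5. The pipeline itself is nearly unbiased (median extension
error -0.14 nm on isolated events, dominated by the last few percent of
servo settling), so recovered peaks of ~4.6-5.0 nm reflect the generated
population, not an estimator defect.

What the generator does *not* emulate: polymer elasticity of the tether
(worm-like-chain force-extension), cantilever hydrodynamics, bilayer
mechanics, low-frequency 1/f noise, or vesicle photobleaching. Passing
recovery tests therefore demonstrate correctness of the analysis chain
under idealised noise, not robustness to every artefact of real traces.

## Numerical choices and degenerate inputs

* Exponential fits (decay-length calibration, Gaussian peaks) use
  Levenberg-Marquardt with positivity bounds and moment-based starts;
  transient decays use log-linear fits, which are exact for clean single
  exponentials and cheap at scale.
* The decay-length aggregate is an inverse-variance weighted RMS mean
  (weights from each fit's covariance); approaches without a monotonic
  intensity increase (Spearman rho > -0.5) are excluded and reported.
* Noise floors: a zero-noise trace gets an effective SD of 1e-4 of the
  largest residual so that thresholding and `t_end` remain defined.
* Time intervals are half-open `[start, end)`; pixel coordinates are
  0-based with the ROI centre naming the central pixel; histogram bins are
  half-open `[centre - w/2, centre + w/2)`.
* Out-of-field intensities (background-subtracted intensity <= 0) yield
  flagged `NA` heights rather than errors, so whole traces convert at once.
* Empty inputs: an event-free segment yields an empty (typed) event table;
  an empty segment table passes the QC cascade with zero counts.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1, out_dir = "demo_run")
res <- run_pipeline(cfg)
res$stats
```

This simulates one recording, calibrates, detects, filters and summarises,
writing the artifact bundle (recording TSV + JSON metadata, ground-truth
log, segment and event tables, QC report, statistics, provenance with seed
and config hash) into `demo_run/`. Re-running with the same seed reproduces
the TSV outputs byte for byte.

The problem sizes used throughout the tests and the acceptance script —
forty 4-segment recordings (a few hundred events) for distribution
recovery, five approach series for decay-length calibration, six hundred
segments for the proportion trend, one hundred seeded repetitions for
detector recall — were chosen to keep every Monte-Carlo standard error
well inside the tolerance it is checked against.

## Known limitations

* Phase parsing reads the acquisition schedule from the recording metadata;
  recordings without a schedule (e.g. hand-imported traces) are not yet
  segmented by plateau detection.
* `v_end` (the post-release free baseline) is unavailable in simulated
  recordings, which end at the last clamp; pipeline forces are then based
  on `v_contact` alone and flagged accordingly.
* The semiautomatic review step of the original workflow is reduced to an
  optional accept/reject mask (`accept_mask` in `detect_events()`); there
  is no interactive curation.
* Complex events carry a single total extension, as in the reference
  analysis; sub-peak decomposition is not attempted.
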
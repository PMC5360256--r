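# tetherclamp

Analysis of combined AFM force-clamp and TIRF recordings of
secretory-vesicle-plasma-membrane tethers.

## The problem

Before a secretory vesicle docks and fuses, it is held to the plasma
membrane by protein tethers whose mechanics can be probed directly: an AFM
cantilever binds a vesicle on a membrane sheet, then pulls at four
successively larger clamped forces (F1-F4, each 12.5 s). Each time a tether
element yields, the deflection voltage spikes upward and the z servo steps
out by the released length — stair-step extensions from a few nm to beyond
a micrometre. Simultaneous TIRF imaging gives an independent height
readout through the evanescent excitation decay,

    I(z)  = I0 * exp(-z / d_TIRF)
    dz    = -d_TIRF * ln((I_f - I_bg) / (I_i - I_bg))

which separates true vesicle-membrane tether extensions from stretching of
the tip-vesicle link. The short extensions cluster around ~4.5 nm — the
gain expected from unfolding single alpha-helices of helical-bundle
tethering complexes (0.365 nm/residue unfolded contour minus 0.15
nm/residue helical rise = 0.215 nm/residue; 25-40-residue helices give
5.4-8.6 nm).

`tetherclamp` is for biophysicists who need this analysis chain as tested,
reusable code: cantilever calibration (deflection sensitivity, drift, pull
force `F = -k*D*(V_set - V_free)` with uncertainty), amperometric-spike-style
transient detection with exponential-decay fitting, two-line extension-step
estimation, the FC/R/F and S/E/C_S/C_E event taxonomy, the segment-selection
cascade, evanescent-field optics, and the summary statistics
(Clopper-Pearson 68% intervals, Poisson rates and exact rate tests,
step-size histograms with Gaussian peak fits). Because no raw recordings of
this kind are deposited, the package includes a seeded synthetic-recording
generator with a ground-truth event log; every stage is validated by
parameter recovery against it.

## Worked example

```r
library(tetherclamp)
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "demo_run"))
str(res$stats)
#> List of 8
#>  $ n_events              : int 10
#>  $ n_fc_short            : int 9
#>  $ total_clamp_duration_s: num 50.2
#>  $ short_event_rate_per_s: num 0.179
#>  $ short_event_rate_se   : num 0.0598
#>  $ dz_peak_nm            : num 7.91
#>  $ dz_peak_se_nm         : num 0.399
#>  $ dz_sd_nm              : num 1.23
```

One simulated recording was generated, drift-corrected, parsed into its
four clamp segments, scanned for events, quality-filtered and summarised:
10 events were detected in 50.2 s of effective clamp time, 9 of them short
(< 50 nm), giving a short-event rate of 0.179 ± 0.060 events/s. (With only
~9 events the fitted histogram peak is noisy — 7.9 nm here; pooled over
forty such recordings it converges near the generating 4.5 nm, which is
what `scripts/acceptance.R` measures.) The retained segments carry their
computed pull forces:

```r
res$qc$survivors[, c("index", "setpoint_F", "F", "sigma_F")]
#>  index setpoint_F        F  sigma_F
#>      1        100 103.3866 2.679992
#>      2        200 203.3866 2.679992
#>      3        300 303.3866 2.679992
#>      4        400 403.3866 2.679992
```

and the event table types and sizes each transient:

```r
head(res$events[, c("segment_index", "event_type", "shape", "size_class",
                    "tau", "dz")], 3)
#>  segment_index event_type   shape size_class    tau   dz
#>              1         FC unitary          S 0.0350 9.32
#>              1         FC unitary          S 0.0302 1.82
#>              2         FC unitary          S 0.0688 7.81
```

Single quantities work standalone:

```r
theoretical_decay_length(488, 66.8, 1.515, 1.33)  # 94.15 nm
event_rate(53, 221)                               # 0.240 +/- 0.033 events/s
poisson_rate_test(19, 238, 11, 200)               # p = 0.42
helix_extension(25)                               # 5.375 nm
```

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R` (`Rscript run_pipeline.R --seed 1 --out
runs/demo`).

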
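# spbquant

Quantitative fluorescence microscopy of spindle pole body (SPB) associated
proteins in budding yeast: acceptor-photobleaching FRET, FRAP recovery
kinetics, SPB intensity asymmetry, and anaphase timing from spindle-length
time-lapse traces — together with a synthetic microscopy-data generator that
provides ground truth for every analysis stage.

The package is written for cell biologists who quantify protein–protein
proximity and binding dynamics at diffraction-limited structures (the yeast
SPB is the motivating case) and want the whole analysis chain — spot
detection, ROI measurement, background correction, normalization, statistics
— to be scripted, testable and reproducible rather than spreadsheet-bound.

## The quantities it computes

**Acceptor-photobleaching FRET.** When a donor fluorophore (e.g. mTurquoise)
transfers energy to a nearby acceptor (e.g. EYFP), destroying the acceptor
with a laser pulse de-quenches the donor. For each cell, mean donor ROI
intensities before and after the bleach are background-corrected with
untagged cells,

    FL_cor = FL − FL_bg                                   (1)

and the apparent efficiency is the percentage increase

    E = 100 · (FL_cor_post − FL_cor_pre) / FL_cor_pre     (2)

Each distribution is then corrected by the median of the donor-only control,

    FRET efficiency% = E − median(E_D)                    (3)

which removes donor-only systematic effects such as acquisition bleaching
between the two donor exposures. A pair is called *positive* when the
normalized donor+acceptor distribution exceeds the donor-only control by a
two-tailed Student t-test at p < 0.01 **and** the shift is an increase.

**FRAP.** Spot-intensity traces around a bleach event are normalized to
their pre-bleach mean and fitted with the single-exponential recovery
`I(t) = c + a·(1 − exp(−k t))`, `t` from the first post-bleach frame. The
fit reports the half-recovery time `t½ = ln 2 / k`, the mobile fraction
`a / (1 − c)`, and R²; flat traces surface as `t½ = ∞`, never as an error.

**Descriptive statistics.** Box-whisker summaries use inclusive
linear-interpolation quartiles with the 1.5 × IQR outlier fence; OLS trend
R²; max-to-1 intensity normalization; strong/weak (SPB1/SPB2) pole
classification; and anaphase duration scored as the time from onset of
rapid spindle elongation to spindle breakdown.

**Synthetic data.** `simulate_fret_image_set()` renders pixel-integrated
Gaussian spots on cytoplasmic background with Poisson shot noise, camera
offset and read noise, encoding donor quenching via `q = e/(100+e)` so a
configured apparent efficiency `e` is recovered exactly by equations (1)–(3)
in the noiseless limit. `simulate_frap_trace()`, `simulate_spindle_traces()`
and `simulate_spb_intensity_table()` provide the corresponding kinetic and
morphometric fixtures, all with recorded ground truth.

## Worked example

```r
library(spbquant)

# tandem donor-acceptor fusion: the maximal-FRET control (26% ground truth)
set <- simulate_fret_image_set(fixture_config("tandem_bfa1", seed = 7))
res <- quantify_image_set(set)
res
#> <fret_pair_result> sim_e26
#>   mean FRET efficiency%: DA 26.24 (n = 40), D 0.15 (n = 40)
#>   donor-only median used for normalization: -0.711
#>   two-tailed Student t-test p = 6.29e-52 (alpha 0.01) -> POSITIVE FRET pair
```

The 40 simulated donor+acceptor cells average 26.24% de-quenching against a
donor-only control centred on zero — recovering the configured 26% within
sampling error — and the pair is called positive. `tidy(res)` gives the
per-group box-whisker table, `autoplot(res)` the box-whisker figure, and
`res$cells` the per-cell audit trail including every exclusion reason.

```r
# FRAP: fast exchange at the SPB (11 s half-recovery ground truth)
traces <- simulate_frap_traces(fixture_config("kar9_misaligned_frap", seed = 7), n = 20)
fit_single_exponential(average_recovery_curve(traces))
#> <frap_fit> single-exponential recovery
#>   k = 0.06176 /s   t-half = 11.22 s   mobile fraction = 0.806   R^2 = 0.9790

# anaphase timing (23 min ground truth)
sp <- simulate_spindle_traces(fixture_config("spc72_aligned_spindle", seed = 7))
sc <- score_spindle_traces(sp)
mean(sc$duration_min[sc$status == "ok"])
#> [1] 23.2
```

A thin command-line front end over the same functions ships at
`inst/scripts/spbquant` (`simulate`, `quantify-fret`, `fit-frap`,
`score-timelapse`, `summarize`, `run-all`), and `run_pipeline()` executes a
whole YAML-configured simulate → quantify → report run with a config echo
for reproducibility.

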
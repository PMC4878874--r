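---
title: "Models and methods: FRET, FRAP and spindle-timing quantification at SPBs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: FRET, FRAP and spindle-timing quantification at SPBs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spbquant)
```

This vignette documents the models behind `spbquant`, the assumptions they
make, the tunable parameters and their defaults, and the design choices
taken where more than one convention was defensible. It states no numbers
that the package's tests and `scripts/acceptance.R` do not themselves
compute.

## Acceptor-photobleaching FRET

### The measurement model

A donor fluorophore within Förster distance (~10 nm) of an acceptor loses a
fraction of its excitations to energy transfer; its emission is *quenched*.
Photobleaching the acceptor abolishes transfer, so the donor de-quenches,
and the fractional rise in donor signal reports the proximity of the pair.
The assay needs three samples: the donor+acceptor strain (`DA`), a
donor-only control (`D`), and untagged cells (`bg`) for background. Four
single-plane images are taken per cell in a fixed order — acceptor pre,
donor pre, acceptor post, donor post — and for each cell the pipeline
computes

1. background correction: `FL_cor = FL − FL_bg`, with `FL_bg` the per-phase
   mean over all background-cell pixels;
2. percentage increase: `E = 100·(FL_cor_post − FL_cor_pre)/FL_cor_pre`;
3. normalization: every `E` minus the donor-only median, so the normalized
   donor-only median is exactly zero.

The pair is *positive* if a two-tailed Student t-test of normalized `DA`
against normalized `D` gives p below `alpha` (default 0.01) **and** the `DA`
mean exceeds the `D` mean; a significant *decrease* is never a FRET call.

### Why normalization is a subtraction

The donor-only control is centred near zero but not at zero: the second
donor exposure loses a little signal to acquisition bleaching, shifting all
percentage increases slightly negative. Subtracting the donor-only median
removes this additive shift and pins the control's median at exactly zero,
which is what the near-zero donor-only distributions in this assay's figures
show. A division variant is implemented (`normalization = "divide"`) but is
numerically unstable precisely because the control's median is near zero;
subtraction is the default.

### Spot detection and ROIs

SPB spots are diffraction limited, so detection band-passes the image with a
difference of Gaussians matched to the spot scale (`smooth_sigma_px`,
default 1.3 px, and 4× that for the background filter), keeps local maxima
above `median + threshold_sd × MAD` (default 5 robust SDs), and suppresses
non-maxima within `min_separation_px` (default 5 px). Measurement is the
plain mean of a `(2h+1)×(2h+1)` pixel box centred on the detected maximum;
`h = 2` (a 5×5 box) covers a diffraction-limited spot at a typical 60×/1.4
oil objective scale (~0.107 µm pixels) and is configurable. Because the same
box is used pre- and post-bleach, the PSF mass inside the box cancels in the
percentage increase; ROI placement does not bias `E`.

Cells with no detectable spot or with non-positive corrected pre-bleach
intensity are excluded, each with a recorded reason in the per-cell table —
never imputed.

### The synthetic image generator

`simulate_fret_image_set()` encodes exactly the photophysics the analysis
assumes. The configured ground truth is the *apparent* efficiency `e` (the
percentage increase the assay reports), converted internally to a quench
factor `q = e/(100+e)`. With pairing fraction `p` and bleach completeness
`β`, expected donor spot amplitudes are `A(1−qp)` pre-bleach and
`A(1−qp(1−β))(1−d)` post-bleach (`d` = per-exposure acquisition bleaching),
so the noiseless un-normalized percentage increase is `100·qpβ/(1−qp)` — and
equals `e` when `p = β = 1` and `d = 0`. Spots are pixel-integrated
isotropic Gaussians (normal-CDF differences per pixel, so ROI means have a
closed form); each pixel's expected photon count is Poisson-sampled, then a
constant camera offset and Gaussian read noise are added.

Defaults, chosen once as representative of SPB imaging with fluorescent
proteins on a scientific CMOS/CCD: donor amplitude 5000 photons per spot,
acceptor 3000, PSF σ 1.3 px, cytoplasmic background 50 photons/px, camera
offset 100 ADU, read noise SD 2, acquisition bleaching 1% per donor
exposure, 48×48 px frames, pixel 0.1067 µm. What the generator does *not*
emulate: cell morphology, 3D PSFs, EM-gain excess noise, stage drift between
phases, or spectral crosstalk. Passing tests therefore validate the
quantification arithmetic and its statistical behaviour under realistic
shot/read noise — not robustness to registration error or bleed-through.

### Uncertainty of the recovered mean

The recovered quantity is `mean(E_DA) − median(E_D)`. Its standard error has
two parts: the per-cell scatter of the `DA` group, and the sampling error of
the donor-only median, which is *shared* by every normalized value. The
recovery tests therefore use
`SE² = var(E_DA)/n_DA + (π/2)·var(E_D)/n_D`
(the `π/2` factor is the asymptotic variance inflation of a median under
approximate normality). Ignoring the second term understates the
estimator's uncertainty. For the same reason, background is pooled over all
pixels of the untagged-cell images rather than one small box per cell: a
noisy background estimate shifts *every* cell's efficiency coherently.

## FRAP recovery fitting

Traces are normalized to their pre-bleach mean (≥3 pre-bleach frames
required); an optional unbleached-reference trace, normalized the same way,
can divide the trace frame-wise to cancel acquisition bleaching. The model
is the reaction-dominant single exponential

`I(t) = c + a·(1 − exp(−k t))`,

with `t = 0` at the first post-bleach frame (the convention of the
time-lapse panels this assay produces). Fits use Levenberg–Marquardt
least squares multi-started over `k ∈ {0.01, 0.05, 0.1, 0.5, 1} s⁻¹`,
keeping the lowest-residual solution, because single-start exponential fits
are initialization-sensitive. Derived quantities: `t½ = ln 2/k`, bleach
depth `1 − c`, mobile fraction `a/(1 − c)`, and R² over the post-bleach
frames.

"No recovery" is a result, not an error: fits with `k` below 10⁻³ s⁻¹ *or*
negligible recovery amplitude (mobile fraction < 10⁻³; on a flat trace `a`
collapses to zero and `k` is unidentifiable) report `t½ = ∞`; optimizer
failure reports `converged = FALSE`.

Whether a data set's half-time should come from fitting the averaged curve
or from averaging per-trace fits is a genuine choice: the averaged-curve fit
is less noisy and matches how recovery figures draw one curve per data set,
while per-trace fits expose the spread. Both are provided
(`average_recovery_curve()` + `fit_single_exponential()`, and
`fit_frap_traces()`); the parameter-recovery checks use the per-trace mean,
which is the more conservative estimator (its Jensen bias on `ln 2/k` is
part of what the tolerance absorbs).

The FRAP simulator draws additive Gaussian noise (`noise_sd` 0.1 of the
pre-bleach level, i.e. SNR 10) on the exact recovery curve; defaults are 10
pre- and 90 post-bleach frames at 1 s. The slow-exchange fixture
(`spc72_misaligned_frap`, 6-fold slower off-rate) observes 240 s
post-bleach — a deliberately longer window, since fitting a rate from a
window much shorter than `1/k` is ill-conditioned.

## Box-whisker, t-test, trend and SPB asymmetry conventions

* Quartiles: inclusive linear interpolation (`quantile(type = 7)`, the
  spreadsheet/plotting default); fences at 1.5 × IQR; whiskers are extreme
  *data* values inside the fences; everything outside is an outlier,
  always reported (display is a flag in `autoplot()`).
* t-test: classical pooled-variance Student form, two-tailed (Welch behind
  `equal_variance = FALSE`); degenerate zero-variance inputs return the
  limiting p-value (1 for equal means, 0 otherwise) with a warning.
* Trend: OLS with `R² = 1 − SSres/SStot`; constant `x` is an error.
* SPB1/SPB2: within a cell the stronger pole is SPB1; ties keep acquisition
  order and set a flag. Pooled displays normalize the data-set maximum to 1.

## Anaphase-duration scoring

Spindle-length traces are scored with two thresholds the original assays
applied by eye, here made explicit and configurable: onset is the first time
the centred 3-frame sliding-window elongation rate exceeds
`rate_threshold_um_per_min` (default 0.5 µm/min — half the canonical
~1 µm/min fast-phase rate), and breakdown is the first subsequent time the
length drops below `collapse_fraction` (default 0.5) of the running maximum
length. Both event estimates are quantized to the sampling grid (±1 sample
at 1-min sampling), but the quantization biases of onset and breakdown
largely cancel in their difference, so durations are recovered essentially
unbiased. Cells without a detectable onset return `status = "no onset"`;
cells that never break down are *censored* at the end of observation
(`censored_at_min`), mirroring how arrested cells are reported as "> span"
rather than given a duration.

The spindle simulator draws onset and duration per cell from normal
distributions (defaults N(10, 2) and N(23, 4) min, durations truncated at
2 min so breakdown always follows onset) over a biphasic profile: metaphase
plateau 1.5 µm, elongation at 1 µm/min to an 8 µm plateau, collapse to
0.5 µm, with 0.05 µm Gaussian length noise at 1-min sampling over 60 min.

## Problem sizes and determinism

All validation runs at desk scale: 40/40/20 cells for the FRET fixtures,
20 traces per FRAP fixture, 30 spindle traces — sizes matching the sample
sizes such experiments typically report, and small enough that the full
test suite and the acceptance script each run in well under a minute per
stage on one CPU. Every stochastic stage takes an explicit integer seed;
`run_pipeline()` fans a single global seed out to independent per-stage
seeds and writes a config echo, so any run is reproducible bit-identically
(deterministic stages) or seed-identically (stochastic ones).

## Known limitations

* Sensitized-emission FRET with crosstalk correction is out of scope; the
  pipeline quantifies donor de-quenching only, and no molecular distance or
  true transfer efficiency is derived from the apparent percentage.
* Single-plane 2D images; no multi-plane registration, no drift model.
* The exponential FRAP model is reaction-dominant; diffusion-coupled
  recovery and multi-component exponentials are not fitted.
* Arrest durations are reported as censored values, not modelled with
  survival methods.
* The synthetic generator's noise model (Poisson + Gaussian read noise +
  offset) omits EMCCD gain-register noise; on EM cameras the effective
  per-photon variance is higher than simulated.
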
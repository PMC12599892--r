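---
title: "Quantifying spheroid mechanics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spheroid mechanics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherelast)
library(dplyr)
```

`spherelast` implements two independent optical readouts of tumor-spheroid
stiffness — shear-wave elastography and Brillouin microscopy — together with
the image-based size tracking and the nonparametric longitudinal statistics
used to compare drug-treated and control spheroids over a multi-day study.
Because real acquisitions of this kind live inside instruments, the package
ships a synthetic-data module that emulates each input with known ground
truth; every stage of the analysis is validated by parameter recovery
against that truth. This vignette explains the models, the parameters that
matter, and the design decisions taken where more than one convention was
defensible.

## Wave-speed elastography

### Model

Phase-sensitive OCT measures axial tissue motion interferometrically: a
displacement $u$ changes the optical phase by

$$\Delta\varphi = \frac{4\pi n u}{\lambda_0},$$

with $\lambda_0$ the source center wavelength (default 1310 nm) and $n$ the
tissue refractive index (default 1.38, the common soft-tissue value; the
instrument this emulates does not constrain it, so it is an explicit
parameter). A mechanical pulse launched at the sample surface arrives at
depth $z$ after a delay $\tau(z) = \tau_0 + z/c$; fitting delay against
depth and inverting the slope yields the wave speed $c$. Young's modulus
then follows from the bulk shear-wave relation

$$c = \sqrt{G/\rho}, \qquad G = \frac{E}{2(1+\nu)}
  \;\;\Longrightarrow\;\; E = 2\rho(1+\nu)\,c^2,$$

with density $\rho = 1000$ kg/m³ and Poisson's ratio $\nu = 0.49$ by
default (soft, nearly incompressible tissue), so $E = 2980\,c^2$ Pa for
$c$ in m/s. Guided-wave and viscoelastic corrections are out of scope: the
inversion deliberately uses the bulk relation only.

### Delay estimation

How the arrival delay is extracted from the depth–time map is a genuine
design choice; we use normalized cross-correlation of each depth's
waveform against a reference depth, with parabolic interpolation of the
correlation peak for sub-frame precision — the standard estimator in
wave-based elastography. The correlation peak value doubles as a per-depth
quality score: depths below `min_quality` (default 0.5) are excluded from
the slope fit, flat waveforms are flagged invalid rather than raising an
error, and a profile with fewer than three usable depths or a non-positive
slope fails explicitly ("no propagating wave detected"). Peak-arrival
tracking would be the simpler alternative; cross-correlation uses the full
waveform and degrades more gracefully with noise. The slope fit is
ordinary least squares by default, with Theil–Sen (median of pairwise
slopes) as a robust option for outlier depths. The default depth window
drops the shallowest 10 % of samples, where surface reflections corrupt
phase most; depth is physical (optical-path–corrected) depth, and the
generator uses the same convention so round trips are exact.

### Synthetic forward model

`simulate_oce_map()` propagates a Gaussian displacement pulse (temporal
sigma 25 µs, amplitude 100 nm) at a configurable speed through a 400 µm
deep, 64-sample axial window recorded over 256 frames at 5 µs — sizes
chosen so even a 0.5 m/s wave crosses the full window, and small enough
that the recovery suites (4 speeds × 100 noise seeds) run in seconds.
Phase noise is additive Gaussian; its default standard deviation,
$4\pi n \cdot 2.6/\lambda_0 \approx 0.034$ rad, is calibrated so that the
equivalent displacement noise equals the 2.6 nm displacement stability of
the emulated instrument. Amplitudes large enough to wrap the phase are
refused unless `allow_wrapping = TRUE`, in which case the per-depth
temporal unwrap in `phase_to_displacement()` restores them. What the
generator does **not** model: speckle decorrelation, depth-dependent
attenuation of the pulse (available but off by default is only amplitude
constancy), guided-wave dispersion in a finite spheroid, and refraction.
Passing the recovery suites therefore demonstrates that the inversion is
correct for a clean time-of-flight field at realistic phase noise, not
that it is robust to every artifact of real tissue data.

## Brillouin microscopy

### Model

Spontaneous Brillouin scattering shifts light by
$\Omega = 2 n v / \lambda$ in backscattering, with $v$ the acoustic
velocity; stiffer material, larger shift. A two-stage VIPA spectrometer
disperses the scattered light so that each spectral order shows an
anti-Stokes and a Stokes peak. Under the convention adopted throughout
the package, the two peaks within one order are separated by

$$d = \frac{\mathrm{FSR} - 2\Omega}{\delta} \;\text{pixels},$$

where FSR is the free spectral range (~30 GHz here) and $\delta$ the
dispersion in GHz/pixel. The generator and the decoder share this
convention; `brillouin_shift()` inverts it as
$\Omega = (\mathrm{FSR} - \delta d)/2$ and rejects decodes outside
$(0, \mathrm{FSR}/2)$ as order-ambiguous.

### Peak fitting and calibration

Peaks are Lorentzian — the physical Brillouin lineshape; instrument
broadening toward a Voigt profile is a documented simplification — and are
fitted jointly by Levenberg–Marquardt least squares with a constant
offset, seeded from local maxima after running-median baseline
subtraction. Calibration uses the reference liquids water, acetone and
methanol: measuring the separation $d_m$ for materials of known shift
$\Omega_m$ makes the instrument model linear in $\mathrm{FSR}/\delta$
(intercept) and $-2/\delta$ (slope), solved in closed form by least
squares. Two materials determine the system exactly (zero residuals);
three overdetermine it and give per-material residuals whose RMS above
0.05 GHz records a quality warning. The known shifts are derived from
tabulated $(n, v)$ at 660 nm via $\Omega = 2nv/\lambda$ (water 5.97 GHz,
acetone 4.83 GHz, methanol 4.44 GHz); on a real instrument they are user
inputs, since they depend on wavelength and temperature.

Reported shift standard errors propagate from the fitted peak-center
covariance assuming homoscedastic noise. Under Poisson (photon-counting)
noise the variance is larger at the peaks, so this stderr underestimates
the empirical spread — by roughly 1.6× at peak SNR ≈ 20 in the validation
suite — while the shift itself remains unbiased well within the claimed
precision. A weighted fit would close that gap and is a known limitation,
not a correctness issue for the shift estimate.

### Simulated spectra

Defaults: 640-pixel axis (wide enough that both orders fit for any shift
in $(0, \mathrm{FSR}/2)$ at $\delta = 0.1$ GHz/px), linewidth 0.6 GHz,
amplitude 1000 counts over a 50-count baseline, with none/Gaussian/Poisson
noise models. The generator places exactly two orders and ideal Lorentzian
peaks; it does not model VIPA envelope curvature, inter-order intensity
variation, cosmic-ray spikes or detector gain.

## Imaging

Repeated B-scans are averaged pixelwise (three repeats in the emulated
protocol); the residual-variance estimate of single-frame noise implies a
$\sqrt{N}$ SNR gain, and identical frames flag the gain as undefined
rather than inventing one. Spheroid segmentation uses Otsu's
between-class-variance threshold — appropriate because a spheroid on a
uniform background is bimodal, and documented as unsuitable for
debris-heavy fields — followed by the largest 8-connected component with
holes filled. A separability guard (class means closer than three
within-class spreads) converts the no-contrast case into an explicit
"segmentation failed". Morphology is reported in physical units:
area, equivalent diameter $2\sqrt{A/\pi}$, and circularity
$4\pi A/P^2$ clamped at 1, since rasterized perimeters carry a few percent
discretization error. Size trajectories are expressed relative to day 0.

## Longitudinal statistics

The study design is 3 culture models (glioblastoma monoculture LN229,
astrocyte monoculture HA, co-culture CO) × 2 conditions × days {0, 4, 7},
with three independent experiments in triplicate (9 replicates per cell).
`summarize_study()` runs a Kruskal–Wallis test across days within each
(group, condition) series and a Mann–Whitney U test between control and
treated at each (group, day) — the per-condition reading of "across days",
with the pooled alternative left to the user — plus the normalized
summary. Conventions, all of which were open choices:

* **Exact U test.** For tie-free data with $n+m \le 14$ the p-value is
  exact over all $\binom{n+m}{n}$ labelings, with the two-sided p defined
  as $2\min\{P(U_1 \le u), P(U_1 \ge u)\}$ capped at 1. The null
  distribution is built by a subset-sum recursion and cached per $(n, m)$.
  Ties disable enumeration and fall back to the mid-rank, tie-corrected
  normal approximation with continuity correction.
* **Kruskal–Wallis.** Tie-corrected H with the $\chi^2_{k-1}$
  approximation; full-permutation exact p available for total $n \le 10$.
  A fully constant sample yields $H = 0$, $p = 1$ instead of 0/0.
* **No multiplicity correction by default**, matching the raw-p-value
  reporting convention for these small designs; Holm adjustment is one
  argument away.
* **Normalization** is the ratio of treated to control *cell means* per
  (group, day) (not the mean of per-replicate ratios), with SD by
  first-order propagation of the cell SDs. Day-0 ratios are reported as
  computed, never rebased to 1, and cells with a missing condition or
  non-positive control mean are flagged invalid rather than dropped.

### The synthetic study

`study_effect_spec()` encodes baseline values per group and multiplicative
per-day decline factors per (group, condition), with log-normal replicate
noise of mean exactly 1 and a stated CV (default 10 %). The default
factors are *synthetic illustration parameters*, chosen once to mimic the
qualitative ordering of a chemosensitivity experiment — treated LN229
softening strongly (day-7 factor 0.5 vs 0.9 in control), HA essentially
flat under treatment, co-culture intermediate (0.75 vs 0.9) — and are not
measurements. Under these conditions the day-7 normalized ratios are
approximately 0.56 (LN229), 0.83 (CO) and 0.99 (HA), and the validation
suite checks that the ordering LN229 < CO < HA ≈ 1 is reproduced in at
least 95 % of seeded runs.

```{r}
tbl <- simulate_study_table(study_effect_spec(seed = 42))
report <- summarize_study(tbl)
report$normalized |> filter(day == 7) |> select(group, ratio, ratio_sd)
```

## Numerical choices and degenerate inputs

* Phase is wrapped to $(-\pi, \pi]$; the unwrapper counts its corrections
  so silent wrap events are visible in metadata.
* Correlation-peak parabolic offsets are clamped to $\pm 0.5$ frame;
  constant delay profiles and non-positive slopes raise errors rather
  than returning infinite speeds.
* The Lorentzian optimizer runs at most 200 iterations and reports
  non-convergence with residual diagnostics; peak seeding requires local
  maxima to clear both a noise floor (5 robust SDs) and a minimum mutual
  separation of 10 px.
* Depth–time maps are persisted as 32-bit TIFF rescaled to $[0,1]$ with
  the original range in a text sidecar, because TIFF integer samples
  cannot carry negative phase directly; round-trip error is below 1e-6.
* All generators take explicit seeds and restore the caller's RNG state,
  so identical configurations are bit-reproducible without side effects.

## Problem sizes used in the validation suites

Recovery suites run at 64 × 256 depth–time maps (4 speeds × 100 noise
seeds), 640-pixel spectra (200 Poisson draws), 2000 null simulations for
the exact-test size check, and 200 seeded study tables — sizes at which
the full suite completes in well under a minute on a single core while
keeping Monte-Carlo error small against each tolerance.

## Known limitations

* The elastography inversion assumes a single non-dispersive bulk wave;
  finite-spheroid guided-wave effects bias real speeds in ways the
  synthetic suite cannot reveal.
* Brillouin shifts are reported in GHz only; conversion to a longitudinal
  modulus needs refractive-index and density maps and is deliberately not
  provided.
* Otsu segmentation requires a bimodal intensity histogram.
* Reported shift standard errors assume homoscedastic noise (see above).
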
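---
title: "Models and methods: time-resolved cardiac autofluorescence and reflectance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langflim)
```

## The measurement this package models

A fiber-probe instrument records, from the surface of an isolated perfused
(Langendorff) heart, two kinds of signal every 5 seconds:

* **TCSPC autofluorescence decays** — photon arrival-time histograms
  (1024 bins spanning a 50 ns repetition period, i.e. 20 MHz pulsed
  excitation) in four spectral channels: CH1 (372 nm excitation,
  410 ± 10 nm emission), CH2 (372 / 455 ± 25, dominated by NAD(P)H),
  CH3 (372 / 525 ± 25, NAD(P)H plus some FAD) and CH4 (438 / 525 ± 25,
  dominated by FAD).
* **Diffuse reflectance spectra** (400–700 nm) against a white reference,
  reporting myoglobin oxygenation and cytochrome-c redox state in
  blood-free tissue.

The experimental protocol has three phases: 3 min baseline perfusion with
oxygenated buffer, 7.5 min perfusion with an insult solution (oxygenated
control, deoxygenated for hypoxia, or glucose-free for substrate
depletion), then 15 min reperfusion. The solution takes roughly two
minutes to travel from the reservoir to the heart, so tissue responses lag
the switch times visibly.

## Decay model

Each channel's decay is modeled as the sum of a fast and a slow
exponential,

$$I(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2},$$

with derived metrics: the intensity-weighted mean lifetime

$$\tau_{mean} = \frac{a_1\tau_1^2 + a_2\tau_2^2}{a_1\tau_1 + a_2\tau_2}$$

and the fast-component amplitude fraction $\alpha_1 = a_1/(a_1+a_2)$.
No biochemical attribution of the two components is made. Note the
denominator of $\tau_{mean}$: it is the total component intensity
$a_1\tau_1 + a_2\tau_2$. Only this form is consistent with the published
control triples for this preparation — e.g. $(\alpha_1, \tau_1, \tau_2) =
(0.87, 0.82, 3.47)$ gives 1.85 ns, whereas replacing $a_2\tau_2$ by
$a_1\tau_2$ gives 0.58 ns, which is below $\tau_1$ and impossible for an
intensity-weighted mean.

At a 20 MHz repetition rate the slow component (~3.5 ns) has not fully
decayed within the 50 ns period, so fluorescence from preceding pulses
wraps around ("incomplete decay"). `model_decay()` handles this exactly:
each component is scaled by the closed-form periodic steady-state factor
$1/(1-e^{-T/\tau})$ and the result is circularly convolved with the
instrument response over the period (FFT, $O(n\log n)$). This is
equivalent to summing the responses of all preceding pulses and is tested
against a 200-pulse brute-force summation to $10^{-9}$ relative error.
Two further terms complete the model: a constant background per bin, and
detector afterpulsing modeled as a uniform component with amplitude
(afterpulse probability) × (total modeled fluorescence) / (number of
bins) — the standard TCSPC treatment of count-correlated delayed pulses.
Background and afterpulse are perfectly collinear (both uniform), so they
are never fitted jointly; by default both are fixed (calibration values),
and each can be switched to fitted via `fit_options()`.

## Fitting

`fit_decay()` minimizes the Neyman-weighted chi-square

$$\chi^2 = \sum_{k=1}^{n} \frac{(I(t_k) - I_{model}(t_k))^2}{\max(I(t_k), 1)}$$

by bounded Levenberg–Marquardt (`minpack.lm::nls.lm`). The $\max(\cdot,1)$
floor keeps zero-count bins usable without dividing by zero; excluding
those bins instead is available via `zero_counts = "exclude"`. Lifetimes
are constrained to [0.01, 20] ns, and a fixed four-point multi-start grid
on $(\tau_1, \tau_2) \in \{0.3, 0.8\} \times \{2.5, 4.0\}$ ns guards
against local minima while keeping the fit fully deterministic — identical
inputs always give identical output. After convergence the components are
swapped if needed so that $\tau_1 \le \tau_2$ (ties broken by larger
amplitude first). Histograms with fewer than `min_counts` photons
(default 1000) are refused rather than fitted badly. An optional IRF
temporal-shift ("color shift") parameter can be fitted
(`fit_shift = TRUE`); it is off by default since the synthetic IRFs are
registered to the data, and real calibrations differ instrument by
instrument. The full period is fitted by default; a truncated window can
be emulated through `zero_counts = "exclude"` after masking.

Noiseless model histograms are inverted to their generating parameters to
better than $10^{-4}$ relative error across a sweep of realistic
parameters, and at $10^6$ Poisson counts with a 0.25 ns FWHM IRF the mean
lifetime is recovered within 2% with replicate SD well under 0.05 ns —
the same order as the published control variability (± 0.04 ns). At the
reduced $10^5$ budget used in the analysis drivers a small downward bias
(~2–3%) in $\tau_{mean}$ appears, as expected for photon-starved
bi-exponential fits; this is visible in `analysis/02_fit_decays.R`'s
truth comparison and is why recovery claims are made at $10^6$ counts.

## Instrument response reconstruction

The IRF of each channel is measured with reference fluorophores of known
short mono-exponential lifetime (~200 ps, comparable to the laser pulse
width). The measured reference decay $M$ is the IRF convolved with
$e^{-t/\tau_{ref}}$, and the analytic inverse of that convolution is
$F(t) = M(t) + \tau_{ref}\,dM/dt$. On the sampled grid the same identity
takes the discrete form

$$F_k = M_k - e^{-\Delta t/\tau_{ref}} M_{k-1},$$

which is the exact inverse of the (periodic) discrete convolution and is
the default in `irf_from_reference()`. The central-difference evaluation
of the continuous form is kept as `method = "central"`; at this
instrument's sampling ($\Delta t \approx 49$ ps against
$\tau_{ref} \approx 200$ ps) it carries an $O(\Delta t/\tau_{ref})$
discretization bias that leaves ~10% round-trip residuals at the decay
peak, while the discrete form round-trips to machine precision on
noiseless input. Differencing amplifies shot noise, so a Savitzky–Golay
smoothing of $M$ (window 5 bins, quadratic) is applied first by default;
negative values are clamped and the result renormalized to unit sum.

## Reflectance metrics

Tissue absorbance is computed from a sample and white-reference spectrum
as $A(\lambda) = -\log_{10}(I/I_0)$. The sign is chosen so that absorber
bands appear as maxima — oxygenated myoglobin then shows its
characteristic double peak at ~544 and ~578 nm; the opposite sign
convention is available as `sign_convention = "as_printed"`. Two ratio
metrics, evaluated by linear interpolation at the exact wavelengths:

* **Oxygenation**: $A(578)/A(600)$ — 578 nm sits on the oxy-myoglobin
  peak, 600 nm is insensitive to oxygenation; the ratio falls with
  deoxygenation.
* **Cytochrome-c state**: $A(502)/A(550)$ — 550 nm is the absorption peak
  of reduced cytochrome c and 502 nm a pseudo-isosbestic point; the ratio
  falls as reduced cytochrome c accumulates in anoxia.

No spectral smoothing is applied before ratio extraction by default.
`difference_spectrum()` locates the wavelengths where two absorbance
spectra differ most (local maxima above a prominence threshold, 5% of the
difference range by default). With overlapping Gaussian chromophore
bands the difference maxima sit a few nm away from the pure template
centers — e.g. the falling flank of the 560 nm deoxy band pushes the
oxy−deoxy maximum from 578 to ~582 nm — which the tests account for.

## Time-course assembly

Intensities (and any other metric) are normalized to the mean of the
first minute of baseline (12 samples at 5 s), making every series
dimensionless with baseline ≈ 1 and invariant to common rescaling. The
optical redox ratio is computed from the normalized intensities as

$$RR = \frac{I_{CH2}}{I_{CH2} + I_{CH3}},$$

the bounded form of the NAD(P)H/FAD balance at 372 nm excitation (the
plain $I_{CH2}/I_{CH3}$ ratio is available via `alternative = TRUE`).
Phases are labeled with half-open intervals $[0,180)$, $[180,630)$,
$[630,1530]$ s — 36, 90 and 180 samples. Group summaries report per-time
mean and sample SD ($n-1$) across hearts, matching each heart's samples
to the common grid by nearest time within 2.5 s; missing acquisitions are
left as gaps, never interpolated.

The speed of an insult or recovery response is summarized by the 10–90%
transition time: the start level is the first sample(s) of the phase
window, the plateau is the median of the window's final 20% (robust to
drift, exact for series that settle), and the crossing times of the 10%
and 90% levels are linearly interpolated. For a saturating exponential
this returns $\tau\ln 9$ within a sample spacing; for a ramp that reaches
its plateau, 80% of the ramp duration. A series with no crossing returns
`NA` flagged "no transition".

## The synthetic-data generator

No deposited data exist for this preparation, so the package ships a
generator that emulates the study conditions with known ground truth.
Its defaults are the study conditions and are not tuned per test:

* **Protocol**: 306 time points (1530 s at 5 s), phases 180/450/900 s,
  transport delay 120 s. Group sizes in the analysis drivers: control 4,
  hypoxia 6, glucose depletion 5 hearts.
* **Decay baselines** (control regime): $\alpha_1$ 0.87–0.89, $\tau_1$
  0.77–0.83 ns, $\tau_2$ 3.05–3.47 ns per channel, matching the published
  control values for CH2–CH4; CH1 is given a similar regime and a low
  relative intensity (little collagen in healthy tissue).
* **Trajectories**: delayed saturating exponentials between baseline and
  insult plateau and back. The published curves are not parameterized
  numerically, so plateaus encode only the stated qualitative orderings:
  hypoxia raises CH2 intensity (+35%), lowers CH4 (−30%) and CH3 (−10%),
  shortens $\tau_1$ / raises $\alpha_1$ in the NAD(P)H channels, and
  lowers $\alpha_1$ in CH4; onset time constant 45 s versus recovery
  120 s, reproducing the reported order (~2 min onset vs ~5 min recovery,
  10–90%). Glucose depletion declines slowly (600 s constant — no plateau
  within the 7.5 min insult) and only in NAD(P)H-related metrics. Control
  is flat.
* **Noise**: per-bin Poisson counts (photon counting), 2% multiplicative
  acquisition noise (beating-heart geometry, averaged over 3–6 beats per
  second of integration), 1% multiplicative reflectance noise, and
  once-per-heart log-normal offsets (5% SD) on baselines and effect
  sizes. Default photon budget $10^6$ counts per 1 s acquisition (typical
  20 MHz TCSPC rates); the analysis drivers use $10^5$ to keep runtimes
  short, which is also the budget at which the end-to-end qualitative
  checks run.
* **Reflectance templates**: Gaussian absorbance bands at 544/578 nm
  (oxy-myoglobin), 560 nm (deoxy-myoglobin) and 550 nm (reduced
  cytochrome c) over a flat baseline that pins the 502 nm
  pseudo-isosbestic level; hypoxia sweeps the oxygenated fraction 1 → 0.05
  and the reduced-cytochrome fraction 0 → 0.8 and back.
* **Seeding**: one master seed split per (heart, time, channel) by a
  32-bit counter-mix (`derive_seed()`), so identical seeds give
  bit-identical datasets and partial regeneration reproduces the same
  draws.

What the generator does **not** emulate: cardiac motion beyond
multiplicative noise, temperature drift, real chromophore extinction
spectra, scattering, heart-rate variability, or any quantitative feature
of the published time-course figures (which were deliberately not read
for numbers). Passing end-to-end tests therefore demonstrates that the
pipeline recovers what the generator put in — directions, orderings and
stability — not that it reproduces the original measurements
quantitatively.

## Numerical and design choices

* Model evaluation clips negative FFT round-off to zero; ratios of model
  bins are accurate to ~$10^{-9}$ where counts are appreciable.
* The control-stability check reads "within noise of baseline" as the
  group mean staying inside three *per-acquisition* noise SDs of 1
  (acquisition noise plus the shared normalization noise) at every one of
  the 306 time points; a per-point SD-of-the-mean band would be violated
  a few times per metric by ordinary 3σ multiplicity even for a perfectly
  stable control.
* Problem sizes in the test suite are chosen for tight-but-fast coverage:
  512-bin grids for fit sweeps, 1024 bins wherever a claim concerns the
  real grid, 50 replicates for noise-recovery statistics, 6 + 4 hearts at
  $10^5$ counts for the end-to-end run.
* Degenerate inputs are errors, not silent results: zero baseline mean,
  both redox channels zero, insufficient photons, zero reference
  intensity (masked with a warning), out-of-range ratio wavelengths.

## Limitations

* The bi-exponential model is a simplification; no tri-exponential or
  lifetime-distribution fitting is offered.
* Afterpulsing is uniform by construction; detectors with structured
  afterpulse distributions are not modeled.
* The reflectance module computes ratio metrics only — no chromophore
  unmixing against extinction-coefficient libraries and no scattering
  correction.
* Group comparisons are descriptive (mean ± SD); no hypothesis testing is
  performed.
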
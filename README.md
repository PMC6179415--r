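# langflim

Analysis pipeline for time-resolved autofluorescence and diffuse-reflectance
measurements of Langendorff-perfused hearts.

Label-free autofluorescence of the metabolic cofactors NAD(P)H and FAD
reports the redox state of cardiac tissue. In a fiber-probe instrument the
fluorescence decay in each spectral channel is recorded by time-correlated
single photon counting (TCSPC: 1024-bin arrival-time histograms over a
50 ns repetition period) while diffuse reflectance against a white
reference tracks myoglobin oxygenation and cytochrome-c redox state. This
package implements the full analysis chain for such experiments, plus a
synthetic-data generator with known ground truth for validating every
step, emulating three-phase perfusion protocols (baseline / insult /
reperfusion) for control, hypoxia and glucose-depletion groups.

## What it computes

**Decay fitting.** Each histogram is fitted with a bi-exponential decay

    I(t) = a1·exp(−t/τ1) + a2·exp(−t/τ2)

convolved with the channel's instrument response function (IRF) and made
periodic-steady-state — at 20 MHz the slow component wraps around the
50 ns period, handled exactly by scaling each component with
1/(1 − e^(−T/τ)) before circular convolution. Constant background and a
uniform afterpulsing term complete the model. The fit minimizes the
Neyman chi-square

    χ² = Σ (I(tk) − Imodel(tk))² / max(I(tk), 1)

by bounded Levenberg–Marquardt with a fixed multi-start, and reports the
intensity-weighted mean lifetime
τ_mean = (a1τ1² + a2τ2²)/(a1τ1 + a2τ2) and the fast fraction
α1 = a1/(a1+a2). IRFs are reconstructed from reference-dye decays
(~200 ps lifetime) via the analytic inverse F_k = M_k − e^(−Δt/τref)·M_(k−1).

**Reflectance.** Absorbance A = −log10(I/I0), oxygenation ratio
A(578)/A(600), cytochrome-c ratio A(502)/A(550), and difference-spectrum
extremum location.

**Time courses.** Baseline normalization (first minute), optical redox
ratio RR = I_CH2/(I_CH2 + I_CH3), phase labeling, group mean ± SD across
hearts, and 10–90% transition times of insult/recovery responses.

## Worked example

```r
library(langflim)

# published control decay components of the NAD(P)H channel
p <- bi_exp_params(870, 130, 0.82, 3.47)
tau_mean(p)
#> [1] 1.846548
alpha_fraction(p)
#> [1] 0.87

# simulate one acquisition at a realistic photon budget and fit it back
irf <- simulate_irf(0.25)                   # Gaussian IRF, 0.25 ns FWHM
h <- simulate_decay_histogram(p, irf, total_counts = 1e6, seed = 42)
h
#> <decay_histogram> ?: 1024 bins x 0.0488 ns, period 50.0 ns, 1.00024e+06 counts
fit_decay(h, irf)
#> <bi_exp_fit> tau_mean=1.832 ns alpha1=0.867 (tau1=0.813 tau2=3.414) red.chi2=0.692 converged

# reflectance: oxygenated vs hypoxic synthetic tissue
oxy  <- simulate_reflectance(oxy_fraction = 1, noise_sd = 0)
hyp  <- simulate_reflectance(oxy_fraction = 0.05, red_cytc_fraction = 0.8,
                             noise_sd = 0)
a_o <- absorbance(oxy$sample, oxy$white_reference)
a_h <- absorbance(hyp$sample, hyp$white_reference)
c(oxygenation_ratio(a_o), oxygenation_ratio(a_h))
#> [1] 2.573794 2.019090
c(cytochrome_ratio(a_o), cytochrome_ratio(a_h))
#> [1] 0.3884706 0.2060840
```

The fitted mean lifetime (1.832 ns) recovers the generating value
(1.847 ns) within 1% at 10^6 counts; a reduced chi-square near 0.7 on
Poisson data indicates the model accounts for the counts. Both
reflectance ratios drop from the oxygenated to the hypoxic spectrum, as
deoxygenation removes the 578 nm oxy-myoglobin peak and reduced
cytochrome c raises absorption at 550 nm.

## Analysis workflow

The `analysis/` drivers run the full study on synthetic data:

```sh
Rscript analysis/01_simulate.R      # 3 groups (4+6+5 hearts), raw data + ground truth
Rscript analysis/02_fit_decays.R    # reconvolution fits vs truth, control tables
Rscript analysis/03_timecourses.R   # normalized metrics, group mean±SD, transitions
Rscript analysis/04_figures.R       # time-course and spectra figures
```

Outputs land under `results/` (tables, figures) with intermediate scratch
under `scratch/`.

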
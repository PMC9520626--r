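# thetagamma

Quantifying treatment effects in rodent hippocampal studies of gamma-band
stimulation: an R toolkit for theta–gamma phase–amplitude coupling, LFP band
power, Y-maze learning curves, microglial skeleton morphometry, and the group
statistics that tie them together. It is written for electrophysiologists and
neuroimmunologists who record local field potentials (LFP) and stain
microglia in disease-model mice (e.g. APP/PS1) and need a scripted,
reproducible version of the analysis chain that is usually spread across
MATLAB, NeuroExplorer, ImageJ and SPSS.

Because raw animal data from such studies are rarely deposited, the package
ships a first-class synthetic-data module: seeded generators for
theta–gamma-coupled LFP with 1/f background, Bernoulli trial sequences with
saturating-exponential learning, and microglia-like images with exact
ground-truth topology. Every analysis stage is tested against those known
truths.

## The core computation

The coupling readout is the Tort modulation index (MI). A recording is
detrended, band-pass filtered into a slow (theta, 8–13 Hz) and a fast
(gamma, 30–42 Hz) band with zero-phase Butterworth filters, and the Hilbert
transform yields the theta phase φ(t) and gamma amplitude envelope A(t).
The phase axis is cut into N = 24 bins of 15°; the mean amplitude per bin,
normalized to a distribution p, gives

    MI = [ln N − H(p)] / ln N,    H(p) = −Σ_j p_j ln p_j

the Kullback–Leibler distance from uniform, scaled to [0, 1]: 0 means the
gamma envelope ignores theta phase, 1 means all gamma amplitude concentrates
in a single phase bin. Scanning band pairs on a grid (1 Hz phase steps, 2 Hz
amplitude steps) yields the comodulogram heatmap.

Around it sit: Welch averaged-periodogram spectra with calibrated band power
(µV²); sliding-window learning curves (window 10, step 5) with an 80 %
trials-to-criterion; Zhang–Suen skeletonization with
branch/junction/endpoint counts, process lengths and distance-transform soma
diameters; and one-way ANOVA with a Brown–Forsythe homogeneity gate routing
LSD or Tamhane-T2 post-hoc comparisons, plus Pearson correlation between
morphometry and MI.

## Worked example

```r
library(thetagamma)

# a 60 s, 500 Hz recording with 80% theta-gamma coupling depth
sim <- generate_coupled_lfp(coupled_lfp_params(coupling = 0.8, seed = 42))
mi_from_recording(sim$recording)$mi
#> [1] 0.002199737

# and one with no coupling
sim0 <- generate_coupled_lfp(coupled_lfp_params(coupling = 0, seed = 42))
mi_from_recording(sim0$recording)$mi
#> [1] 2.163309e-06

# full seven-group study (n = 5/group): synthesize, analyze, report
res <- run_pipeline(NULL, mode = "full", study_dir = "study_out", seed = 1)
dplyr::filter(res$report$summary, measure == "mi")
#> # A tibble: 7 x 6
#>   measure group        n     mean       sd      sem
#>   <chr>   <chr>    <int>    <dbl>    <dbl>    <dbl>
#> 1 mi      APP_PS1      5 5.61e-06 4.06e-06 1.82e-06
#> 2 mi      sham         5 8.28e-06 3.83e-06 1.71e-06
#> 3 mi      tACS_14d     5 1.74e-04 1.16e-05 5.17e-06
#> 4 mi      tACS_21d     5 3.85e-04 2.01e-05 8.99e-06
#> 5 mi      tACS_28d     5 6.89e-04 2.00e-05 8.95e-06
#> 6 mi      tACS_7d      5 5.59e-05 1.15e-05 5.14e-06
#> 7 mi      WT           5 1.30e-03 4.07e-05 1.82e-05
res$report$correlation
#> <correlation_fit> r = -0.695, p = 3.64e-06, n = 35
```

Group-mean MI rises monotonically from the untreated disease model through
increasing stimulation durations to wild type, mirroring the coupling depths
the generator was given; the negative correlation says subjects with more
microglia (the disease-model end) have weaker theta–gamma coupling. Reports
(per-subject TSVs, ANOVA, post-hoc and correlation tables, run manifest)
land in `study_out/reports/`. `autoplot()` methods draw spectra,
phase–amplitude distributions, comodulograms, learning curves and
correlation fits; a thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

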